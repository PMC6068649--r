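subject_id,class_printed,D,d,dos_printed,age,gender,hd_hand
P01,1,1.04,0.94,18.31,81,male,left
P02,1,1.18,1.09,14.67,78,male,left
P03,1,1.36,1.17,25.99,87,male,left
P04,1,0.80,0.70,23.30,86,male,left
P05,1,1.71,1.45,28.10,65,male,left
P06,2,0.73,0.59,34.68,81,male,left
P07,2,1.16,0.83,48.80,54,male,left
P08,2,1.08,0.81,44.30,67,male,left
P09,2,0.78,0.58,44.38,87,male,left
P10,3,0.88,0.44,74.72,75,female,left
P11,3,0.98,0.23,94.50,86,male,left
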