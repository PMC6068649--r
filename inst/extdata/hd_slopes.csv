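subject_id,feature,phase,value
P01,rs,before,0.0792
P02,rs,before,0.0724
P03,rs,before,0.0867
P04,rs,before,0.0789
P05,rs,before,0.0854
P06,rs,before,0.1058
P07,rs,before,0.0751
P08,rs,before,0.1194
P09,rs,before,0.1194
P10,rs,before,0.1020
P11,rs,before,0.0874
P01,rs,after,0.1139
P02,rs,after,0.0917
P03,rs,after,0.0865
P04,rs,after,0.0778
P05,rs,after,0.1023
P06,rs,after,0.1058
P07,rs,after,0.0958
P08,rs,after,0.1307
P09,rs,after,0.1243
P10,rs,after,0.1035
P11,rs,after,0.0867
P01,fs,before,0.1233
P02,fs,before,0.0920
P03,fs,before,0.0847
P04,fs,before,0.1037
P05,fs,before,0.1572
P06,fs,before,0.0950
P07,fs,before,0.0871
P08,fs,before,0.0686
P09,fs,before,0.0686
P10,fs,before,0.0770
P11,fs,before,0.1146
P01,fs,after,0.1348
P02,fs,after,0.1254
P03,fs,after,0.0714
P04,fs,after,0.0930
P05,fs,after,0.0937
P06,fs,after,0.0950
P07,fs,after,0.0757
P08,fs,after,0.1255
P09,fs,after,0.1254
P10,fs,after,0.1254
P11,fs,after,0.0790
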