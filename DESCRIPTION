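Package: ppgstenosis
Title: Arteriovenous Fistula Stenosis Classification from Dual-PPG Pulse Slopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading arteriovenous fistula (AVF) stenosis in
    hemodialysis patients from photoplethysmography (PPG) pulse waveforms.
    Provides a seeded synthetic dual-PPG generator with analytic ground-truth
    beat landmarks, robust local-regression smoothing and detrending, pulse
    rising/falling-slope feature extraction with min-max rescaling, paired
    t-test feature selection, degree-of-stenosis computation from vessel
    diameters with a three-class partition, a logistic-sigmoid multilayer
    perceptron with analytic gradients and error Jacobian, from-scratch
    Levenberg-Marquardt, scaled conjugate gradient and resilient
    backpropagation trainers (plus a momentum gradient-descent reference),
    and repeated stratified k-fold evaluation with micro-aggregated
    confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
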