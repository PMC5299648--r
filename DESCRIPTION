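Package: saecgtf
Title: Transfer-Function Modelling of Intervention-Induced ECG Change via
    Signal-Averaged ECGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds signal-averaged electrocardiograms (SAECGs) from
    single-lead ECG recordings taken before, during and after an
    intervention, estimates discrete-time rational transfer functions
    between period pairs by output-error system identification (ARX
    least-squares initialization refined by Levenberg-Marquardt), selects
    the model order over a goodness-of-fit grid, and averages individual
    transfer functions coefficient-wise into generalized transfer
    functions. Includes a synthetic multi-subject trial generator with a
    known ground-truth transfer function linking periods, so the whole
    pipeline is testable without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
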