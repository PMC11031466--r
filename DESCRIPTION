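Package: ctperfusion
Title: Temporal Sampling Analysis for Brain CT Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of the effect of temporal sampling on
    brain CT perfusion (CTP). Generates synthetic 4D dynamic-contrast
    acquisitions over a two-hemisphere brain phantom with known ground-truth
    perfusion parameters and controllable artifact scenarios; simulates
    reduced temporal resolution by frame decimation; computes relative CBF,
    CBV, Tmax and MTT maps by Tikhonov-regularized deconvolution with
    contralateral normalization; applies automated quality-control rules
    (bolus truncation, low contrast-to-noise, motion); segments hypoperfusion
    (Tmax > 6 s) and infarct core (relative CBF < 30%) and derives DEFUSE-3
    style thrombectomy decisions with margin-zone exclusion; and quantifies
    agreement between sampling schemes (ICC, median and SD of differences,
    Bland-Altman) together with frame-proportional radiation-dose scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
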