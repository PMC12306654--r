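Package: bonemri
Title: CT-Like Bone MRI Simulation and Image-Quality Analysis for the Lumbar Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-echo ultrashort echo time (UTE) and field echo (FE)
    magnitude MRI acquisitions of a lumbar-spine-like digital phantom containing
    cortical bone, muscle, marrow and air, with an optional pars-defect gap.
    Converts the echo series to CT-like images by echo averaging and intensity
    inversion, quantifies image quality with region-of-interest signal-to-noise
    and contrast-to-noise ratios and slice-to-slice coefficient of variation,
    measures fracture-gap width as the full width at half maximum of a signal
    profile, and compares sequence and processing choices with a balanced
    two-way factorial analysis of variance. Metric tables are tibbles, fitted
    objects have tidy() and glance() methods, and result types have autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
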