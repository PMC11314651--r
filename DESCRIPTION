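Package: avfthrill
Title: Non-Contact Arteriovenous Fistula Thrill Quantification and Stenosis Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the Thrill vibration of hemodialysis arteriovenous
    fistulas (AVF) from non-contact luminance image stacks. Provides a
    synthetic AVF video generator, spatial moving-average filtering over a
    sweep of kernel sizes, Hanning-windowed segmented FFT power spectra,
    the band-limited Thrill signal-to-noise ratio SNR_thr(N) (5-10 Hz
    Thrill band over 15-20 Hz noise band), kernel-size optimization by
    polynomial smoothing of the residual between normalized cohort SNR
    curves, and nonparametric comparison of normal and stenotic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
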