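Package: jointsuv
Title: Joint-Level SUV Quantification for FDG and NaF PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semiautomated quantification of tracer uptake in large joints
    (knee, hip, sacroiliac) on coregistered PET/CT. Builds landmark-driven
    rectangular regions of interest, segments bone on the CT component by
    Hounsfield-unit thresholding or seeded region growing followed by
    morphological closing, converts PET activity to body-weight standardized
    uptake values, and reports the global SUVmean per joint and side.
    Includes cohort-level statistics (paired laterality t-tests, Pearson
    correlations against clinical covariates, minimal-detectable-correlation
    power arithmetic) and fully synthetic digital joint phantoms and clinical
    cohorts with designed correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
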