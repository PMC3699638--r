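Package: pulsebold
Title: Physiological Noise and Cardiac Pulsatility Mapping for Resting-State BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise decomposition of resting-state BOLD fMRI temporal
    variance into thermal and physiological components via the square
    summation law, and a cardiac pulsatility metric obtained by integrating
    the one-sided amplitude spectrum within a narrow window around the
    pulse-oximetry-derived cardiac frequency. Provides S4 containers for 4D
    BOLD series, tissue masks, pulse traces and voxel metric maps; mask
    erosion and thermal-noise ROI selection; per-subject tissue summaries;
    a cohort-level statistical battery (ANOVA/ANCOVA, post-hoc t-tests with
    Bonferroni correction, paired lesion contrasts with Cohen's d, Levene
    and Shapiro-Wilk diagnostics, correlations and age regression); and a
    synthetic BOLD phantom generator with tissue-specific cardiac
    pulsatility, broadband physiological noise, drift, thermal noise and
    lesion geometry for end-to-end validation at both cardiac-sampled
    (TR 0.25 s) and conventional (TR 2 s, cardiac-aliased) acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
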