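Package: rsfcnet
Title: Three-Level Resting-State Functional Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of resting-state fMRI functional connectivity at the
    integrity (nodal degree), network (intra-/inter-network), and edge levels
    on the 90-region AAL parcellation grouped into eight resting-state
    networks. Provides temporal preprocessing of ROI time series (volume
    trimming, linear detrending, nuisance regression, zero-phase band-pass
    filtering), Pearson correlation matrices with Fisher-z and exponential
    transforms, covariate-adjusted general-linear-model group contrasts with
    Freedman-Lane permutation and Benjamini-Hochberg false-discovery-rate
    correction, exploratory clinical-score regressions, cohort description
    from summary statistics, and a seeded block-covariance BOLD simulator for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
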