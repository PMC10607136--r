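Package: seroMAD
Title: Robust Seropositivity Calling and Prevalence Analysis for Antigen Bead Arrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of autoantibody profiles measured on planar and suspension
    bead antigen arrays. Implements per-sample robust seropositivity cutoffs of
    the form median + n * MAD on raw median fluorescence intensities, nMAD
    normalization, autoantibody load, exact Fisher prevalence comparisons
    between clinical groups, combination-panel classification with ROC curves
    and paired bootstrap comparison, ELISA verification calling (mean + 3 SD of
    healthy controls), paired longitudinal serostatus tests, and a synthetic
    cohort generator with planted seropositivity truth for end-to-end
    validation. Data are held in a SummarizedExperiment-derived container with
    antigens in rows and serum samples in columns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
biocViews: Proteomics, ImmunoOncology, Software, StatisticalMethod
RoxygenNote: 7.3.3
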