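Package: mgskit
Title: Mitotic Gene Signature Analysis and Drug Combination Synergy Scoring
    for MYCN-Driven Neuroblastoma Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the computational analyses used in studies
    of MYCN-driven neuroblastoma: genotype-by-time expression divergence and
    mitotic gene signature (MGS) construction from bulk timecourses; targeted
    single-cell qPCR normalization, signature Z-scoring and rule-based cell
    typing; tumor-cohort stratification into MGS.High/Int/Low classes with
    Kaplan-Meier and log-rank survival analysis; and AUC-based Bliss
    synergy/potency scoring of antimitotic/pro-apoptotic drug combinations
    measured as constant-ratio dose series. A synthetic-data module generates
    every input the pipeline consumes with known ground truth, so the whole
    workflow runs and is verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    pracma,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
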