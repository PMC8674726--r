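Package: metamr
Title: GWAS Summary-Statistics Meta-Analysis, Fine-Mapping, and Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A summary-statistics analysis chain for multi-cohort genome-wide
    association studies: reading and harmonizing per-cohort summary statistics,
    inverse-variance-weighted fixed-effect meta-analysis with genomic control,
    locus definition with lead-SNP selection and novelty flagging, Bayesian
    fine-mapping with 99 percent credible sets under a single-causal-variant
    model, and two-sample Mendelian randomization (IVW, MR-Egger, weighted
    median, Cochran's Q, pleiotropy exclusion) with LD-clumped instrument
    selection. Includes a summary-level simulator with known causal structure
    so every stage is testable without external consortium data, and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
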