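Package: fgcnminer
Title: Frequent Gene Co-Expression Network Mining Across Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds frequency-weighted consensus co-expression networks across
    multiple gene-expression cohorts and mines them with the local maximal
    quasi-clique merger (lmQCM) algorithm. Downstream characterization of the
    mined modules includes two-group differential expression with
    Benjamini-Hochberg correction and fold-change gating, module, cytoband and
    upstream-regulator enrichment via one-sided hypergeometric tests,
    differential copy-number analysis, and copy-number/expression concordance
    calls. A synthetic multi-cohort generator with planted copy-number-driven
    and transcription-factor-driven modules provides ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
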