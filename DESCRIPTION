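Package: pwfrank
Title: Proportion-Weighted F Ranking and Rank-Based Gene-Set Enrichment
    for Factorial Expression Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression analysis for small factorial microarray
    or RNA-seq designs with experiment-level replication. Fits a per-transcript
    linear mixed-effects model (two crossed two-level factors plus their
    interaction as fixed effects, experiment as a random intercept), ranks
    transcripts by the proportion-weighted F (PWF) statistic, calibrates the
    observed ranking against permutation-null rank envelopes, tests gene sets
    by the CERNO rank-based enrichment statistic with Benjamini-Hochberg FDR,
    and orders the resulting set-by-gene design structure matrix by
    hierarchical clustering on Canberra distances. Includes a synthetic-data
    generator with ground truth for recovery testing, and validation
    arithmetic for qPCR delta-delta-Ct concordance, cross-platform
    fold-change regression and phosphoprotein ratio filters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
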