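Package: mrprep
Title: Search-Model Preparation, Ensembling and Solution Triage for Molecular Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prepares molecular-replacement (MR) search models from
    sequence-search hits and homologue coordinates: hit filtering and
    redundancy reduction, domain clustering by alignment midpoint and
    extent, alignment-guided side-chain pruning (mixed models to the
    C-gamma atom), polyalanine reduction, iterative least-squares
    superposition onto a calculated centroid, per-position C-alpha
    variance, variance-ranked ensemble truncation with r.m.s.d.
    annotations, copy-number estimation via the Matthews coefficient,
    and triage of MR, refinement and tracing scores into ranked summary
    tables. A deterministic synthetic-fixture generator makes the whole
    pipeline testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
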