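Package: clonotools
Title: Downstream Analysis of T Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for downstream analysis of T cell receptor (TCR)
    clonotype tables after CDR3 extraction: tab-delimited clonotype I/O with
    configurable column dialects, filtering and clonotype collapsing,
    descriptive statistics and in-silico CDR3 spectratyping, sequence motif
    search, shared-clonotype and repertoire-overlap analysis (Jaccard,
    Morisita, top-cross curves), V/J gene-usage statistics (Shannon entropy,
    Jensen-Shannon divergence, PCA), repertoire diversity estimation (Hill
    numbers, Gini, Gini-Simpson, inverse Simpson, Chao1, rarefaction),
    artificial repertoire generation from a factorized V(D)J recombination
    model, and automatic single-sample and multi-sample report generation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    Biostrings,
    optparse,
    yaml
Config/testthat/edition: 3
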