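Package: tcrgvhd
Title: T-Cell Receptor Repertoire Analysis for Acute Graft-Versus-Host Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for bulk T-cell receptor (TCR) repertoires after
    allogeneic hematopoietic stem cell transplantation, oriented towards acute
    graft-versus-host disease (aGVHD). Reads AIRR Rearrangement and simplified
    clonotype tables, normalizes samples to a common productive-read depth by
    without-replacement downsampling, computes diversity and clonal-expansion
    statistics (richness, Chao1, inverse Simpson, z-score expanded clones,
    rank-band mass, CDR3 length and V/J usage spectra), clusters CDR3s into
    GLIPH-style specificity groups (local k-mer motif enrichment against a
    reference repertoire plus global near-identity), quantifies cross-sample
    sharing with the Jaccard index and classifies pre-symptomatic samples
    against GVHD and no-GVHD libraries, tracks top clonotypes across disease
    stages with Morisita-Horn overlap, and scores intersection of
    high-frequency clones with annotated antigen-specific TCR databases.
    Ships a fully deterministic synthetic-cohort generator so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
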