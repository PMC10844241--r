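Package: exprevol
Title: Phylogenetic Analysis of Gene Expression Evolution Across Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how gene expression levels evolve across a
    species phylogeny, built around Ornstein-Uhlenbeck (OU) and Brownian
    motion (BM) trait models. Provides whole-transcriptome stationary-OU
    distances with neighbour-joining expression trees and gene-bootstrap
    supports, relative-rate tests with a subsampled Wilcoxon significance
    procedure, per-gene BM/OU/multi-optimum model selection with exhaustive
    shift-configuration search scored by a combinatorially corrected BIC,
    a coincidental index quantifying whether multi-tissue expression changes
    fall on the same branch, tau expression-specificity at tissue and
    cell-cluster level, expression gain/loss calls by Fitch parsimony,
    cross-tissue cell-type homology scoring from marker overlap and profile
    correlation, conserved-region trimming of multi-species ortholog
    alignments into trimmed GTF annotations, and a simplified negative
    binomial Wald engine for sex-biased expression. A synthetic-data module
    generates expression panels evolved on a tree, count tables, toy cell
    atlases and toy alignments with known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
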