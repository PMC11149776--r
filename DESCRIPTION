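Package: treeprofiles
Title: Compact Gene-Family Views from Reconciled Gene Trees and
    Phylogenetic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Visualize large gene families compactly by linking a
    reconciled gene tree, its species tree and a matrix of phylogenetic
    profiles.  Subtrees collapsed against the species tree are summarized
    as per-species gene copy-number rows (with loss-zeros and outgroup
    blanks) instead of being hidden, so the collapsed view stays
    information-equivalent to the full tree.  Includes readers for newick
    species trees, a documented JSON gene-family dialect and orthoXML,
    cached adapters for public family resources, a species-tree-guided
    collapse algebra (smart collapse, collapse-all, taxon collapse,
    auto-collapse at depth), exact-rational profile computation with
    in-paralog averaging, deterministic SVG/HTML rendering, a birth-death
    family simulator with ground-truth event logs, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
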