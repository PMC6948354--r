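Package: netpharm
Title: Network Pharmacology Screening of Herb-Component-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible network-pharmacology pipeline for multi-herb
    formulae: ADME screening of herbal components by oral bioavailability and
    drug-likeness with a literature-rescue whitelist, standardization of
    component targets to official gene symbols, intersection with disease gene
    sets to obtain putative therapeutic targets, construction of typed
    component-target and disease-mapping networks, a two-stage median-based
    degree/betweenness/closeness screen that nominates core targets on a
    protein-protein interaction graph, and hypergeometric over-representation
    analysis of GO and pathway collections with Benjamini-Hochberg false
    discovery rate control. Includes a ground-truthed synthetic study
    generator so the whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
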