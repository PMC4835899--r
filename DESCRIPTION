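Package: FdxBarrel
Title: Topology and Heme-Site Analysis of Ferredoxin Alpha+Beta Barrels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of eight-stranded alpha+beta
    barrels built from two ferredoxin-like (beta-alpha-beta-beta-alpha-beta)
    domains, the fold adopted by IsdG/MhuD heme oxygenases, aldoxime
    dehydratase, chlorite dismutase, DyP peroxidases and siroheme
    decarboxylase. From a PDB or mmCIF file the package assigns secondary
    structure from backbone hydrogen bonds, builds the strand-pairing graph
    and the cyclic strand order of the barrel, labels the two ferredoxin-like
    domains (beta1-alpha1-beta2-beta3-alpha2-beta4), classifies the barrel
    packing as Type-1 (beta2-beta4 inter-domain pairing) or Type-2
    (beta2-beta2/beta4-beta4), superposes domains under direct, 180-degree
    rotated and circularly permuted element correspondences, and locates and
    classifies heme/siroheme sites (proximal and distal axial residues, host
    element, domain-cleft versus barrel-cavity binding mode, porphyrin
    ruffling). A deterministic generator of idealized synthetic barrels with
    full ground truth makes every stage testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
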