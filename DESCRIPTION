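Package: miDomains
Title: Structural Fingerprints of Multi-Interface Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies and characterises protein domains that present
    several distinct binding sites (multi-interface domains) from
    multi-chain crystal structures. Provides structure filtering by
    resolution, chain length and biological-unit membership; clustering of
    near-identical chains by local sequence alignment; interface-residue
    detection at a heavy-atom distance cutoff with multiple-alignment
    position mapping and de-duplication; residue contact graphs from
    Delaunay tessellation intersected with a distance cutoff; mining of
    closed frequent labeled subgraphs as interface fingerprints; and
    statistics on fingerprint relations (cooperative pairs, distinctive
    sets, isomorphism counts with random-graph null p-values, assortativity
    comparisons). A synthetic-structure generator supports fully
    self-contained analyses and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
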