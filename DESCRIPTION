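Package: mitoarch
Title: Comparative Architecture and Composition Analysis of Insect Mitogenomes
Version: 0.1.0
Authors@R: person("Mito", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistics and structural comparisons for annotated insect
    mitochondrial genomes: base composition and AT/GC strand skews, codon
    usage and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code, start/stop codon tabulation with
    incomplete-stop detection, gene overlap and intergenic spacer accounting,
    gene-order comparison, control-region motif scanning (conserved motifs,
    poly-T stretches, microsatellite-like tandem repeats), and a lightweight
    distance-based (K2P + neighbor-joining) phylogeny module with
    Robinson-Foulds topology comparison. Includes a seeded synthetic
    mitogenome generator and a tree-based sequence evolution simulator so the
    whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
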