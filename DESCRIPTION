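Package: ClutchPhase
Title: Heterochromatin-Like Domain Census and Clutch-Level Flory-Huggins
    Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide survey of HP1/H3K9me3 co-localization from binned
    ChIP-seq fold-enrichment tracks, calling of heterochromatin-like
    domains and complexes outside constitutive heterochromatin with
    classification into three size classes, and a thermodynamic treatment
    of their micro-phase separation from euchromatin. The thermodynamics
    covers the Flory-Huggins interaction parameter chi at several levels
    (incompressible-lattice contact energies, dispersive van der Waals
    interactions, the empirical temperature form, and a nucleosome-clutch
    decomposition for bridged chromatin), the segregation product chi*N,
    the random-phase-approximation spinodal of a diblock copolymer
    (order-disorder threshold about 10.5 at symmetric composition),
    lamellar composition profiles in the weak and strong segregation
    regimes, and a loop-extrusion mixing model. A synthetic track
    generator with planted ground truth makes the genomic pipeline
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
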