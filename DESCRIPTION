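Package: nucarray
Title: Geometry, Statistics and Coarse-Grained Simulation of Nucleosome Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-particle geometric analysis of nucleosome array models given as
    base-pair helical-center traces with nucleosome core particle (NCP) placements:
    detection of the wrapped DNA interval against an ideal superhelical path (8 Angstrom
    overlap criterion), NCP coordinate-frame fitting, linker-arm angles (theta and its
    planar projections, wrapping angle alpha, bending angle beta), unwrapping footprints,
    inter-NCP distances and discoidal-plane dihedrals, and a linker-length
    self-consistency check. Companion statistics (Gaussian-mixture and kernel-density
    fits, two-state Boltzmann energy gaps, a Kolmogorov-Smirnov test against the
    random-plane sine null), Kabsch-RMSD single-linkage conformational classification, a
    sequential-assembly coarse-grained chromatin fiber simulator with worm-like-chain
    persistence-length and radius-of-gyration analysis, a condensate density estimator,
    and a synthetic-array generator with presets matching published per-condition
    distribution statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    ape,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
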