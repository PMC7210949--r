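Package: coreceptor
Title: Integrative Analysis of Auxin Co-Receptor Assembly Constrained by
    Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying how intrinsically disordered
    regions flanking the AUX/IAA degron position AUX/IAA repressors on the
    TIR1 F-box protein. Segments AUX/IAA sequences into DI, linker, core
    degron, degron tail and PB1 modules; classifies per-residue disorder and
    computes Kyte-Doolittle hydropathy; calibrates size-exclusion
    chromatography and classifies hydrodynamic fold classes from Stokes
    radii; fits one-site total plus nonspecific saturation radioligand
    binding curves for auxin dissociation constants; filters replicated
    crosslinking mass-spectrometry tables and derives distance restraints,
    including a polymer-scaling restraint for the disordered degron tail;
    scans the accessible interaction space of a rigid ligand body around a
    receptor under distance restraints; and post-processes MM-GBSA effective
    binding free-energy trajectories and per-residue decompositions
    (accumulated means, hot-spot calling, computational alanine scanning).
    Includes seeded synthetic-data generators with planted ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    seqinr,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
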