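Package: metcof
Title: Metal Cofactor Inference for Nitrogenase D-Subunit Homologs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers the active-site metal cofactor (FeMo-co, FeV-co or
    FeFe-co) of nitrogenase D-subunit homologs from structure and sequence.
    Provides cofactor-shell residue extraction and motif-region grouping,
    grid-based active-site pocket volumetrics with a solvent probe,
    contact-set structural similarity with complete-linkage dendrograms,
    alignment-guided Kabsch superposition, a position-specific motif
    fingerprint classifier over the conserved active-site sequence areas of
    NifD, VnfD and AnfD, synthetic fixture generators, and a pipeline that
    combines the three evidence lines into a per-query cofactor call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
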