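Package: famdev
Title: Residue-Level Biophysical Deviation of a Protein from Its Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and localizes how a reference protein differs from a
    family of homologous proteins with respect to amino-acid biophysical
    index scales (AAindex), accounting for family conservation and for
    3D proximity between residues. Computes per-residue, per-characteristic
    deviation z-scores ("c-scores") from a multiple sequence alignment,
    derives representative property scales per characteristic class by
    principal components, extracts C-alpha geometry from PDB structures to
    link sequence deviations to spatial neighbourhoods (proximity chords),
    and exports a schema-described JSON bundle for visualization front-ends.
    Includes synthetic-data generators (families with implanted anomalous
    regions, correlated index scales, C-alpha traces) so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
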