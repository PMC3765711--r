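Package: lig2d
Title: 2D Diagrams of Biomacromolecule-Ligand Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic generation of two-dimensional diagrams of the
    interactions between a ligand and its biomacromolecular environment from
    PDB coordinate files. Ligands and metal ions are detected directly from
    HETATM, LINK and CONECT records; bond orders are mapped from chemical
    component definitions; the ligand is partitioned into rings (smallest set
    of smallest rings), chains, isolated and terminal atoms and laid out in
    2D with 120-degree chain angles and regular-polygon rings, with special
    handling of macro-cycles; hydrogen bonds, water-mediated hydrogen-bond
    paths and nearby residues are detected with geometric criteria and placed
    around the ligand by rotational search; diagrams are exported as SVG or
    PNG and interaction lists as flat text. A synthetic-fixture generator
    produces small test structures with controlled geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    png,
    jsonlite,
    bio3d,
    withr
Config/testthat/edition: 3
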