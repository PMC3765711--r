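# lig2d — 2D diagrams of biomacromolecule–ligand interactions

Structural biologists routinely summarise a 3D protein–ligand complex as a
flat schematic: the ligand drawn with clean chemical geometry, hydrogen
bonds as annotated lines, contacting residues as labelled ovals,
water-mediated bridges on request. `lig2d` generates such diagrams
directly from PDB coordinate files, with no manual intervention: it
detects ligands and metal ions, computes 2D coordinates, detects the
interactions geometrically, arranges everything to minimise visual
clutter, and writes SVG/PNG plus a flat-text interaction list.

## Method at a glance

* **Ligand detection.** Non-water HETATM residues; residues joined by
  LINK/CONECT records or heavy-atom pairs at covalent distance merge into
  composite ligands (cyclic peptides and other multi-residue ligands come
  out whole); single metal atoms are metal-ion ligands; polymer residues
  LINKed to the ligand become *explicit residues* drawn alongside it.
  User-specified residue ranges are supported (`select_composite()`).
* **2D layout.** The ligand graph (bond orders mapped in from
  chemical-component definitions) is partitioned into rings — the
  smallest set of smallest rings, i.e. a minimal cycle basis — chains,
  isolated and terminal atoms. Chains are drawn as 120° zigzags, rings as
  regular polygons (central angle 360°/*n*), macro-cycles (≥ 10 atoms)
  first as one large polygon. Clashes — non-bonded atoms closer than
  0.4 Å — are removed by flipping acyclic torsions (0 → 180°) whenever a
  flip strictly reduces the conflict count.
* **Interactions.** Nearby residues have ≥ 1 heavy atom within 4 Å
  (default) of the ligand. A hydrogen bond joins a donor D and acceptor A
  within 3.3 Å when some acceptor neighbour *aa* gives angle(D, A, aa)
  < 90°. Water bridges are simple paths of 1–4 water oxygens between
  ligand and residue donor/acceptor atoms with every step ≤ 3.3 Å.
* **Placement.** Each interacting element sits on a circle of radius
  equal to its real 3D distance, evaluated every 5° (72 candidates):
  fewest bond crossings wins, ties by fewest < 0.4 Å contacts. Hydrogen
  bonds are placed first, then residue ovals, then water bridges.
  Residue names go on a circle of radius max(distance(centroid, atom)) +
  0.5 Å, evaluated every 10°, minimising elements within 2 Å.

All searches start from seeded random angles, so output is reproducible
byte for byte for a fixed seed.

## Worked example

The package ships a synthetic-fixture generator, so the example needs no
downloads: a small carbonyl probe ligand with one shell residue at
exactly 3.9 Å, one donor at 3.0 Å / 60°, and a one-water bridge.

```r
library(lig2d)

fx <- make_site(shells = list(list(res = "ALA", dist = 3.9)),
                waters = 1L, hbonds = list(c(3.0, 60)))
comps <- lapply(fx$components, parse_component)

detect_ligands(parse_pdb(fx$pdb))[[1]]
#> <ligand_instance> PRB L1 (3 atoms)

scene <- draw_diagram(fx$struct, comps, include_waters = TRUE)
scene
#> <lig2d_scene> 3 atoms, 5 placed elements (1 hbond_partner, 2 residue_oval,
#>   2 water_bridge), 1 labels

cat(export_interactions(scene$interactions, scene$struct))
#> type	ligand_atom	partner	chain	distance
#> hbond	O1	DNR2:N	A	3.00
#> nearby_residue	C1	DNR2	A	2.61
#> nearby_residue	O1	ALA1	A	3.90
#> water_bridge	O1	SER3 (1 H2O)	A	3.00,3.00 (total 6.00)
#> water_bridge	O1	ALA1 (1 H2O)	A	3.00,2.61 (total 5.61)

writeLines(render_svg(scene), "site.svg")
```

Reading the table: the environment donor N of residue `DNR 2` hydrogen
bonds to the ligand carbonyl `O1` at 3.00 Å (the 60° acceptor-neighbour
angle passes the < 90° test); `ALA 1`'s closest heavy atom sits at
exactly the requested 3.90 Å, inside the 4 Å cutoff; the designed
one-water bridge reaches `SER 3` in two 3.00 Å steps (a second,
incidental one-water path to `ALA 1` is also found — the search reports
every qualifying path).

### Command line

```sh
inst/cli/lig2d list site.pdb
inst/cli/lig2d draw site.pdb --ligand L:1 --components defs/ --waters \
    --color-scheme charge --arrows --distances --out site.svg
inst/cli/lig2d interactions site.pdb --components defs/ --out site.txt
inst/cli/lig2d fixtures --kind macrocycle --out fixtures/
```

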