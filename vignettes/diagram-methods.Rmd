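---
title: "How lig2d builds a ligand-environment diagram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How lig2d builds a ligand-environment diagram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lig2d)
```

lig2d turns a PDB entry into a 2D diagram of a ligand and the residues,
hydrogen bonds and water-mediated contacts around it. This vignette is the
package's own account of the method: what each stage computes, which
constants drive it, and where we had to make choices the problem statement
leaves open.

## The pipeline

1. **Parse** the PDB file (ATOM/HETATM/LINK/CONECT/HELIX/SHEET) and, per
   residue name, a chemical-component definition supplying bond orders.
2. **Detect ligands**: non-water HETATM residues, merged into composites
   through LINK/CONECT records or heavy-atom pairs at covalent distance;
   single metal atoms are metal-ion ligands; polymer residues LINKed to the
   ligand are *explicit residues*.
3. **Build the molecular graph** and partition it into structural elements:
   rings (the smallest set of smallest rings), chains of at least three
   connected non-terminal C/N/O/S atoms, terminal atoms (degree 1) and
   isolated atoms.
4. **Lay out** the ligand in 2D, then resolve clashes by torsion flips and
   attach explicit residues.
5. **Detect and place interactions**, then **place residue-name labels**.
6. **Render** to SVG (canonical) or PNG, or export the interaction list as
   flat text.

## Ligand layout

The ligand is drawn element by element, starting from the macro-cycle if
there is one, otherwise the longest chain, otherwise the largest ring. A
depth-first walk then places every atom next to its already-placed
neighbours:

* interior chain angles are exactly 120 degrees (a zigzag alternating +60
  and -60 degree turns);
* each ring is a regular polygon whose central angle is 360/n; a ring
  reached through a bond is anchored at its entry atom and grows away from
  the placed neighbourhood; a ring fused along an edge keeps that edge as
  one polygon side;
* acyclic bonds are drawn at a fixed 2D bond length of 1.5 angstrom. The
  constant is drawing convention, not physics; it keeps the 0.4 angstrom
  conflict threshold meaningful relative to bond spacing;
* when no atom of an element is fixed yet, its orientation comes from the
  orthographic projection of the 3D coordinates onto their least-squares
  plane (computed by SVD), so the diagram inherits the pose of the crystal
  structure;
* atoms with two or more placed neighbours take the bisector of the
  largest angular gap, which pushes substituents radially away from rings.

Macro-cycles (rings of 10 atoms or more) are drawn first as one large
regular polygon so the cyclic backbone stays readable; smaller fused rings
and the other elements are added afterwards. The threshold of 10 is a
drawing choice: common small rings have up to 8 atoms, cyclic-peptide
backbones far more.

### Ring perception

The smallest set of smallest rings is computed as a minimal cycle basis:
candidate cycles are assembled from per-vertex shortest-path trees (each
candidate is two shortest paths plus one closing edge), then selected
greedily in order of length under GF(2) independence. We preferred this
construction over ad-hoc smallest-ring extraction because it is exact and
easy to verify: the suite checks |SSSR| = E − V + C on every fixture and
compares the basis against brute-force cycle enumeration on graphs of up
to 14 atoms. Ties are broken by member atom serials, making the output
deterministic.

### Conflict resolution

Two non-bonded atoms closer than **0.4 angstrom** in 2D are a conflict.
Every acyclic bond is a candidate torsion: flipping it 0 to 180 degrees is
realised in 2D as reflecting the smaller branch across the bond axis. A
flip is kept only when the total conflict count strictly decreases —
strictness plus a pass limit of 10 guarantees termination, and the suite
property-checks that resolution never increases the conflict count.
Ring-internal bonds are never flipped.

### Explicit residues

A LINKed residue is laid out independently by the same algorithm, then
rigid-body placed so its anchor atom sits on the circle whose radius is
the real 3D anchor distance. Candidates every **10 degrees** (36 in all)
from a seeded random start are scored by bond crossings plus atom
overlaps against the ligand; the minimum wins, ties by candidate index.

## Interaction detection

All criteria operate on heavy atoms; hydrogens in coordinates are parsed
but ignored, since the geometric criteria are defined on heavy atoms.

| parameter | default | meaning |
|---|---|---|
| `residue_cutoff` | 4.0 A | nearby residue: ≥ 1 heavy atom within this of any ligand atom |
| `hbond_cutoff` | 3.3 A | maximum donor-acceptor distance |
| `hbond_angle_max` | 90 deg | a bond needs some acceptor neighbour aa with angle(D,A,aa) below this |
| `water_radius` | 3.3 A | maximum step along a water-mediated path |
| `max_bridge_waters` | 4 | longest admissible water chain |

The donor-acceptor distance cutoff is configurable and defaults to the
water radius, 3.3 angstrom, for consistency between the direct and
water-mediated criteria.

Donor/acceptor typing reads the component definition: an O with a bonded
hydrogen is donor and acceptor, any other O is acceptor only (carbonyl,
carboxylate, ether); an N with a bonded hydrogen is a donor, an N without
one an acceptor; S is included as a weak donor and acceptor. When a
residue has no definition, or its definition carries no hydrogens at all,
N and O are typed permissively as both — detection degrades gracefully
rather than silently dropping contacts.

The angle criterion is existential: the pair is accepted if *some*
covalent neighbour of the acceptor passes, and the smallest-angle
neighbour is recorded. We apply it symmetrically whichever side donates.
Two edge cases are decided here: an acceptor with no covalent neighbour
at all (an ion) passes vacuously, and each unordered atom pair is
reported once, keeping the direction with the smaller neighbour angle.

Water-mediated paths are simple paths (no water revisited) of one to four
water oxygens between a ligand donor/acceptor and a residue
donor/acceptor, every step within the water radius, enumerated by
depth-limited search over the water contact graph.

## Placing interactions and text

Each interacting element is placed on the circle around its ligand anchor
whose radius is the **real 3D distance**, evaluated every **5 degrees**
(72 candidates) from a seeded random start. The best candidate minimises
bond crossings with everything already drawn; ties fall to the fewest
close contacts (< 0.4 angstrom), then to candidate order. Hydrogen bonds
are placed first (lines cross most easily), then residue ovals, then —
only on request — water bridges, each new element treating its
predecessors as immovable obstacles. A residue that hydrogen-bonds to the
ligand is drawn once, at its bond partner's position. Ovals are
approximated as 1.2-angstrom circles for scoring; crossing tests are
standard segment intersection with shared endpoints not counted.

Residue names are placed on the circle centred at the residue's 2D
centroid with radius max(distance(centroid, atom)) + 0.5 angstrom,
evaluated every **10 degrees** (36 candidates); the score is the number of
diagram elements within **2 angstrom** of the candidate.

Every "random" start angle is drawn from a seeded stream
(`layout_config(seed = )`), so a fixed input and seed reproduce the
diagram byte for byte — the SVG writer emits deterministic text for
exactly this reason.

## What the synthetic fixtures do and do not show

The package bundles a generator (`make_ligand()`, `make_site()`) that
builds small ligands (chains, rings, fused rings, LINKed macrocycles) and
binding-site environments in which every requested geometric feature is
realised exactly: shell residues at a stated minimum distance, donors at a
stated distance and acceptor-neighbour angle, water chains with stated
step lengths. The generator validates its own output and refuses requests
it cannot realise. Pseudo-residues carry 3-5 heavy atoms — positions,
names and donor/acceptor elements are all the geometric criteria need.

Two caveats. First, PDB text stores coordinates to 3 decimals, so
geometry re-read from the emitted *text* is quantized to about 1e-3
angstrom; the generator therefore also returns its full-precision
structure (`fx$struct`), which the self-consistency checks and threshold
measurements use. Second, passing on these fixtures demonstrates the
geometric criteria and search behaviour, not robustness to everything in
real crystallographic data: altloc-rich entries, chain breaks, unusual
het-group nomenclature and very large ligands are exercised only to the
extent the parser tests cover them.

Test problem sizes are deliberately small — ligands of 3 to 30 atoms,
sites of under 50 atoms, brute-force oracles on graphs of at most 14
atoms and flip spaces of at most 2^6 — chosen so each oracle is
exhaustively checkable.

## Other decisions and limitations

* Only MODEL 1 of multi-model files is read, and only the first alternate
  location per atom; NMR ensembles and occupancy-weighted alternates are
  out of scope.
* Element symbols missing from columns 77-78 are inferred from the atom
  name (two-letter metals recognised by position in the name field).
* Modified polymer residues (HETATM inside a polymer chain's numbering
  span) are not auto-detected as ligands; select them explicitly with
  `select_composite()`.
* PDBSum-style merging is approximated by LINK/CONECT plus a covalent
  distance rule (< 1.9 angstrom heavy-heavy, 2.4 when sulfur is
  involved).
* A residue atom renamed relative to its component definition is
  recovered by element-labelled subgraph isomorphism against the
  distance-inferred residue graph; if that fails the residue falls back
  to distance bonds with single orders.
* Rendering: SVG is the single geometry source of truth; PNG draws the
  same scene through the R graphics device. Other raster/vector formats
  are left to external converters. Colours approximate the conventional
  schemes (hydrophobicity, Shapely-like amino-acid colours, charge,
  secondary structure) and every scheme is total over residue names with
  a fallback; all colours are overridable.
* No hydrophobic-contact spokes, pi-stacking or salt-bridge
  special-casing: the interaction vocabulary is hydrogen bonds, nearby
  residues and water bridges.
* Whether single heavy-atom ring substituents are "terminal" or
  "isolated" is resolved by degree: degree 1 means terminal.

## A worked example

```{r example}
fx <- make_site(shells = list(list(res = "ALA", dist = 3.9)),
                waters = 1L, hbonds = list(c(3.0, 60)))
comps <- lapply(fx$components, parse_component)
scene <- draw_diagram(fx$struct, comps, include_waters = TRUE)
scene
cat(export_interactions(scene$interactions, scene$struct))
```
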