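test_that("ring fixture parses to the expected atoms and records", {
  fx <- make_ligand("ring", n = 6)
  s <- parse_pdb(fx$pdb)
  expect_equal(nrow(s$atoms), 6)
  expect_equal(nrow(s$links), 0)
  expect_true(all(s$atoms$is_het))
  expect_true(all(s$atoms$element == "C"))
  expect_false(any(s$atoms$is_water))
})

test_that("LINK records parse and resolve to atoms", {
  fx <- make_site(covalent_link = TRUE)
  s <- parse_pdb(fx$pdb)
  expect_equal(nrow(s$links), 1)
  l <- s$links[1, ]
  expect_equal(l$name1, "C2")
  expect_equal(l$res_name2, "CYS")
  # both endpoints resolve to existing atoms
  expect_true(any(s$atoms$name == l$name1 & s$atoms$chain == l$chain1 &
                    s$atoms$res_seq == l$res_seq1))
  expect_true(any(s$atoms$name == l$name2 & s$atoms$chain == l$chain2 &
                    s$atoms$res_seq == l$res_seq2))
})

test_that("first alternate location is kept, the rest dropped", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00 10.00           C",
    sep = "\n")
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atoms), 2)
  kept <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(kept$alt_loc, "A")
  expect_equal(kept$x, 0)
})

test_that("only the first model of a multi-model file is read", {
  body1 <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C"
  body2 <- "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00 10.00           C"
  txt <- paste("MODEL        1", body1, "ENDMDL",
               "MODEL        2", body2, "ENDMDL", sep = "\n")
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 0)
})

test_that("round-trip through PDB text preserves atoms to format precision", {
  fx <- make_site(shells = list(list(res = "ALA", dist = 3.9)),
                  waters = 2L, covalent_link = TRUE)
  s1 <- parse_pdb(fx$pdb)
  s2 <- parse_pdb(write_pdb(s1))
  expect_equal(s2$atoms$name, s1$atoms$name)
  expect_equal(s2$atoms$element, s1$atoms$element)
  expect_equal(s2$atoms$res_name, s1$atoms$res_name)
  expect_equal(round(s2$atoms$x, 3), round(s1$atoms$x, 3))
  expect_equal(round(s2$atoms$y, 3), round(s1$atoms$y, 3))
  expect_equal(round(s2$atoms$z, 3), round(s1$atoms$z, 3))
  expect_equal(nrow(s2$links), nrow(s1$links))
})

test_that("CONECT adjacency is symmetric", {
  txt <- paste(
    "HETATM    1  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  LIG L   1       1.500   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C3  LIG L   1       3.000   0.000   0.000  1.00  0.00           C",
    "CONECT    1    2",
    "CONECT    2    1    3",
    sep = "\n")
  s <- parse_pdb(txt)
  m <- s$conect
  for (r in seq_len(nrow(m))) {
    expect_true(any(m[, 1] == m[r, 2] & m[, 2] == m[r, 1]))
  }
  # 1-2 appears once per direction, 2-3 symmetrised even though only one way
  expect_equal(nrow(m), 4)
})

test_that("element inference from atom names follows PDB conventions", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00",
    "HETATM    2 FE   HEM A   2       5.000   0.000   0.000  1.00 10.00",
    "HETATM    3  OXT LIG L   3      10.000   0.000   0.000  1.00 10.00",
    "HETATM    4 CA    CA A   4      15.000   0.000   0.000  1.00 10.00",
    sep = "\n")
  s <- parse_pdb(txt)
  expect_equal(s$atoms$element, c("C", "FE", "O", "CA"))
})

test_that("malformed records warn with line numbers; empty input is fatal", {
  txt <- paste(
    "HETATM    1  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    X  C2  LIG L   1       bad     0.000   0.000  1.00  0.00           C",
    sep = "\n")
  expect_warning(s <- parse_pdb(txt), "line")
  expect_equal(nrow(s$atoms), 1)
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM or HETATM")
})

test_that("coordinates agree with an independent PDB reader", {
  fx <- make_ligand("fused_rings")
  tmp <- tempfile(fileext = ".pdb")
  writeLines(fx$pdb, tmp)
  s <- parse_pdb(fx$pdb)
  ref <- bio3d::read.pdb(tmp)
  expect_equal(nrow(s$atoms), nrow(ref$atom))
  expect_equal(s$atoms$x, ref$atom$x, tolerance = 1e-9)
  expect_equal(s$atoms$y, ref$atom$y, tolerance = 1e-9)
  expect_equal(s$atoms$name, ref$atom$elety)
})

test_that("component definitions parse atoms, bonds and orders", {
  fx <- make_ligand("ring", n = 6)
  cd <- parse_component(fx$components$RNG)
  expect_equal(cd$comp_id, "RNG")
  expect_equal(nrow(cd$bonds), 6)
  expect_true(all(cd$bonds$order == "aromatic"))

  fxs <- make_site()
  prb <- parse_component(fxs$components$PRB)
  co <- prb$bonds[prb$bonds$a2 == "O1" | prb$bonds$a1 == "O1", ]
  expect_equal(co$order, "double")

  metal_txt <- paste("data_ZN", "_chem_comp.id ZN", "loop_",
                     "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
                     "_chem_comp_atom.type_symbol", "ZN ZN ZN", sep = "\n")
  zn <- parse_component(metal_txt)
  expect_equal(nrow(zn$bonds), 0)
  expect_equal(zn$atoms$element, "ZN")

  bad <- paste("data_BAD", "loop_", "_chem_comp_atom.comp_id",
               "_chem_comp_atom.atom_id", "_chem_comp_atom.type_symbol",
               "BAD C1 C", "loop_", "_chem_comp_bond.comp_id",
               "_chem_comp_bond.atom_id_1", "_chem_comp_bond.atom_id_2",
               "_chem_comp_bond.value_order", "BAD C1 C9 SING", sep = "\n")
  expect_error(parse_component(bad), "undefined atom")
})

test_that("component directories load keyed by component id", {
  d <- withr::local_tempdir()
  fx <- make_ligand("ring", n = 6)
  writeLines(fx$components$RNG, file.path(d, "RNG.cif"))
  fx2 <- make_site()
  writeLines(fx2$components$PRB, file.path(d, "PRB.cif"))
  defs <- read_component_dir(d)
  expect_setequal(names(defs), c("RNG", "PRB"))
  expect_s3_class(defs$RNG, "component_def")
})
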