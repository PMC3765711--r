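site_fx <- make_site(shells = list(list(res = "ALA", dist = 3.9),
                                   list(res = "SER", dist = 4.1)),
                     waters = c(1L, 2L, 3L, 4L, 5L, 6L),
                     hbonds = list(c(3.0, 60), c(3.0, 120)))
site_s <- site_fx$struct
site_lig <- detect_ligands(site_s)[[1]]
site_comps <- parsed_components(site_fx)

shell_dist <- function(nb, info) {
  hit <- nb[nb$chain == info$chain & nb$res_seq == info$res_seq, ]
  if (nrow(hit)) hit$min_distance else NA_real_
}

test_that("nearby residues respect the 4 angstrom default cutoff", {
  nb <- find_nearby_residues(site_lig, site_s)
  sh <- site_fx$info$shell_residues
  expect_equal(shell_dist(nb, sh[[1]]), 3.9, tolerance = 1e-9)
  expect_true(is.na(shell_dist(nb, sh[[2]])))
  # raising the cutoff admits the second shell
  nb45 <- find_nearby_residues(site_lig, site_s,
                               interaction_config(residue_cutoff = 4.5))
  expect_equal(shell_dist(nb45, sh[[2]]), 4.1, tolerance = 1e-9)
  # sorted by distance
  expect_false(is.unsorted(nb$min_distance))
})

test_that("an empty environment yields an empty nearby list", {
  fx <- make_ligand("ring", n = 6)
  lig <- detect_ligands(fx$struct)[[1]]
  expect_equal(nrow(find_nearby_residues(lig, fx$struct)), 0)
})

test_that("nearby detection is monotone in the cutoff", {
  keys <- function(nb) paste(nb$chain, nb$res_seq)
  prev <- character()
  for (cutoff in c(2, 3, 4, 5, 6)) {
    nb <- find_nearby_residues(site_lig, site_s,
                               interaction_config(residue_cutoff = cutoff))
    expect_true(all(prev %in% keys(nb)))
    prev <- keys(nb)
  }
})

test_that("donor/acceptor typing follows the component hydrogen rule", {
  # carbonyl O (double bond to C, no H): acceptor only
  fl <- assign_donors_acceptors(site_s, site_lig$atom_idx, site_comps)
  o1 <- fl[site_s$atoms$name[fl$row] == "O1", ]
  expect_false(o1$is_donor)
  expect_true(o1$is_acceptor)
  # aliphatic C: neither
  c1 <- fl[site_s$atoms$name[fl$row] == "C1", ]
  expect_false(c1$is_donor || c1$is_acceptor)

  # hydroxyl-style O and amide/imine N via a hand-written definition
  txt <- paste("data_TST", "loop_", "_chem_comp_atom.comp_id",
               "_chem_comp_atom.atom_id", "_chem_comp_atom.type_symbol",
               "TST O1 O", "TST HO1 H", "TST N1 N", "TST HN1 H", "TST N2 N",
               "loop_", "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
               "_chem_comp_bond.atom_id_2", "_chem_comp_bond.value_order",
               "TST O1 HO1 SING", "TST N1 HN1 SING", sep = "\n")
  comp <- parse_component(txt)
  s <- parse_pdb(paste(
    "HETATM    1  O1  TST L   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  N1  TST L   1       2.000   0.000   0.000  1.00  0.00           N",
    "HETATM    3  N2  TST L   1       4.000   0.000   0.000  1.00  0.00           N",
    sep = "\n"))
  fl <- assign_donors_acceptors(s, 1:3, list(TST = comp))
  expect_true(fl$is_donor[1] && fl$is_acceptor[1])    # O-H: both
  expect_true(fl$is_donor[2] && !fl$is_acceptor[2])   # N-H: donor
  expect_true(!fl$is_donor[3] && fl$is_acceptor[3])   # N without H: acceptor
  # without any definition: permissive
  fl0 <- assign_donors_acceptors(s, 1:3, list())
  expect_true(all(fl0$is_donor & fl0$is_acceptor))
})

test_that("hydrogen bonds require the acceptor-neighbour angle under 90", {
  hb <- find_hydrogen_bonds(site_lig, site_s, components = site_comps)
  dn <- site_fx$info$donor_residues
  hit_for <- function(info) {
    rows <- which(site_s$atoms$chain == info$chain &
                    site_s$atoms$res_seq == info$res_seq)
    hb[hb$donor_row %in% rows | hb$acceptor_row %in% rows, ]
  }
  ok60 <- hit_for(dn[[1]])
  expect_equal(nrow(ok60), 1)
  expect_equal(ok60$distance, 3.0, tolerance = 1e-9)
  expect_equal(ok60$angle, 60, tolerance = 1e-6)
  expect_false(ok60$ligand_is_donor)
  expect_equal(nrow(hit_for(dn[[2]])), 0)  # 120 degrees: rejected
})

test_that("hydrogen bonds respect the distance cutoff", {
  fx <- make_site(hbonds = list(c(3.5, 60)))
  lig <- detect_ligands(fx$struct)[[1]]
  hb <- find_hydrogen_bonds(lig, fx$struct, components = parsed_components(fx))
  expect_equal(nrow(hb), 0)
  hb2 <- find_hydrogen_bonds(lig, fx$struct,
                             interaction_config(hbond_cutoff = 3.6),
                             components = parsed_components(fx))
  expect_equal(nrow(hb2), 1)
})

test_that("water bridges span 1 to 4 waters and respect the water radius", {
  br <- find_water_bridges(site_lig, site_s, components = site_comps)
  for (info in site_fx$info$bridge_residues) {
    hits <- br[br$chain == info$chain & br$res_seq == info$res_seq, ]
    if (info$n_waters <= 4) {
      expect_true(info$n_waters %in% hits$n_waters)
    } else {
      expect_equal(nrow(hits), 0)
    }
  }
  # a first leg over 3.3 angstrom excludes the water
  fx <- make_site(waters = 1L, water_first_leg = 3.4)
  lig <- detect_ligands(fx$struct)[[1]]
  expect_equal(nrow(find_water_bridges(lig, fx$struct,
                                       components = parsed_components(fx))), 0)
  fx2 <- make_site(waters = 1L, water_first_leg = 3.2)
  lig2 <- detect_ligands(fx2$struct)[[1]]
  br2 <- find_water_bridges(lig2, fx2$struct, components = parsed_components(fx2))
  expect_gte(nrow(br2), 1)
})

test_that("reported distances equal independent 3D recomputation", {
  a <- site_s$atoms
  hb <- find_hydrogen_bonds(site_lig, site_s, components = site_comps)
  for (i in seq_len(nrow(hb))) {
    d <- sqrt(sum((a[hb$donor_row[i], c("x", "y", "z")] -
                     a[hb$acceptor_row[i], c("x", "y", "z")])^2))
    expect_equal(hb$distance[i], d, tolerance = 1e-9)
  }
  br <- find_water_bridges(site_lig, site_s, components = site_comps)
  for (i in seq_len(nrow(br))) {
    nodes <- c(br$lig_row[i], br$water_rows[[i]], br$res_row[i])
    steps <- vapply(seq_len(length(nodes) - 1L), function(m) {
      sqrt(sum((a[nodes[m], c("x", "y", "z")] - a[nodes[m + 1], c("x", "y", "z")])^2))
    }, 0)
    expect_equal(br$step_distances[[i]], steps, tolerance = 1e-9)
    expect_true(all(steps <= 3.3 + 1e-12))
  }
})

test_that("no interaction involves a hydrogen or a water endpoint", {
  a <- site_s$atoms
  hb <- find_hydrogen_bonds(site_lig, site_s, components = site_comps)
  rows <- c(hb$donor_row, hb$acceptor_row)
  nb <- find_nearby_residues(site_lig, site_s)
  rows <- c(rows, nb$lig_row, nb$res_row)
  br <- find_water_bridges(site_lig, site_s, components = site_comps)
  rows <- c(rows, br$lig_row, br$res_row)
  expect_false(any(a$element[rows] == "H"))
  expect_false(any(a$is_water[rows]))
})

test_that("detection matches the brute-force enumerator on a small site", {
  fx <- make_site(shells = list(list(res = "ALA", dist = 3.7)),
                  waters = c(1L, 2L), hbonds = list(c(3.1, 45)))
  s <- fx$struct
  lig <- detect_ligands(s)[[1]]
  comps <- parsed_components(fx)

  nb <- find_nearby_residues(lig, s)
  onb <- oracle_nearby(s, lig$atom_idx)
  expect_setequal(paste(nb$chain, nb$res_seq, sep = "|"), names(onb))
  for (i in seq_len(nrow(nb))) {
    expect_equal(nb$min_distance[i],
                 onb[[paste(nb$chain[i], nb$res_seq[i], sep = "|")]],
                 tolerance = 1e-12)
  }

  hb <- find_hydrogen_bonds(lig, s, components = comps)
  ohb <- oracle_hbonds(s, lig$atom_idx, comps)
  expect_setequal(paste(pmin(hb$donor_row, hb$acceptor_row),
                        pmax(hb$donor_row, hb$acceptor_row)), names(ohb))

  br <- find_water_bridges(lig, s, components = comps)
  obr <- oracle_bridges(s, lig$atom_idx, comps)
  got <- sort(paste(br$lig_row,
                    vapply(br$water_rows, paste, "", collapse = ","),
                    br$res_row))
  expect_equal(got, obr)
})
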