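scene_fx <- make_site(shells = list(list(res = "ALA", dist = 3.9)),
                      waters = c(1L, 2L), hbonds = list(c(3.0, 60)))

build_scene <- function(fx = scene_fx, include_waters = TRUE, seed = 0L) {
  s <- fx$struct
  comps <- parsed_components(fx)
  lig <- detect_ligands(s)[[1]]
  g <- build_graph(lig, s, comps)
  lay <- resolve_conflicts(layout_ligand(g, NULL, layout_config(seed = seed)))
  ints <- detect_interactions(lig, s, components = comps, graph = g)
  place_interactions(lay, ints, s, layout_config(seed = seed),
                     include_waters = include_waters)
}

test_that("hydrogen bonds are placed before ovals, ovals before bridges", {
  sc <- build_scene()
  kinds <- vapply(sc$placed, `[[`, "", "kind")
  rank <- match(kinds, c("hbond_partner", "residue_oval", "water_bridge"))
  expect_false(is.unsorted(rank))
  expect_true(all(c("hbond_partner", "residue_oval", "water_bridge") %in% kinds))
})

test_that("placed elements sit exactly on their real-3D-distance circles", {
  sc <- build_scene()
  for (el in sc$placed) {
    if (el$kind == "water_bridge" || isTRUE(el$via_hbond)) next
    d <- sqrt(sum((el$position - el$anchor)^2))
    expect_equal(d, el$radius, tolerance = 1e-9)
  }
  # water bridge nodes: every searched step at its 3D step distance
  wb <- Filter(function(e) e$kind == "water_bridge", sc$placed)
  for (el in wb) {
    prev <- el$anchor
    for (s in seq_along(el$node_pos)) {
      # the final node may reuse an existing oval position
      if (s == length(el$node_pos)) break
      d <- sqrt(sum((el$node_pos[[s]] - prev)^2))
      expect_equal(d, el$step_distances[s], tolerance = 1e-9)
      prev <- el$node_pos[[s]]
    }
  }
})

test_that("interaction search scans 72 candidates 5 degrees apart", {
  sc <- build_scene()
  el <- sc$placed[[1]]
  expect_equal(nrow(el$trace), 72)
  diffs <- diff(el$trace$angle) %% 360
  expect_true(all(abs(diffs - 5) < 1e-9))
})

test_that("the chosen position is the lexicographic optimum of its candidates", {
  sc <- build_scene()
  for (el in sc$placed) {
    if (is.null(el$trace)) next
    tr <- el$trace
    best <- order(tr$crossings, tr$contacts)[1]
    expect_equal(el$score[1], tr$crossings[best])
    expect_equal(el$score[2], tr$contacts[best])
  }
})

test_that("an uncluttered single hydrogen bond places with zero crossings", {
  fx <- make_site(hbonds = list(c(3.0, 60)))
  s <- fx$struct
  lig <- detect_ligands(s)[[1]]
  g <- build_graph(lig, s, parsed_components(fx))
  lay <- layout_ligand(g)
  ints <- detect_interactions(lig, s, components = parsed_components(fx), graph = g)
  sc <- place_interactions(lay, ints, s, layout_config())
  hb <- Filter(function(e) e$kind == "hbond_partner", sc$placed)
  expect_length(hb, 1)
  expect_equal(hb[[1]]$score[1], 0)
})

test_that("earlier elements are obstacles for later ones and never move", {
  sc <- build_scene()
  hb_before <- Filter(function(e) e$kind == "hbond_partner", sc$placed)
  # re-run with waters excluded: hbond and oval placements are identical
  sc2 <- build_scene(include_waters = FALSE)
  hb_after <- Filter(function(e) e$kind == "hbond_partner", sc2$placed)
  expect_equal(lapply(hb_before, `[[`, "position"),
               lapply(hb_after, `[[`, "position"))
  ov1 <- Filter(function(e) e$kind == "residue_oval", sc$placed)
  ov2 <- Filter(function(e) e$kind == "residue_oval", sc2$placed)
  expect_equal(lapply(ov1, `[[`, "position"), lapply(ov2, `[[`, "position"))
})

test_that("a residue with a hydrogen bond keeps a single unified depiction", {
  sc <- build_scene()
  hb <- Filter(function(e) e$kind == "hbond_partner", sc$placed)[[1]]
  ov <- Filter(function(e) e$kind == "residue_oval" && isTRUE(e$via_hbond),
               sc$placed)
  expect_length(ov, 1)
  expect_equal(ov[[1]]$position, hb$position)
})

test_that("labels search 36 candidates 10 degrees apart on the centroid circle", {
  sc <- place_labels(build_scene())
  expect_gte(length(sc$labels), 1)
  lb <- sc$labels[[1]]
  expect_equal(nrow(lb$trace), 36)
  diffs <- diff(lb$trace$angle) %% 360
  expect_true(all(abs(diffs - 10) < 1e-9))
  expect_equal(sqrt(sum((lb$position - lb$centroid)^2)), lb$radius,
               tolerance = 1e-9)
  expect_equal(lb$score, min(lb$trace$nearby))
})

test_that("label radius is max centroid distance plus half an angstrom", {
  # degenerate: single-atom residue -> radius exactly 0.5
  txt <- "HETATM    1 ZN    ZN A 401       0.000   0.000   0.000  1.00  0.00          ZN"
  s <- parse_pdb(txt)
  lig <- detect_ligands(s)[[1]]
  g <- build_graph(lig, s)
  lay <- layout_ligand(g)
  sc <- place_interactions(lay, detect_interactions(lig, s), s, layout_config())
  sc <- place_labels(sc)
  expect_equal(sc$labels[[1]]$radius, 0.5, tolerance = 1e-12)

  # residue spanning 2.0 angstrom from centroid -> radius 2.5
  g2 <- mk_graph(rbind(c(-2, 0, 0), c(2, 0, 0)), list(c(1L, 2L)))
  lay2 <- mk_layout(rbind(c(-2, 0), c(2, 0)), g2)
  sc2 <- structure(list(layout = lay2, placed = list(), struct = NULL,
                        config = layout_config()), class = "lig2d_scene")
  sc2 <- place_labels(sc2)
  expect_equal(sc2$labels[[1]]$radius, 2.5, tolerance = 1e-12)
})

test_that("the label scorer counts elements within 2 angstrom", {
  expect_equal(label_nearby_count(c(0, 0), rbind(c(1.9, 0))), 1)
  expect_equal(label_nearby_count(c(0, 0), rbind(c(2.1, 0))), 0)
  expect_equal(label_nearby_count(c(0, 0), rbind(c(1, 0), c(0, 1), c(3, 3))), 2)
  expect_equal(label_nearby_count(c(0, 0), NULL), 0)
})

test_that("scene assembly is deterministic under a fixed seed", {
  a <- place_labels(build_scene(seed = 11L))
  b <- place_labels(build_scene(seed = 11L))
  expect_equal(lapply(a$placed, `[[`, "position"),
               lapply(b$placed, `[[`, "position"))
  expect_equal(lapply(a$labels, `[[`, "position"),
               lapply(b$labels, `[[`, "position"))
  # and a different seed starts the search elsewhere
  c_ <- build_scene(seed = 99L)
  expect_false(identical(a$placed[[1]]$trace$angle[1],
                         c_$placed[[1]]$trace$angle[1]))
})
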