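layout_of <- function(fx, ...) {
  s <- fx$struct
  g <- build_graph(detect_ligands(s)[[1]], s, parsed_components(fx))
  layout_ligand(g, ...)
}

test_that("chain interior angles are exactly the configured 120 degrees", {
  lay <- layout_of(make_ligand("linear_chain", n = 5))
  p <- lay$pos
  for (i in 2:4) {
    u <- p[i - 1, ] - p[i, ]; v <- p[i + 1, ] - p[i, ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(ang, 120, tolerance = 1e-9)
  }
})

test_that("rings are regular polygons with central angle 360/n", {
  for (n in c(5, 6, 8)) {
    lay <- layout_of(make_ligand("ring", n = n))
    ctr <- colMeans(lay$pos)
    radii <- sqrt(rowSums(sweep(lay$pos, 2, ctr)^2))
    expect_lt(diff(range(radii)), 1e-6)
    for (i in seq_len(n)) {
      j <- i %% n + 1
      u <- lay$pos[i, ] - ctr; v <- lay$pos[j, ] - ctr
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      expect_equal(ang, 360 / n, tolerance = 1e-6)
    }
  }
})

test_that("acyclic drawn bonds all have the configured bond length", {
  g <- branched_fixture()
  lay <- layout_ligand(g)
  rings <- perceive_sssr(g)
  ring_edge <- function(i, j) any(vapply(rings, function(r) {
    k <- length(r)
    any((r == i & r[c(2:k, 1)] == j) | (r == j & r[c(2:k, 1)] == i))
  }, TRUE))
  for (m in seq_len(nrow(g$edges))) {
    i <- g$edges$i[m]; j <- g$edges$j[m]
    if (ring_edge(i, j)) next
    expect_equal(sqrt(sum((lay$pos[i, ] - lay$pos[j, ])^2)), 1.5,
                 tolerance = 1e-9)
  }
})

test_that("macro-cycle atoms are laid out first as one regular polygon", {
  fx <- make_ligand("macrocycle", n_residues = 10)
  lay <- layout_of(fx)
  g <- lay$graph
  rings <- detect_macrocycles(perceive_sssr(g))
  rpos <- lay$pos[rings[[1]], ]
  ctr <- colMeans(rpos)
  radii <- sqrt(rowSums(sweep(rpos, 2, ctr)^2))
  expect_lt(diff(range(radii)), 1e-6)
})

test_that("layout is deterministic", {
  fx <- make_ligand("fused_rings")
  expect_identical(layout_of(fx)$pos, layout_of(fx)$pos)
})

test_that("conflicts are exactly the non-bonded pairs under 0.4 angstrom", {
  expect_equal(nrow(detect_conflicts(pair_layout(0.3))), 1)
  expect_equal(nrow(detect_conflicts(pair_layout(0.5))), 0)
  expect_equal(nrow(detect_conflicts(layout_of(make_ligand("ring", n = 6)))), 0)
  # bonded pairs are never conflicts
  g <- mk_graph(rbind(c(0, 0, 0), c(0.2, 0, 0)), list(c(1L, 2L)))
  lay <- mk_layout(rbind(c(0, 0), c(0.2, 0)), g)
  expect_equal(nrow(detect_conflicts(lay)), 0)
})

# a layout where one branch lies on top of the main chain; a single flip
# frees it
crowded_layout <- function() {
  g <- mk_graph(cbind(seq_len(5), 0, 0),
                list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L)),
                names_ = paste0("C", 1:5))
  pos <- rbind(c(0, 0), c(1.5, 0), c(2.25, 1.3), c(0.1, 0.1), c(-0.05, 1.6))
  mk_layout(pos, g)
}

# oracle: minimum conflict count reachable over all flip subsets applied in
# canonical edge order
brute_flip_min <- function(lay) {
  g <- lay$graph
  rot <- seq_len(nrow(g$edges))
  ig <- igraph::make_graph(edges = rbind(g$edges$i, g$edges$j),
                           n = nrow(g$atoms), directed = FALSE)
  best <- nrow(detect_conflicts(lay))
  for (mask in 0:(2^length(rot) - 1)) {
    trial <- lay
    for (b in seq_along(rot)) {
      if (!bitwAnd(mask, bitwShiftL(1L, b - 1L))) next
      k <- rot[b]
      a <- g$edges$i[k]; bb <- g$edges$j[k]
      g2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(a, bb)))
      cmp <- igraph::components(g2)
      if (cmp$no < 2) next
      sa <- which(cmp$membership == cmp$membership[a])
      sb <- which(cmp$membership == cmp$membership[bb])
      branch <- if (length(sb) <= length(sa)) setdiff(sb, bb) else setdiff(sa, a)
      if (!length(branch)) next
      p1 <- trial$pos[a, ]; p2 <- trial$pos[bb, ]
      u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
      for (at in branch) {
        w <- trial$pos[at, ] - p1
        trial$pos[at, ] <- p1 + 2 * sum(w * u) * u - w
      }
    }
    best <- min(best, nrow(detect_conflicts(trial)))
  }
  best
}

test_that("torsion flips reach the brute-force minimum on a crowded fixture", {
  lay <- crowded_layout()
  before <- nrow(detect_conflicts(lay))
  expect_gt(before, 0)
  resolved <- resolve_conflicts(lay)
  after <- nrow(detect_conflicts(resolved))
  expect_lte(after, before)
  expect_equal(after, brute_flip_min(lay))
  expect_equal(after, 0)
})

test_that("a conflict-free layout passes through resolution unchanged", {
  lay <- layout_of(make_ligand("ring", n = 6))
  out <- resolve_conflicts(lay)
  expect_identical(out$pos, lay$pos)
  expect_equal(attr(out, "n_flips"), 0L)
})

test_that("conflict count never increases through resolution", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    # random tree with random 2D positions (deliberately clumped)
    edges <- lapply(2:n, function(i) c(sample(seq_len(i - 1L), 1), i))
    g <- mk_graph(cbind(stats::runif(n, 0, 3), stats::runif(n, 0, 3), 0), edges)
    lay <- mk_layout(cbind(stats::runif(n, 0, 2.5), stats::runif(n, 0, 2.5)), g)
    before <- nrow(detect_conflicts(lay))
    after <- nrow(detect_conflicts(resolve_conflicts(lay)))
    expect_lte(after, before)
  }
})

test_that("explicit residues land on the real-distance circle at the best angle", {
  fx <- make_site(covalent_link = TRUE)
  s <- fx$struct
  lig <- detect_ligands(s)[[1]]
  g <- build_graph(lig, s, parsed_components(fx))
  lay <- layout_ligand(g)
  rows <- which(s$atoms$res_name == "CYS")
  pseudo <- structure(list(residues = lig$explicit_residues, atom_idx = rows,
                           is_metal = FALSE, explicit_residues = data.frame()),
                      class = "ligand_instance")
  rg <- build_graph(pseudo, s, list())
  rlay <- layout_ligand(rg)
  anchor_lig <- which(g$atoms$name == "C2")
  anchor_res <- which(rg$atoms$name == "SG")
  pl <- place_explicit_residue(lay, rlay, anchor_lig, anchor_res, 1.8)
  # anchor sits on the circle of the 3D distance
  d <- sqrt(sum((pl$res_pos[anchor_res, ] - lay$pos[anchor_lig, ])^2))
  expect_equal(d, 1.8, tolerance = 1e-9)
  # 36 candidates, 10 degrees apart
  expect_equal(nrow(pl$trace), 36)
  diffs <- diff(pl$trace$angle) %% 360
  expect_true(all(abs(diffs - 10) < 1e-9))
  # chosen score is the exhaustive-candidate minimum
  expect_equal(pl$score, min(pl$trace$crossings + pl$trace$overlaps))
  expect_error(place_explicit_residue(lay, rlay, anchor_lig, anchor_res, 0),
               "positive")
})

test_that("disconnected components are separated horizontally", {
  g <- mk_graph(rbind(c(0, 0, 0), c(1.5, 0, 0), c(50, 0, 0), c(51.5, 0, 0)),
                list(c(1L, 2L), c(3L, 4L)))
  lay <- layout_ligand(g)
  expect_true(all(!is.na(lay$pos)))
  d12 <- min(dist(lay$pos))
  expect_gt(min(abs(lay$pos[3, 1] - lay$pos[2, 1]),
                abs(lay$pos[3, 1] - lay$pos[1, 1])), 1.5)
})
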