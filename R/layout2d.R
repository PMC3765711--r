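# 2D ligand layout: recursive placement by structural element. Chains are
# drawn as 120-degree zigzags, rings as regular polygons (central angle
# 360/n), acyclic bonds at a fixed 2D bond length. When no atom of an
# element has been fixed yet its initial orientation is taken from the
# orthographic projection of the 3D coordinates onto their least-squares
# plane. Conflicts (non-bonded atoms closer than 0.4 A) are resolved by
# flipping acyclic torsions 0 -> 180 degrees (reflection of the smaller
# branch across the bond axis) whenever the flip strictly reduces the
# conflict count.

#' Layout configuration
#'
#' @param bond_length 2D bond length for acyclic bonds, angstrom.
#' @param chain_angle interior angle at chain atoms, degrees.
#' @param conflict_distance two non-bonded atoms closer than this in 2D are
#'   in conflict, angstrom.
#' @param explicit_step angular step of the explicit-residue circle search,
#'   degrees.
#' @param max_passes conflict-resolution pass limit.
#' @param seed seed for the randomised circle-search start angles.
#' @return a `layout_config` list.
#' @export
layout_config <- function(bond_length = 1.5, chain_angle = 120,
                          conflict_distance = 0.4, explicit_step = 10,
                          max_passes = 10L, seed = 0L) {
  stopifnot(bond_length > 0, conflict_distance > 0,
            conflict_distance < bond_length)
  structure(list(bond_length = bond_length, chain_angle = chain_angle,
                 conflict_distance = conflict_distance,
                 explicit_step = explicit_step, max_passes = max_passes,
                 seed = seed),
            class = "layout_config")
}

#' Compute 2D coordinates for a ligand
#'
#' Recursive placement: the start element is the macro-cycle if one exists,
#' otherwise the longest chain, otherwise the largest ring; from there a
#' depth-first walk places every atom and its neighbours. Ring atoms are
#' placed together as a regular polygon the moment the walk enters the
#' ring.
#'
#' @param graph a `molecular_graph`.
#' @param elements partition from [partition_elements()]; recomputed when
#'   NULL.
#' @param config a [layout_config()].
#' @return a `layout2d`: list with `pos` (n x 2 matrix, angstrom), `graph`,
#'   `elements`, `config`.
#' @export
layout_ligand <- function(graph, elements = NULL, config = layout_config()) {
  if (is.null(elements)) elements <- partition_elements(graph)
  n <- nrow(graph$atoms)
  proj <- project_plane(as.matrix(graph$atoms[, c("x", "y", "z")]))
  adj <- adjacency_list(graph)
  g <- as_igraph(graph)
  comps <- igraph::components(g)

  pos <- matrix(NA_real_, n, 2)
  turn_sign <- rep(NA_real_, n)

  ring_elements <- Filter(function(e) e$kind == "ring", elements)
  ring_of_edge <- function(a, b) {
    for (ri in seq_along(ring_elements)) {
      r <- ring_elements[[ri]]$atoms
      k <- length(r)
      for (m in seq_len(k)) {
        if ((r[m] == a && r[m %% k + 1] == b) || (r[m] == b && r[m %% k + 1] == a)) {
          return(ri)
        }
      }
    }
    NA_integer_
  }
  ring_placed <- rep(FALSE, length(ring_elements))
  rings_of_atom <- lapply(seq_len(n), function(a) {
    which(vapply(ring_elements, function(e) a %in% e$atoms, TRUE))
  })

  place_ring <- function(ri) {
    r <- ring_elements[[ri]]$atoms
    k <- length(r)
    done <- which(!is.na(pos[r, 1]))
    side <- config$bond_length
    # fused edge: two consecutive placed members fix the side length
    fused_pair <- NULL
    if (length(done) >= 2L) {
      for (m in seq_len(k)) {
        a <- r[m]; b <- r[m %% k + 1]
        if (!is.na(pos[a, 1]) && !is.na(pos[b, 1])) {
          fused_pair <- c(m, m %% k + 1)
          side <- dist2(pos[a, ], pos[b, ])
          break
        }
      }
    }
    rad <- side / (2 * sin(pi / k))
    step <- 2 * pi / k
    orient <- ring_orientation(r, proj)

    if (is.null(fused_pair) && length(done) == 0L) {
      ctr <- colMeans(proj[r, , drop = FALSE])
      phi0 <- atan2(proj[r[1], 2] - ctr[2], proj[r[1], 1] - ctr[1])
      for (m in seq_len(k)) {
        pos[r[m], ] <<- ctr + rad * c(cos(phi0 + orient * (m - 1) * step),
                                      sin(phi0 + orient * (m - 1) * step))
      }
    } else if (is.null(fused_pair)) {
      v <- r[done[1]]
      p <- pos[v, ]
      nb <- adj[[v]][!is.na(pos[adj[[v]], 1])]
      nb <- setdiff(nb, r)
      u <- if (length(nb)) {
        -unit2(colMeans(pos[nb, , drop = FALSE]) - p)
      } else c(1, 0)
      ctr <- p + rad * u
      phi0 <- atan2(p[2] - ctr[2], p[1] - ctr[1])
      shift <- done[1] - 1L
      for (m in seq_len(k)) {
        ang <- phi0 + orient * ((m - shift - 1L) %% k) * step
        if (is.na(pos[r[m], 1])) pos[r[m], ] <<- ctr + rad * c(cos(ang), sin(ang))
      }
    } else {
      m1 <- fused_pair[1]; m2 <- fused_pair[2]
      p1 <- pos[r[m1], ]; p2 <- pos[r[m2], ]
      mid <- (p1 + p2) / 2
      apo <- side / (2 * tan(pi / k))
      nrm <- unit2(c(-(p2 - p1)[2], (p2 - p1)[1]))
      others <- which(!is.na(pos[, 1]))
      others <- setdiff(others, r[c(m1, m2)])
      ctr_a <- mid + apo * nrm
      ctr_b <- mid - apo * nrm
      ctr <- if (length(others)) {
        oc <- colMeans(pos[others, , drop = FALSE])
        if (dist2(ctr_a, oc) >= dist2(ctr_b, oc)) ctr_a else ctr_b
      } else ctr_a
      phi1 <- atan2(p1[2] - ctr[2], p1[1] - ctr[1])
      phi2 <- atan2(p2[2] - ctr[2], p2[1] - ctr[1])
      dirn <- if (sin(phi2 - phi1) >= 0) 1 else -1
      for (m in seq_len(k)) {
        off <- (m - m1) %% k
        ang <- phi1 + dirn * off * step
        if (is.na(pos[r[m], 1])) pos[r[m], ] <<- ctr + rad * c(cos(ang), sin(ang))
      }
    }
    ring_placed[ri] <<- TRUE
  }

  # generic single-atom placement off an already-placed neighbour
  place_atom <- function(b, a) {
    placed_nb <- adj[[a]][!is.na(pos[adj[[a]], 1])]
    placed_nb <- setdiff(placed_nb, b)
    if (!length(placed_nb)) {
      d0 <- unit2(proj[b, ] - proj[a, ])
      pos[b, ] <<- pos[a, ] + config$bond_length * d0
      turn_sign[b] <<- 1
      return(invisible())
    }
    if (length(placed_nb) == 1L) {
      q <- placed_nb[1]
      s <- if (!is.na(turn_sign[a])) -turn_sign[a] else zig_sign(q, a, b, proj)
      dev <- 180 - config$chain_angle
      d0 <- unit2(pos[a, ] - pos[q, ])
      dir <- rot2(d0, s * dev)
      pos[b, ] <<- pos[a, ] + config$bond_length * dir
      turn_sign[b] <<- s
      return(invisible())
    }
    dir <- gap_bisector(pos[a, ], pos[placed_nb, , drop = FALSE])
    pos[b, ] <<- pos[a, ] + config$bond_length * dir
    turn_sign[b] <<- 1
    invisible()
  }

  dfs_place <- function(start) {
    stack <- start
    visited <- rep(FALSE, n)
    visited[start] <- TRUE
    while (length(stack)) {
      a <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nbrs <- adj[[a]]
      nbrs <- nbrs[order(graph$atoms$serial[nbrs])]
      for (b in nbrs) {
        rings_b <- rings_of_atom[[b]]
        unplaced_rings <- rings_b[!ring_placed[rings_b]]
        if (is.na(pos[b, 1]) && length(unplaced_rings)) {
          # anchor the ring: the entry atom is placed off `a` at bond
          # length, then the whole ring grows from it
          place_atom(b, a)
          for (ri in unplaced_rings) place_ring(ri)
        } else if (is.na(pos[b, 1])) {
          place_atom(b, a)
        } else if (length(unplaced_rings)) {
          for (ri in unplaced_rings) place_ring(ri)
        }
        if (!visited[b] && !is.na(pos[b, 1])) {
          visited[b] <- TRUE
          stack <- c(stack, b)
        }
      }
    }
  }

  for (ci in seq_len(comps$no)) {
    members <- which(comps$membership == ci)
    el_comp <- Filter(function(e) e$atoms[1] %in% members, elements)
    start_el <- pick_start_element(el_comp)
    if (is.null(start_el)) next
    if (start_el$kind == "ring") {
      ri <- which(vapply(ring_elements, function(e)
        identical(e$atoms, start_el$atoms), TRUE))[1]
      place_ring(ri)
      start_atom <- start_el$atoms[1]
    } else {
      start_atom <- chain_start_atom(start_el, adj, graph)
      pos[start_atom, ] <- proj[start_atom, ]
      turn_sign[start_atom] <- 1
    }
    dfs_place(start_atom)
    # sweep up anything unreachable through placed neighbours
    left <- members[is.na(pos[members, 1])]
    while (length(left)) {
      progressed <- FALSE
      for (b in left) {
        pn <- adj[[b]][!is.na(pos[adj[[b]], 1])]
        if (length(pn)) {
          ub <- rings_of_atom[[b]][!ring_placed[rings_of_atom[[b]]]]
          if (length(ub)) for (ri in ub) place_ring(ri) else place_atom(b, pn[1])
          progressed <- TRUE
        }
      }
      left <- members[is.na(pos[members, 1])]
      if (!progressed) {
        pos[left[1], ] <- proj[left[1], ]
        left <- left[-1]
      }
    }
  }

  # separate disconnected components horizontally
  if (comps$no > 1L) {
    offset <- 0
    for (ci in seq_len(comps$no)) {
      members <- which(comps$membership == ci)
      xr <- range(pos[members, 1])
      pos[members, 1] <- pos[members, 1] - xr[1] + offset
      offset <- offset + (xr[2] - xr[1]) + 2 * config$bond_length
    }
  }

  structure(list(pos = pos, graph = graph, elements = elements, config = config),
            class = "layout2d")
}

pick_start_element <- function(elements) {
  if (!length(elements)) return(NULL)
  macro <- Filter(function(e) isTRUE(e$is_macrocycle), elements)
  if (length(macro)) return(macro[[1]])
  chains <- Filter(function(e) e$kind == "chain", elements)
  if (length(chains)) {
    lens <- vapply(chains, function(e) length(e$atoms), 0L)
    return(chains[[which.max(lens)]])
  }
  rings <- Filter(function(e) e$kind == "ring", elements)
  if (length(rings)) {
    lens <- vapply(rings, function(e) length(e$atoms), 0L)
    return(rings[[which.max(lens)]])
  }
  elements[[1]]
}

# the walk starts at a terminal atom hanging off the chain end when there is
# one, else at the chain end itself
chain_start_atom <- function(el, adj, graph) {
  if (el$kind != "chain") return(el$atoms[1])
  ends <- el$atoms[c(1, length(el$atoms))]
  for (e in ends) {
    term <- adj[[e]][vapply(adj[[e]], function(x) length(adj[[x]]) == 1L, TRUE)]
    term <- setdiff(term, el$atoms)
    if (length(term)) return(term[order(graph$atoms$serial[term])][1])
  }
  ends[1]
}

# zigzag turn sign from the projected 3D geometry
zig_sign <- function(q, a, b, proj) {
  v1 <- proj[a, ] - proj[q, ]
  v2 <- proj[b, ] - proj[a, ]
  s <- sign(v1[1] * v2[2] - v1[2] * v2[1])
  if (s == 0) 1 else s
}

ring_orientation <- function(r, proj) {
  p <- proj[r, , drop = FALSE]
  area <- 0
  k <- nrow(p)
  for (m in seq_len(k)) {
    nxt <- m %% k + 1
    area <- area + p[m, 1] * p[nxt, 2] - p[nxt, 1] * p[m, 2]
  }
  if (area < 0) -1 else 1
}

# unit bisector of the largest angular gap among neighbour directions
gap_bisector <- function(p, nb_pos) {
  angs <- sort(apply(nb_pos, 1L, function(q) atan2(q[2] - p[2], q[1] - p[1])))
  k <- length(angs)
  gaps <- c(diff(angs), angs[1] + 2 * pi - angs[k])
  gi <- which.max(gaps)
  mid <- angs[gi] + gaps[gi] / 2
  c(cos(mid), sin(mid))
}

#' Detect 2D conflicts
#'
#' Non-bonded atom pairs closer than the conflict distance (default 0.4
#' angstrom) in the 2D layout.
#'
#' @param layout a `layout2d` (or any list with `pos` and `graph`).
#' @param config a [layout_config()].
#' @return data frame: i, j, dist.
#' @export
detect_conflicts <- function(layout, config = layout$config) {
  if (is.null(config)) config <- layout_config()
  pos <- layout$pos
  n <- nrow(pos)
  be <- normalise_edges(layout$graph$edges)
  bonded <- paste(be$i, be$j)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (paste(i, j) %in% bonded) next
        d <- dist2(pos[i, ], pos[j, ])
        if (d < config$conflict_distance) {
          out[[length(out) + 1L]] <- data.frame(i = i, j = j, dist = d)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  do.call(rbind, out)
}

#' Resolve layout conflicts by torsion flips
#'
#' Each acyclic rotatable bond is tried in turn: the smaller branch is
#' reflected across the bond axis (the 2D realisation of a 0 -> 180 degree
#' torsion flip) and the flip is kept only when the total conflict count
#' strictly decreases. Passes repeat until no flip is accepted (bounded by
#' `config$max_passes`). Ring-internal bonds are never flipped.
#'
#' @param layout a `layout2d`.
#' @param config a [layout_config()].
#' @return the layout with updated `pos`; attribute `n_flips` records the
#'   number of accepted flips.
#' @export
resolve_conflicts <- function(layout, config = layout$config) {
  if (is.null(config)) config <- layout_config()
  graph <- layout$graph
  pos <- layout$pos
  rings <- Filter(function(e) e$kind == "ring", layout$elements %||% list())
  ring_edges <- character()
  for (e in rings) {
    r <- e$atoms; k <- length(r)
    for (m in seq_len(k)) {
      a <- r[m]; b <- r[m %% k + 1]
      ring_edges <- c(ring_edges, paste(min(a, b), max(a, b)))
    }
  }
  ne <- normalise_edges(graph$edges)
  ekeys <- paste(ne$i, ne$j)
  rot <- which(!(ekeys %in% ring_edges))
  g <- as_igraph(graph)
  n_flips <- 0L
  lay <- layout
  lay$pos <- pos
  for (pass in seq_len(config$max_passes)) {
    accepted <- FALSE
    base <- nrow(detect_conflicts(lay, config))
    if (base == 0L) break
    for (k in rot) {
      a <- graph$edges$i[k]; b <- graph$edges$j[k]
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
      cmp <- igraph::components(g2)
      if (cmp$no < 2L) next  # edge inside a larger cycle
      side_a <- which(cmp$membership == cmp$membership[a])
      side_b <- which(cmp$membership == cmp$membership[b])
      branch <- if (length(side_b) <= length(side_a)) setdiff(side_b, b)
                else setdiff(side_a, a)
      if (!length(branch)) next
      trial <- lay$pos
      trial[branch, ] <- reflect_across(lay$pos[branch, , drop = FALSE],
                                        lay$pos[a, ], lay$pos[b, ])
      lay2 <- lay; lay2$pos <- trial
      newc <- nrow(detect_conflicts(lay2, config))
      if (newc < base) {
        lay$pos <- trial
        base <- newc
        accepted <- TRUE
        n_flips <- n_flips + 1L
      }
    }
    if (!accepted) break
  }
  attr(lay, "n_flips") <- n_flips
  lay
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Place an explicit residue around the ligand
#'
#' The residue (laid out independently) is rigid-body translated so its
#' anchor atom lies on the circle of radius `distance3d` centred on the
#' ligand anchor atom. Candidate positions every `config$explicit_step`
#' degrees (36 at the default 10) from a seeded random start are scored by
#' bond crossings plus atom overlaps against the ligand; the minimum wins,
#' ties by angle index.
#'
#' @param layout ligand `layout2d`.
#' @param residue_layout `layout2d` of the explicit residue.
#' @param anchor_lig,anchor_res atom indices (into the respective graphs) of
#'   the LINKed atom pair.
#' @param distance3d real 3D distance between the anchor atoms, angstrom.
#' @param config a [layout_config()].
#' @return list with `res_pos` (residue coordinates), `angle` (chosen
#'   degrees), `score`, and a `trace` data frame of all candidates.
#' @export
place_explicit_residue <- function(layout, residue_layout, anchor_lig,
                                   anchor_res, distance3d,
                                   config = layout$config) {
  if (is.null(config)) config <- layout_config()
  if (distance3d <= 0) stop("distance3d must be positive")
  lig_segs <- bond_segments(layout)
  lig_pts <- layout$pos
  apos <- layout$pos[anchor_lig, ]
  start <- with_seed(config$seed, stats::runif(1, 0, 360))
  nc <- round(360 / config$explicit_step)
  angles <- (start + config$explicit_step * (0:(nc - 1))) %% 360
  best <- NULL
  trace <- data.frame(angle = angles, crossings = NA_integer_,
                      overlaps = NA_integer_)
  for (ai in seq_len(nc)) {
    th <- deg2rad(angles[ai])
    target <- apos + distance3d * c(cos(th), sin(th))
    shift <- target - residue_layout$pos[anchor_res, ]
    rp <- sweep(residue_layout$pos, 2, -shift)
    segs <- c(bond_segments(list(pos = rp, graph = residue_layout$graph)),
              list(list(p1 = apos, p2 = target)))
    crossings <- sum(vapply(segs, function(s1) {
      sum(vapply(lig_segs, function(s2)
        segments_cross(s1$p1, s1$p2, s2$p1, s2$p2), TRUE))
    }, 0))
    overlaps <- 0L
    for (i in seq_len(nrow(rp))) {
      overlaps <- overlaps +
        sum(sqrt(rowSums(sweep(lig_pts, 2, rp[i, ])^2)) < config$conflict_distance)
    }
    trace$crossings[ai] <- crossings
    trace$overlaps[ai] <- overlaps
    sc <- crossings + overlaps
    if (is.null(best) || sc < best$score) {
      best <- list(res_pos = rp, angle = angles[ai], score = sc, index = ai)
    }
  }
  best$trace <- trace
  best
}

bond_segments <- function(layout) {
  e <- layout$graph$edges
  lapply(seq_len(nrow(e)), function(k) {
    list(p1 = layout$pos[e$i[k], ], p2 = layout$pos[e$j[k], ],
         order = e$order[k])
  })
}

#' @export
print.layout2d <- function(x, ...) {
  cat(sprintf("<layout2d> %d atoms placed, %d conflicts\n",
              sum(!is.na(x$pos[, 1])), nrow(detect_conflicts(x))))
  invisible(x)
}
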