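# Diagram assembly. Interacting elements are placed around the laid-out
# ligand on circles whose radius is the real 3D distance, by rotational
# search: hydrogen-bond partners first (lines cross most easily), then
# nearby-residue ovals, then water bridges; finally residue-name labels.
# Every candidate position is scored against everything already drawn, so
# earlier elements are obstacles for later ones and are never moved.

INTERACTION_STEP <- 5    # degrees between candidate interaction positions
LABEL_STEP <- 10         # degrees between candidate label positions
LABEL_NEARBY_DIST <- 2.0 # a diagram element within this of a candidate label counts against it
OVAL_RADIUS <- 1.2       # residue ovals approximated as circles of this radius, angstrom
CONTACT_DIST <- 0.4      # close-contact distance used in placement scoring

#' Count diagram elements near a candidate label position
#'
#' The label-placement score: how many obstacle points lie within
#' `threshold` (default 2 angstrom) of `position`.
#'
#' @param position 2-vector candidate position.
#' @param obstacles matrix of obstacle points (one per row), or NULL.
#' @param threshold nearby distance, angstrom.
#' @return integer count.
#' @export
label_nearby_count <- function(position, obstacles, threshold = LABEL_NEARBY_DIST) {
  if (is.null(obstacles) || !nrow(obstacles)) return(0L)
  sum(sqrt(rowSums(sweep(obstacles, 2, position)^2)) < threshold)
}

# score one candidate against current obstacles
score_candidate <- function(cand, anchor_pos, segs, points, ovals,
                            contact_dist = CONTACT_DIST, is_oval = FALSE) {
  conn <- list(p1 = anchor_pos, p2 = cand)
  crossings <- sum(vapply(segs, function(s)
    segments_cross(conn$p1, conn$p2, s$p1, s$p2), TRUE))
  if (length(ovals)) {
    crossings <- crossings + sum(vapply(ovals, function(o)
      segment_hits_circle(conn$p1, conn$p2, o$centre, o$r), TRUE))
  }
  eff <- contact_dist + if (is_oval) OVAL_RADIUS else 0
  contacts <- 0L
  if (!is.null(points) && nrow(points)) {
    contacts <- sum(sqrt(rowSums(sweep(points, 2, cand)^2)) < eff)
  }
  c(crossings = crossings, contacts = contacts)
}

# 72-candidate (default) rotational search around anchor_pos; the start
# angle is drawn from the scene RNG stream, ties break by angle index
rotational_search <- function(anchor_pos, radius, step_deg, segs, points,
                              ovals, is_oval = FALSE) {
  nc <- round(360 / step_deg)
  start <- stats::runif(1, 0, 360)
  angles <- (start + step_deg * (0:(nc - 1))) %% 360
  trace <- data.frame(angle = angles, crossings = NA_integer_,
                      contacts = NA_integer_)
  best <- NULL
  for (ai in seq_len(nc)) {
    th <- deg2rad(angles[ai])
    cand <- anchor_pos + radius * c(cos(th), sin(th))
    sc <- score_candidate(cand, anchor_pos, segs, points, ovals,
                          is_oval = is_oval)
    trace$crossings[ai] <- sc["crossings"]
    trace$contacts[ai] <- sc["contacts"]
    if (is.null(best) || sc["crossings"] < best$score[1] ||
        (sc["crossings"] == best$score[1] && sc["contacts"] < best$score[2])) {
      best <- list(pos = cand, angle = angles[ai], index = ai,
                   score = unname(sc))
    }
  }
  best$trace <- trace
  best
}

#' Place interactions around a laid-out ligand
#'
#' Hydrogen-bond partner atoms are placed first, then nearby-residue ovals,
#' then water bridges (each bridge water stepwise). Each element is placed
#' on the circle of its real 3D distance from its anchor, evaluated every 5
#' degrees; the candidate minimising bond crossings wins, ties broken by
#' fewest close contacts (< 0.4 angstrom), then by angle index from the
#' seeded random start. A nearby residue that hydrogen-bonds to the ligand
#' is drawn at its hydrogen-bond partner's position rather than placed
#' twice.
#'
#' @param layout ligand `layout2d` (pipeline coordinates, conflict-resolved).
#' @param interactions an `interaction_set` from [detect_interactions()].
#' @param struct the `pdb_structure`.
#' @param config a [layout_config()] (supplies the seed).
#' @param include_waters also place water bridges (they are always
#'   computed; drawn only on request).
#' @param explicit placed explicit residues (as built by [draw_diagram()]):
#'   their bonds and atoms are obstacles for the search.
#' @return a `scene`: list with `layout`, `placed` (list of placed
#'   elements: kind, anchor, position, radius, score, trace, ...),
#'   `interactions`, `struct`, `explicit`.
#' @export
place_interactions <- function(layout, interactions, struct,
                               config = layout$config,
                               include_waters = FALSE, explicit = list()) {
  if (is.null(config)) config <- layout_config()
  a <- struct$atoms
  segs <- bond_segments(layout)
  points <- layout$pos[!is.na(layout$pos[, 1]), , drop = FALSE]
  for (ex in explicit) {
    segs <- c(segs, bond_segments(list(pos = ex$pos, graph = ex$graph)),
              list(list(p1 = ex$anchor_lig_pos, p2 = ex$pos[ex$anchor_res, ])))
    points <- rbind(points, ex$pos)
  }
  ovals <- list()
  placed <- list()
  # map structure row -> 2D position for ligand atoms
  row2pos <- function(row) {
    k <- match(row, layout$graph$atoms$idx)
    layout$pos[k, ]
  }
  res_key_of <- function(df) paste(df$chain, df$res_seq, df$res_name, sep = "|")

  with_seed(config$seed, {
    hb <- interactions$hbonds
    hb_res_pos <- list()  # residue key -> partner 2D position
    if (!is.null(hb) && nrow(hb)) {
      for (i in seq_len(nrow(hb))) {
        lig_row <- if (hb$ligand_is_donor[i]) hb$donor_row[i] else hb$acceptor_row[i]
        par_row <- if (hb$ligand_is_donor[i]) hb$acceptor_row[i] else hb$donor_row[i]
        anchor <- row2pos(lig_row)
        found <- rotational_search(anchor, hb$distance[i], INTERACTION_STEP,
                                   segs, points, ovals)
        el <- list(kind = "hbond_partner", anchor_row = lig_row,
                   partner_row = par_row, anchor = anchor,
                   position = found$pos, radius = hb$distance[i],
                   angle = found$angle, score = found$score,
                   trace = found$trace, distance = hb$distance[i],
                   ligand_is_donor = hb$ligand_is_donor[i])
        placed[[length(placed) + 1L]] <- el
        segs[[length(segs) + 1L]] <- list(p1 = anchor, p2 = found$pos)
        points <- rbind(points, found$pos)
        key <- paste(a$chain[par_row], a$res_seq[par_row], a$res_name[par_row],
                     sep = "|")
        hb_res_pos[[key]] <- found$pos
      }
    }

    nb <- interactions$nearby
    res_oval_pos <- list()
    # residues drawn as explicit (covalently linked) are not doubled as ovals
    explicit_keys <- vapply(explicit, function(ex)
      paste(ex$chain, ex$res_seq, ex$res_name, sep = "|"), "")
    if (!is.null(nb) && nrow(nb)) {
      for (i in seq_len(nrow(nb))) {
        key <- res_key_of(nb[i, ])
        if (key %in% explicit_keys) next
        if (!is.null(hb_res_pos[[key]])) {
          # unified depiction: oval at the hydrogen-bonded partner position
          el <- list(kind = "residue_oval", res_name = nb$res_name[i],
                     chain = nb$chain[i], res_seq = nb$res_seq[i],
                     anchor = row2pos(nb$lig_row[i]),
                     position = hb_res_pos[[key]],
                     radius = nb$min_distance[i], angle = NA_real_,
                     score = c(0L, 0L), trace = NULL, via_hbond = TRUE)
          placed[[length(placed) + 1L]] <- el
          ovals[[length(ovals) + 1L]] <- list(centre = el$position, r = OVAL_RADIUS)
          res_oval_pos[[key]] <- el$position
          next
        }
        anchor <- row2pos(nb$lig_row[i])
        found <- rotational_search(anchor, nb$min_distance[i], INTERACTION_STEP,
                                   segs, points, ovals, is_oval = TRUE)
        el <- list(kind = "residue_oval", res_name = nb$res_name[i],
                   chain = nb$chain[i], res_seq = nb$res_seq[i],
                   anchor = anchor, position = found$pos,
                   radius = nb$min_distance[i], angle = found$angle,
                   score = found$score, trace = found$trace, via_hbond = FALSE)
        placed[[length(placed) + 1L]] <- el
        ovals[[length(ovals) + 1L]] <- list(centre = found$pos, r = OVAL_RADIUS)
        points <- rbind(points, found$pos)
        res_oval_pos[[key]] <- found$pos
      }
    }

    br <- interactions$bridges
    if (include_waters && !is.null(br) && nrow(br)) {
      for (i in seq_len(nrow(br))) {
        anchor <- row2pos(br$lig_row[i])
        steps <- br$step_distances[[i]]
        node_pos <- list()
        cur <- anchor
        for (s in seq_along(steps)) {
          is_last <- s == length(steps)
          key <- paste(br$chain[i], br$res_seq[i], br$res_name[i], sep = "|")
          if (is_last && !is.null(res_oval_pos[[key]])) {
            # endpoint residue already drawn: connect to it
            node_pos[[s]] <- res_oval_pos[[key]]
            segs[[length(segs) + 1L]] <- list(p1 = cur, p2 = node_pos[[s]])
            break
          }
          found <- rotational_search(cur, steps[s], INTERACTION_STEP,
                                     segs, points, ovals, is_oval = is_last)
          node_pos[[s]] <- found$pos
          segs[[length(segs) + 1L]] <- list(p1 = cur, p2 = found$pos)
          points <- rbind(points, found$pos)
          if (is_last) {
            ovals[[length(ovals) + 1L]] <- list(centre = found$pos, r = OVAL_RADIUS)
          }
          cur <- found$pos
        }
        placed[[length(placed) + 1L]] <- list(
          kind = "water_bridge", anchor_row = br$lig_row[i],
          res_name = br$res_name[i], chain = br$chain[i],
          res_seq = br$res_seq[i], anchor = anchor,
          node_pos = node_pos, n_waters = br$n_waters[i],
          radius = steps[1], position = node_pos[[1]],
          step_distances = steps)
      }
    }
  })

  structure(list(layout = layout, placed = placed, interactions = interactions,
                 struct = struct, config = config, explicit = explicit),
            class = "lig2d_scene")
}

#' Place residue-name labels
#'
#' For each ligand residue and explicit residue the label is placed on the
#' circle centred on the residue centroid (mean of its 2D atom positions)
#' with radius Max(distance(centroid, atom)) + 0.5 angstrom, evaluated
#' every 10 degrees from a seeded random start; the candidate with the
#' fewest diagram elements within 2 angstrom wins, ties by angle index.
#'
#' @param scene a `lig2d_scene` from [place_interactions()].
#' @param config a [layout_config()].
#' @return the scene with a `labels` list added (one entry per residue:
#'   text, centroid, radius, position, score, trace).
#' @export
place_labels <- function(scene, config = scene$config) {
  if (is.null(config)) config <- layout_config()
  layout <- scene$layout
  ga <- layout$graph$atoms
  obstacles <- layout$pos[!is.na(layout$pos[, 1]), , drop = FALSE]
  for (el in scene$placed) {
    if (!is.null(el$position)) obstacles <- rbind(obstacles, el$position)
    if (!is.null(el$node_pos)) {
      for (np in el$node_pos) obstacles <- rbind(obstacles, np)
    }
  }
  for (ex in scene$explicit %||% list()) obstacles <- rbind(obstacles, ex$pos)
  labels <- list()
  rk <- paste(ga$chain, ga$res_seq, ga$res_name, sep = "|")
  groups <- lapply(unique(rk), function(key) {
    rows <- which(rk == key)
    list(res_name = ga$res_name[rows[1]], chain = ga$chain[rows[1]],
         res_seq = ga$res_seq[rows[1]],
         pts = layout$pos[rows, , drop = FALSE])
  })
  for (ex in scene$explicit %||% list()) {
    groups[[length(groups) + 1L]] <- list(res_name = ex$res_name,
                                          chain = ex$chain,
                                          res_seq = ex$res_seq, pts = ex$pos)
  }
  with_seed(config$seed + 1L, {
    for (grp in groups) {
      pts <- grp$pts
      pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
      if (!nrow(pts)) next
      ctr <- colMeans(pts)
      rad <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) + 0.5
      nc <- round(360 / LABEL_STEP)
      start <- stats::runif(1, 0, 360)
      angles <- (start + LABEL_STEP * (0:(nc - 1))) %% 360
      trace <- data.frame(angle = angles, nearby = NA_integer_)
      best <- NULL
      for (ai in seq_len(nc)) {
        th <- deg2rad(angles[ai])
        cand <- ctr + rad * c(cos(th), sin(th))
        cnt <- label_nearby_count(cand, obstacles)
        trace$nearby[ai] <- cnt
        if (is.null(best) || cnt < best$score) {
          best <- list(position = cand, angle = angles[ai], index = ai,
                       score = cnt)
        }
      }
      lab <- list(text = sprintf("%s %s%d", grp$res_name, grp$chain,
                                 grp$res_seq),
                  res_name = grp$res_name, chain = grp$chain,
                  res_seq = grp$res_seq, centroid = ctr,
                  radius = rad, position = best$position,
                  angle = best$angle, score = best$score, trace = trace)
      labels[[length(labels) + 1L]] <- lab
      obstacles <- rbind(obstacles, best$position)
    }
  })
  scene$labels <- labels
  scene
}

#' @export
print.lig2d_scene <- function(x, ...) {
  kinds <- vapply(x$placed, `[[`, "", "kind")
  cat(sprintf("<lig2d_scene> %d atoms, %d placed elements (%s), %d labels\n",
              nrow(x$layout$pos), length(x$placed),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              length(x$labels %||% list())))
  invisible(x)
}
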