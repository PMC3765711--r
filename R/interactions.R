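# Geometric interaction detection between a ligand and its environment:
# nearby residues (minimum heavy-atom distance within a cutoff), hydrogen
# bonds (donor/acceptor pairs with an acceptor-neighbour angle criterion)
# and water-mediated hydrogen-bond paths of 1-4 waters. All criteria use
# heavy atoms only.

#' Interaction detection configuration
#'
#' @param residue_cutoff nearby-residue cutoff, angstrom (default 4.0).
#' @param hbond_cutoff donor-acceptor distance cutoff, angstrom
#'   (default 3.3).
#' @param water_radius maximum step length along a water-mediated path,
#'   angstrom (default 3.3).
#' @param max_bridge_waters maximum waters per bridge (default 4).
#' @param hbond_angle_max a donor/acceptor pair is accepted when some
#'   acceptor neighbour aa satisfies angle(D, A, aa) below this, degrees
#'   (default 90).
#' @return an `interaction_config` list.
#' @export
interaction_config <- function(residue_cutoff = 4.0, hbond_cutoff = 3.3,
                               water_radius = 3.3, max_bridge_waters = 4L,
                               hbond_angle_max = 90) {
  stopifnot(residue_cutoff > 0, hbond_cutoff > 0, water_radius > 0,
            max_bridge_waters >= 1)
  structure(list(residue_cutoff = residue_cutoff, hbond_cutoff = hbond_cutoff,
                 water_radius = water_radius,
                 max_bridge_waters = as.integer(max_bridge_waters),
                 hbond_angle_max = hbond_angle_max),
            class = "interaction_config")
}

env_atom_rows <- function(struct, ligand) {
  a <- struct$atoms
  setdiff(which(!a$is_het & !a$is_water & a$element != "H"), ligand$atom_idx)
}

#' Find residues near a ligand
#'
#' Biomacromolecule residues with at least one heavy atom within
#' `residue_cutoff` of any ligand atom, with the minimum heavy-atom
#' distance and the closest atom pair, sorted by distance. Waters and
#' ligand members are excluded.
#'
#' @param ligand a `ligand_instance`.
#' @param struct the `pdb_structure`.
#' @param config an [interaction_config()].
#' @return data frame: res_name, chain, res_seq, min_distance, lig_row,
#'   res_row (row indices into `struct$atoms`).
#' @export
find_nearby_residues <- function(ligand, struct, config = interaction_config()) {
  a <- struct$atoms
  env <- env_atom_rows(struct, ligand)
  empty <- data.frame(res_name = character(), chain = character(),
                      res_seq = integer(), min_distance = numeric(),
                      lig_row = integer(), res_row = integer(),
                      stringsAsFactors = FALSE)
  if (!length(env)) return(empty)
  ligm <- as.matrix(a[ligand$atom_idx, c("x", "y", "z")])
  out <- list()
  for (key in unique(residue_key(a)[env])) {
    rows <- env[residue_key(a)[env] == key]
    dm <- cross_dist(ligm, as.matrix(a[rows, c("x", "y", "z"), drop = FALSE]))
    best <- arrayInd(which.min(dm), dim(dm))
    dmin <- dm[best]
    if (dmin <= config$residue_cutoff) {
      out[[length(out) + 1L]] <- data.frame(
        res_name = a$res_name[rows[1]], chain = a$chain[rows[1]],
        res_seq = a$res_seq[rows[1]], min_distance = dmin,
        lig_row = ligand$atom_idx[best[1]], res_row = rows[best[2]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$min_distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag hydrogen-bond donors and acceptors
#'
#' Typing over N, O, S heavy atoms. With a component definition: an O with
#' a bonded hydrogen is donor and acceptor, any other O is acceptor; an N
#' with a bonded hydrogen is donor, otherwise acceptor; S is a weak donor
#' and acceptor. Without a definition (or a definition carrying no
#' hydrogens at all) N and O are treated permissively as both donor and
#' acceptor. Other elements are neither.
#'
#' @param struct the `pdb_structure`.
#' @param rows atom row indices to type.
#' @param components named list of `component_def` keyed by residue name.
#' @return data frame: row, element, is_donor, is_acceptor.
#' @export
assign_donors_acceptors <- function(struct, rows, components = list()) {
  a <- struct$atoms
  is_donor <- logical(length(rows))
  is_acceptor <- logical(length(rows))
  el <- a$element[rows]
  for (k in seq_along(rows)) {
    if (!el[k] %in% c("N", "O", "S")) next
    if (el[k] == "S") { is_donor[k] <- TRUE; is_acceptor[k] <- TRUE; next }
    comp <- components[[a$res_name[rows[k]]]]
    has_h_info <- !is.null(comp) && any(comp$atoms$element == "H")
    if (!has_h_info) { is_donor[k] <- TRUE; is_acceptor[k] <- TRUE; next }
    nm <- a$name[rows[k]]
    nbrs <- c(comp$bonds$a2[comp$bonds$a1 == nm], comp$bonds$a1[comp$bonds$a2 == nm])
    n_h <- sum(comp$atoms$element[match(nbrs, comp$atoms$name)] == "H")
    if (el[k] == "O") {
      is_acceptor[k] <- TRUE
      is_donor[k] <- n_h >= 1
    } else {             # N
      is_donor[k] <- n_h >= 1
      is_acceptor[k] <- n_h == 0
    }
  }
  data.frame(row = rows, element = el, is_donor = is_donor,
             is_acceptor = is_acceptor, stringsAsFactors = FALSE)
}

# covalent heavy-atom neighbours of `row` among `candidate_rows`
covalent_neighbours <- function(struct, row, candidate_rows) {
  a <- struct$atoms
  p <- as.numeric(a[row, c("x", "y", "z")])
  keep <- integer()
  for (r in setdiff(candidate_rows, row)) {
    thr <- if (a$element[row] == "S" || a$element[r] == "S")
      COVALENT_DIST_S else COVALENT_DIST
    if (dist3(p, as.numeric(a[r, c("x", "y", "z")])) < thr) keep <- c(keep, r)
  }
  keep
}

#' Detect hydrogen bonds between a ligand and its environment
#'
#' For every cross (ligand/environment) donor-acceptor pair within
#' `hbond_cutoff`, the bond is accepted when some covalent neighbour aa of
#' the acceptor gives angle(D, A, aa) below `hbond_angle_max`; the
#' smallest-angle aa is stored. The criterion is applied symmetrically
#' (ligand as donor or as acceptor). An acceptor with no covalent
#' neighbour passes vacuously (aa = NA). Each unordered atom pair is
#' reported once.
#'
#' @param ligand a `ligand_instance`.
#' @param struct the `pdb_structure`.
#' @param config an [interaction_config()].
#' @param components component definitions for donor/acceptor typing.
#' @param graph optional `molecular_graph` of the ligand (supplies ligand
#'   acceptor neighbours; inferred from distances when absent).
#' @param env_rows environment atom rows to consider; defaults to all
#'   heavy polymer atoms within `residue_cutoff`-qualifying residues.
#' @return data frame: donor_row, acceptor_row, aa_row, distance, angle,
#'   ligand_is_donor.
#' @export
find_hydrogen_bonds <- function(ligand, struct, config = interaction_config(),
                                components = list(), graph = NULL,
                                env_rows = NULL) {
  a <- struct$atoms
  if (is.null(env_rows)) {
    wide <- config
    wide$residue_cutoff <- max(config$residue_cutoff, config$hbond_cutoff)
    nb <- find_nearby_residues(ligand, struct, wide)
    keys <- paste(nb$chain, nb$res_seq, nb$res_name, sep = "|")
    env_rows <- env_atom_rows(struct, ligand)
    env_rows <- env_rows[residue_key(a)[env_rows] %in% keys]
  }
  empty <- data.frame(donor_row = integer(), acceptor_row = integer(),
                      aa_row = integer(), distance = numeric(),
                      angle = numeric(), ligand_is_donor = logical())
  if (!length(env_rows)) return(empty)

  fl <- assign_donors_acceptors(struct, ligand$atom_idx, components)
  fe <- assign_donors_acceptors(struct, env_rows, components)
  lig_nbrs <- function(row) {
    if (!is.null(graph)) {
      k <- match(row, graph$atoms$idx)
      if (!is.na(k)) {
        nb <- c(graph$edges$j[graph$edges$i == k], graph$edges$i[graph$edges$j == k])
        return(graph$atoms$idx[nb])
      }
    }
    covalent_neighbours(struct, row, ligand$atom_idx)
  }
  env_nbrs <- function(row) covalent_neighbours(struct, row, env_rows)

  cands <- list()
  for (li in seq_len(nrow(fl))) {
    for (ei in seq_len(nrow(fe))) {
      lrow <- fl$row[li]; erow <- fe$row[ei]
      d <- dist3(as.numeric(a[lrow, c("x", "y", "z")]),
                 as.numeric(a[erow, c("x", "y", "z")]))
      if (d > config$hbond_cutoff) next
      for (dir in c("lig_donor", "env_donor")) {
        ok_roles <- if (dir == "lig_donor") fl$is_donor[li] && fe$is_acceptor[ei]
                    else fe$is_donor[ei] && fl$is_acceptor[li]
        if (!ok_roles) next
        drow <- if (dir == "lig_donor") lrow else erow
        arow <- if (dir == "lig_donor") erow else lrow
        aa <- if (dir == "lig_donor") env_nbrs(arow) else lig_nbrs(arow)
        dpos <- as.numeric(a[drow, c("x", "y", "z")])
        apos <- as.numeric(a[arow, c("x", "y", "z")])
        if (!length(aa)) {
          cands[[length(cands) + 1L]] <- data.frame(
            donor_row = drow, acceptor_row = arow, aa_row = NA_integer_,
            distance = d, angle = NA_real_, ligand_is_donor = dir == "lig_donor")
          next
        }
        angs <- vapply(aa, function(r)
          angle_at(apos, dpos, as.numeric(a[r, c("x", "y", "z")])), 0)
        if (min(angs) < config$hbond_angle_max) {
          best <- which.min(angs)
          cands[[length(cands) + 1L]] <- data.frame(
            donor_row = drow, acceptor_row = arow, aa_row = aa[best],
            distance = d, angle = angs[best],
            ligand_is_donor = dir == "lig_donor")
        }
      }
    }
  }
  if (!length(cands)) return(empty)
  out <- do.call(rbind, cands)
  # one report per unordered atom pair: keep the smaller-angle direction
  pk <- apply(out[, c("donor_row", "acceptor_row")], 1L,
              function(r) paste(sort(r), collapse = "-"))
  out <- out[order(pk, out$angle, !out$ligand_is_donor), , drop = FALSE]
  out <- out[!duplicated(apply(out[, c("donor_row", "acceptor_row")], 1L,
                               function(r) paste(sort(r), collapse = "-"))), ,
             drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find water-mediated hydrogen-bond paths
#'
#' Breadth-limited enumeration of simple paths from a ligand donor/acceptor
#' atom through 1 to `max_bridge_waters` water oxygens to an environment
#' donor/acceptor atom, every step within `water_radius`.
#'
#' @param ligand a `ligand_instance`.
#' @param struct the `pdb_structure`.
#' @param config an [interaction_config()].
#' @param components component definitions for donor/acceptor typing.
#' @return data frame: lig_row, res_name, chain, res_seq, res_row,
#'   n_waters, water_rows (list column), step_distances (list column),
#'   total_distance.
#' @export
find_water_bridges <- function(ligand, struct, config = interaction_config(),
                               components = list()) {
  a <- struct$atoms
  empty <- data.frame(lig_row = integer(), res_name = character(),
                      chain = character(), res_seq = integer(),
                      res_row = integer(), n_waters = integer(),
                      total_distance = numeric())
  empty$water_rows <- list(); empty$step_distances <- list()

  waters <- which(a$is_water & a$element == "O")
  if (!length(waters)) return(empty)
  fl <- assign_donors_acceptors(struct, ligand$atom_idx, components)
  lig_da <- fl$row[fl$is_donor | fl$is_acceptor]
  env <- env_atom_rows(struct, ligand)
  fe <- assign_donors_acceptors(struct, env, components)
  env_da <- fe$row[fe$is_donor | fe$is_acceptor]
  if (!length(lig_da) || !length(env_da)) return(empty)

  xyz <- function(r) as.numeric(a[r, c("x", "y", "z")])
  wmat <- as.matrix(a[waters, c("x", "y", "z"), drop = FALSE])
  wd <- as.matrix(stats::dist(wmat))

  paths <- list()
  walk <- function(lrow, chain_w, last_pos, dists) {
    # terminate at any reachable environment donor/acceptor
    for (erow in env_da) {
      dstep <- dist3(last_pos, xyz(erow))
      if (dstep <= config$water_radius) {
        paths[[length(paths) + 1L]] <<- list(
          lig = lrow, waters = waters[chain_w], res = erow,
          dists = c(dists, dstep))
      }
    }
    if (length(chain_w) >= config$max_bridge_waters) return()
    for (wi in seq_along(waters)) {
      if (wi %in% chain_w) next
      dstep <- wd[chain_w[length(chain_w)], wi]
      if (dstep <= config$water_radius) {
        walk(lrow, c(chain_w, wi), wmat[wi, ], c(dists, dstep))
      }
    }
  }
  for (lrow in lig_da) {
    lp <- xyz(lrow)
    for (wi in seq_along(waters)) {
      d1 <- dist3(lp, wmat[wi, ])
      if (d1 <= config$water_radius) walk(lrow, wi, wmat[wi, ], d1)
    }
  }
  if (!length(paths)) return(empty)
  out <- data.frame(
    lig_row = vapply(paths, `[[`, 0L, "lig"),
    res_name = a$res_name[vapply(paths, `[[`, 0L, "res")],
    chain = a$chain[vapply(paths, `[[`, 0L, "res")],
    res_seq = a$res_seq[vapply(paths, `[[`, 0L, "res")],
    res_row = vapply(paths, `[[`, 0L, "res"),
    n_waters = vapply(paths, function(p) length(p$waters), 0L),
    total_distance = vapply(paths, function(p) sum(p$dists), 0),
    stringsAsFactors = FALSE)
  out$water_rows <- lapply(paths, `[[`, "waters")
  out$step_distances <- lapply(paths, `[[`, "dists")
  ord <- order(paste(out$lig_row, out$res_row), out$n_waters, out$total_distance)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect all interactions for a ligand
#'
#' Convenience wrapper bundling [find_nearby_residues()],
#' [find_hydrogen_bonds()] and [find_water_bridges()].
#'
#' @param ligand a `ligand_instance`.
#' @param struct the `pdb_structure`.
#' @param config an [interaction_config()].
#' @param components component definitions.
#' @param graph optional ligand `molecular_graph`.
#' @return an `interaction_set`: list(nearby, hbonds, bridges).
#' @export
detect_interactions <- function(ligand, struct, config = interaction_config(),
                                components = list(), graph = NULL) {
  structure(list(
    nearby = find_nearby_residues(ligand, struct, config),
    hbonds = find_hydrogen_bonds(ligand, struct, config, components, graph),
    bridges = find_water_bridges(ligand, struct, config, components)
  ), class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set> %d hydrogen bonds, %d nearby residues, %d water paths\n",
              nrow(x$hbonds), nrow(x$nearby), nrow(x$bridges)))
  invisible(x)
}
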