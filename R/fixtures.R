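# Synthetic fixture generation: small ligands, pseudo-protein shells, water
# chains and covalently linked residues with exactly controlled geometry,
# plus matching minimal component definitions. Pseudo-residues carry 2-5
# heavy atoms: the geometric criteria only need positions, names and
# donor/acceptor elements, not chemically complete amino acids.

#' Generate a synthetic ligand PDB plus its component definition
#'
#' @param kind one of `"linear_chain"`, `"ring"`, `"fused_rings"`,
#'   `"macrocycle"`.
#' @param n atom count for `linear_chain` / ring size for `ring`.
#' @param n_residues residue count for `macrocycle` (each residue
#'   contributes an N-CA-C backbone; consecutive residues and the
#'   head-to-tail closure are joined by LINK records).
#' @param seed fixture seed (generation is deterministic; the seed is
#'   recorded so downstream seeded searches are reproducible).
#' @return list with `pdb` (PDB text), `components` (named list of component
#'   definition texts) and `spec` (the echoed parameters).
#' @examples
#' fx <- make_ligand("linear_chain", n = 5)
#' parse_pdb(fx$pdb)
#' @export
make_ligand <- function(kind = c("linear_chain", "ring", "fused_rings", "macrocycle"),
                        n = 6, n_residues = 10, seed = 0) {
  kind <- match.arg(kind)
  if (kind %in% c("linear_chain", "ring") && n < ifelse(kind == "ring", 3, 2)) {
    stop("atom count too small for kind ", kind)
  }
  bl <- 1.5
  if (kind == "linear_chain") {
    # zigzag in the xy-plane: 1.5 A bonds, 120 degree 3D angles
    xyz <- matrix(0, n, 3)
    dirs <- rep(c(30, -30), length.out = n - 1)
    for (i in seq_len(n - 1)) {
      step <- bl * c(cos(deg2rad(dirs[i])), sin(deg2rad(dirs[i])), 0)
      xyz[i + 1, ] <- xyz[i, ] + step
    }
    names_ <- paste0("C", seq_len(n))
    comp <- format_component("CHN",
      data.frame(name = names_, element = "C"),
      data.frame(a1 = names_[-n], a2 = names_[-1], order = "single"))
    atoms <- ligand_atom_df(names_, "C", xyz, "CHN")
    return(fixture_result(atoms, NULL, list(CHN = comp), kind, seed))
  }
  if (kind == "ring") {
    r <- bl / (2 * sin(pi / n))
    ang <- 2 * pi * (seq_len(n) - 1) / n
    xyz <- cbind(r * cos(ang), r * sin(ang), 0)
    names_ <- paste0("C", seq_len(n))
    ord <- if (n == 6) "aromatic" else "single"
    comp <- format_component("RNG",
      data.frame(name = names_, element = "C"),
      data.frame(a1 = names_, a2 = names_[c(2:n, 1)], order = ord))
    atoms <- ligand_atom_df(names_, "C", xyz, "RNG")
    return(fixture_result(atoms, NULL, list(RNG = comp), kind, seed))
  }
  if (kind == "fused_rings") {
    # naphthalene-like: two hexagons sharing an edge; 10 atoms, 11 bonds
    a6 <- deg2rad(30 + 60 * (0:5))
    ring_a <- cbind(bl * cos(a6), bl * sin(a6), 0)
    mirror_x <- bl * cos(deg2rad(30))
    shared <- which(abs(ring_a[, 1] - mirror_x) < 1e-9)
    others <- setdiff(seq_len(6), shared)
    ring_b_new <- ring_a[others, , drop = FALSE]
    ring_b_new[, 1] <- 2 * mirror_x - ring_b_new[, 1]
    xyz <- rbind(ring_a, ring_b_new)
    names_ <- paste0("C", seq_len(10))
    edge <- function(i, j) data.frame(a1 = names_[i], a2 = names_[j], order = "aromatic")
    # ring A cycle in angular order; ring B cycle via shared edge
    ordA <- order(atan2(ring_a[, 2], ring_a[, 1]))
    bonds <- do.call(rbind, lapply(seq_len(6), function(k) {
      edge(ordA[k], ordA[k %% 6 + 1])
    }))
    # ring B: shared vertices + mirrored others, ordered by angle about ring B centre
    bc <- c(2 * mirror_x, 0)
    bidx <- c(shared, 6 + seq_along(others))
    bang <- atan2(xyz[bidx, 2] - bc[2], xyz[bidx, 1] - bc[1])
    ordB <- bidx[order(bang)]
    for (k in seq_len(6)) {
      i <- ordB[k]; j <- ordB[k %% 6 + 1]
      if (!(i %in% shared && j %in% shared)) bonds <- rbind(bonds, edge(i, j))
    }
    comp <- format_component("FUS", data.frame(name = names_, element = "C"), bonds)
    atoms <- ligand_atom_df(names_, "C", xyz, "FUS")
    return(fixture_result(atoms, NULL, list(FUS = comp), kind, seed))
  }
  # macrocycle: n_residues residues of N-CA-C on a large circle, closed
  # head-to-tail by a LINK record
  if (n_residues < 4) stop("macrocycle needs >= 4 residues")
  total <- 3L * n_residues
  r <- bl / (2 * sin(pi / total))
  ang <- 2 * pi * (seq_len(total) - 1) / total
  xyz <- cbind(r * cos(ang), r * sin(ang), 0)
  res_seq <- rep(seq_len(n_residues), each = 3)
  names_ <- rep(c("N", "CA", "C"), n_residues)
  elems <- rep(c("N", "C", "C"), n_residues)
  atoms <- data.frame(
    serial = seq_len(total), name = names_, alt_loc = " ", res_name = "MMA",
    chain = "B", res_seq = res_seq, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = elems, is_het = TRUE, is_water = FALSE,
    stringsAsFactors = FALSE
  )
  links <- data.frame(
    name1 = "C", res_name1 = "MMA", chain1 = "B", res_seq1 = seq_len(n_residues),
    name2 = "N", res_name2 = "MMA", chain2 = "B",
    res_seq2 = c(seq_len(n_residues)[-1], 1L),
    distance = bl, stringsAsFactors = FALSE
  )
  comp <- format_component("MMA",
    data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C")),
    data.frame(a1 = c("N", "CA"), a2 = c("CA", "C"), order = "single"))
  fixture_result(atoms, links, list(MMA = comp), "macrocycle", seed)
}

ligand_atom_df <- function(names_, elements, xyz, res_name,
                           chain = "L", res_seq = 1L, serial0 = 0L, het = TRUE) {
  data.frame(
    serial = serial0 + seq_along(names_), name = names_, alt_loc = " ",
    res_name = res_name, chain = chain, res_seq = res_seq,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = rep(elements, length.out = length(names_)),
    is_het = het, is_water = FALSE, stringsAsFactors = FALSE
  )
}

fixture_result <- function(atoms, links, components, kind, seed) {
  if (is.null(links)) {
    links <- data.frame(name1 = character(), res_name1 = character(),
                        chain1 = character(), res_seq1 = integer(),
                        name2 = character(), res_name2 = character(),
                        chain2 = character(), res_seq2 = integer(),
                        distance = numeric(), stringsAsFactors = FALSE)
  }
  struct <- structure(list(
    atoms = atoms, links = links,
    conect = matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b"))),
    helix = data.frame(chain = character(), first = integer(), last = integer()),
    sheet = data.frame(chain = character(), first = integer(), last = integer())
  ), class = "pdb_structure")
  # `struct` carries full-precision coordinates; the PDB text is quantized
  # to the format's 3 decimals
  list(pdb = write_pdb(struct), struct = struct, components = components,
       spec = list(kind = kind, seed = seed))
}

#' Generate a synthetic binding-site PDB around a probe ligand
#'
#' Builds a HETATM probe ligand (C2-C1=O1: a carbonyl acceptor on a short
#' chain) surrounded by the requested environment, each feature realising its
#' stated geometry exactly:
#' \itemize{
#'   \item `shells`: pseudo-residues whose closest heavy atom sits at exactly
#'     the given minimum distance from the ligand.
#'   \item `waters`: water chains of the given lengths bridging the ligand
#'     acceptor O1 to a distinct serine-like residue, with every consecutive
#'     step at `water_step` angstrom.
#'   \item `hbonds`: donor residues whose N sits at the given donor-acceptor
#'     distance from O1 with the given (D, A, aa) angle (aa = C1, the
#'     acceptor's only neighbour).
#'   \item `covalent_link`: a cysteine-like residue whose SG is joined to
#'     ligand C2 through a LINK record.
#' }
#'
#' @param shells list of `list(res =, dist =)` entries (or two-column
#'   data frame) giving residue name and minimum heavy-atom distance in
#'   angstrom.
#' @param waters integer vector of bridge lengths (waters per bridge).
#' @param hbonds list of `c(distance, angle)` pairs (angstrom, degrees).
#' @param covalent_link logical; add the LINKed cysteine.
#' @param water_step angstrom between consecutive atoms along a water chain.
#' @param water_first_leg optional angstrom override for the ligand-to-first-
#'   water distance (subsequent steps stay at `water_step`).
#' @param seed fixture seed (recorded; generation is deterministic).
#' @return list with `pdb`, `components` (named list incl. the ligand
#'   component `PRB`), and `info` describing the designated residues
#'   (shell/bridge/donor residue ids).
#' @export
make_site <- function(shells = list(), waters = integer(), hbonds = list(),
                      covalent_link = FALSE, water_step = 3.0,
                      water_first_leg = NULL, seed = 0) {
  if (is.data.frame(shells)) shells <- lapply(seq_len(nrow(shells)), function(i) {
    list(res = shells$res[i], dist = shells$dist[i])
  })
  stopifnot(all(vapply(shells, function(s) s$dist > 0, TRUE)),
            all(waters >= 1), water_step > 0)

  lig_names <- c("C2", "C1", "O1")
  lig_xyz <- rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.23, 0, 0))
  atoms <- ligand_atom_df(lig_names, c("C", "C", "O"), lig_xyz, "PRB")
  o1 <- lig_xyz[3, ]
  # hydrogens live only in the definition (not in coordinates); their
  # presence makes the carbonyl O1 type as acceptor-only
  comp_prb <- format_component("PRB",
    data.frame(name = c(lig_names, "H21", "H22", "H23"),
               element = c("C", "C", "O", "H", "H", "H")),
    data.frame(a1 = c("C2", "C1", "C2", "C2", "C2"),
               a2 = c("C1", "O1", "H21", "H22", "H23"),
               order = c("single", "double", "single", "single", "single")))
  links <- NULL
  info <- list(shell_residues = list(), bridge_residues = list(),
               donor_residues = list())
  serial <- 3L
  seq_a <- 0L

  add_res <- function(res_name, names_, elems, xyz, chain = "A", het = FALSE) {
    seq_a <<- seq_a + 1L
    df <- ligand_atom_df(names_, elems, xyz, res_name, chain = chain,
                         res_seq = seq_a, serial0 = serial, het = het)
    serial <<- serial + length(names_)
    atoms <<- rbind(atoms, df)
    list(res_name = res_name, chain = chain, res_seq = seq_a)
  }

  # shells: in-plane directions, 55 degrees apart
  for (i in seq_along(shells)) {
    sh <- shells[[i]]
    u <- dir_vec(55 * (i - 1), 0)
    ref <- extreme_atom(atoms[atoms$res_name == "PRB", ], u)
    p0 <- ref + sh$dist * u
    xyz <- rbind(p0, p0 + 1.5 * u, p0 + 3.0 * u)
    id <- add_res(sh$res, c("N", "CA", "CB"), c("N", "C", "C"), xyz)
    info$shell_residues[[i]] <- c(id, dist = sh$dist)
  }

  # hydrogen-bond donors: angle measured at O1 against its neighbour C1
  for (i in seq_along(hbonds)) {
    hb <- hbonds[[i]]
    d <- hb[[1]]; theta <- hb[[2]]
    u1 <- c(-1, 0, 0)                       # O1 -> C1
    az <- deg2rad(75 * (i - 1))
    u2 <- c(0, cos(az), sin(az))
    dpos <- o1 + d * (cos(deg2rad(theta)) * u1 + sin(deg2rad(theta)) * u2)
    outward <- unit3(dpos - o1)
    xyz <- rbind(dpos, dpos + 1.5 * outward)
    id <- add_res("DNR", c("N", "CA"), c("N", "C"), xyz)
    info$donor_residues[[i]] <- c(id, dist = d, angle = theta)
  }

  # water bridges: cone directions alternating above/below the ligand plane
  w_seq <- 0L
  for (i in seq_along(waters)) {
    k <- waters[i]
    u <- dir_vec(60 * (i - 1) + 25, if (i %% 2 == 0) -35 else 35)
    pos <- o1
    for (j in seq_len(k)) {
      step_j <- if (j == 1L && !is.null(water_first_leg)) water_first_leg else water_step
      pos <- pos + step_j * u
      w_seq <- w_seq + 1L
      df <- ligand_atom_df("O", "O", matrix(pos, 1), "HOH", chain = "W",
                           res_seq = w_seq, serial0 = serial, het = TRUE)
      df$is_water <- TRUE
      serial <- serial + 1L
      atoms <- rbind(atoms, df)
    }
    term <- pos + water_step * u
    xyz <- rbind(term, term + 1.5 * u)
    id <- add_res("SER", c("OG", "CA"), c("O", "C"), xyz)
    info$bridge_residues[[i]] <- c(id, n_waters = k)
  }

  if (covalent_link) {
    u <- c(-1, 0, 0)
    sg <- c(-1.5, 0, 0) + 1.8 * u
    xyz <- rbind(sg, sg + 1.5 * u)
    id <- add_res("CYS", c("SG", "CB"), c("S", "C"), xyz)
    links <- data.frame(
      name1 = "C2", res_name1 = "PRB", chain1 = "L", res_seq1 = 1L,
      name2 = "SG", res_name2 = "CYS", chain2 = id$chain, res_seq2 = id$res_seq,
      distance = 1.8, stringsAsFactors = FALSE
    )
    info$covalent_residue <- id
  }

  atoms$serial <- seq_len(nrow(atoms))
  out <- fixture_result(atoms, links, list(PRB = comp_prb), "site", seed)
  out$info <- info
  validate_site(out, shells, waters, hbonds, water_step)
  out
}

unit3 <- function(v) v / vnorm(v)

dir_vec <- function(az_deg, el_deg) {
  az <- deg2rad(az_deg); el <- deg2rad(el_deg)
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

extreme_atom <- function(lig_atoms, u) {
  proj <- as.matrix(lig_atoms[, c("x", "y", "z")]) %*% u
  as.numeric(lig_atoms[which.max(proj), c("x", "y", "z")])
}

# Re-measures every requested geometric constraint on the generated
# structure (full-precision coordinates); refuses to emit a fixture that
# does not realise its request.
validate_site <- function(out, shells, waters, hbonds, water_step) {
  s <- out$struct
  lig <- s$atoms[s$atoms$res_name == "PRB", ]
  ligm <- as.matrix(lig[, c("x", "y", "z")])
  for (i in seq_along(shells)) {
    id <- out$info$shell_residues[[i]]
    ra <- s$atoms[s$atoms$chain == id$chain & s$atoms$res_seq == id$res_seq, ]
    dmin <- min(cross_dist(ligm, as.matrix(ra[, c("x", "y", "z")])))
    if (abs(dmin - shells[[i]]$dist) > 1e-6) {
      stop(sprintf("unrealizable shell %d: wanted %.6f got %.6f", i,
                   shells[[i]]$dist, dmin))
    }
  }
  for (i in seq_along(hbonds)) {
    id <- out$info$donor_residues[[i]]
    dn <- s$atoms[s$atoms$chain == id$chain & s$atoms$res_seq == id$res_seq &
                    s$atoms$name == "N", ]
    o1 <- as.numeric(lig[lig$name == "O1", c("x", "y", "z")])
    c1 <- as.numeric(lig[lig$name == "C1", c("x", "y", "z")])
    dpos <- as.numeric(dn[, c("x", "y", "z")])
    if (abs(dist3(dpos, o1) - hbonds[[i]][[1]]) > 1e-6 ||
        abs(angle_at(o1, dpos, c1) - hbonds[[i]][[2]]) > 1e-4) {
      stop("unrealizable hbond geometry ", i)
    }
  }
  invisible(out)
}

cross_dist <- function(m1, m2) {
  outer(seq_len(nrow(m1)), seq_len(nrow(m2)),
        Vectorize(function(i, j) dist3(m1[i, ], m2[j, ])))
}
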