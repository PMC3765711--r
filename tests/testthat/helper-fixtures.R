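# Shared fixture builders and independent oracles. Oracles deliberately use
# their own plain-loop code paths so they can stand as cross-checks for the
# package implementations.

# --- constructors for hand-built graphs/layouts -----------------------------

mk_graph <- function(pos3, edges, elements = NULL, names_ = NULL, elems = NULL) {
  n <- nrow(pos3)
  atoms <- data.frame(
    serial = seq_len(n),
    name = names_ %||% paste0("C", seq_len(n)),
    alt_loc = " ", res_name = "LIG", chain = "L", res_seq = 1L,
    x = pos3[, 1], y = pos3[, 2], z = if (ncol(pos3) >= 3) pos3[, 3] else 0,
    occupancy = 1, element = elems %||% rep("C", n),
    is_het = TRUE, is_water = FALSE, idx = seq_len(n),
    stringsAsFactors = FALSE)
  e <- if (length(edges)) {
    data.frame(i = vapply(edges, `[[`, 0L, 1L), j = vapply(edges, `[[`, 0L, 2L),
               order = "single", stringsAsFactors = FALSE)
  } else data.frame(i = integer(), j = integer(), order = character())
  structure(list(atoms = atoms, edges = e), class = "molecular_graph")
}

mk_layout <- function(pos2, graph, config = layout_config()) {
  structure(list(pos = pos2, graph = graph,
                 elements = partition_elements(graph), config = config),
            class = "layout2d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two unbonded atoms at separation d in 2D
pair_layout <- function(d) {
  g <- mk_graph(rbind(c(0, 0, 0), c(d, 0, 0)), list())
  mk_layout(rbind(c(0, 0), c(d, 0)), g)
}

# branched ligand: 6-atom chain, a 5-ring hanging off atom 4, two terminal
# oxygens; exercises ring + chain + terminal partitioning together
branched_fixture <- function() {
  bl <- 1.5
  chain <- t(sapply(0:5, function(i) c(i * bl, 0, 0)))
  ring_ctr <- c(3 * bl, 2.2, 0)
  rr <- bl / (2 * sin(pi / 5))
  ring <- t(sapply(0:4, function(k) ring_ctr + c(rr * cos(pi / 2 + 2 * pi * k / 5),
                                                 rr * sin(pi / 2 + 2 * pi * k / 5), 0)))
  ring[1, ] <- chain[4, ] + c(0, bl, 0)   # ring attachment atom
  ox <- rbind(chain[6, ] + c(bl, 0.2, 0), chain[6, ] + c(0.5, -1.4, 0))
  pos <- rbind(chain, ring, ox)
  edges <- c(lapply(1:5, function(i) c(i, i + 1L)),
             list(c(4L, 7L)),
             lapply(0:4, function(k) c(7L + k, 7L + (k + 1L) %% 5L)),
             list(c(6L, 12L), c(6L, 13L)))
  nm <- c(paste0("C", 1:6), paste0("R", 1:5), "O1", "O2")
  el <- c(rep("C", 11), "O", "O")
  mk_graph(pos, edges, names_ = nm, elems = el)
}

parsed_components <- function(fx) lapply(fx$components, parse_component)

# --- oracle: minimal cycle basis by exhaustive cycle enumeration ------------

oracle_cycle_basis <- function(graph) {
  n <- nrow(graph$atoms)
  stopifnot(n <= 14)
  adj <- lapply(seq_len(n), function(i) {
    sort(c(graph$edges$j[graph$edges$i == i], graph$edges$i[graph$edges$j == i]))
  })
  cycles <- list()
  # enumerate simple cycles whose smallest vertex is the start
  for (v in seq_len(n)) {
    stack <- list(v)
    dfs <- function(path) {
      cur <- path[length(path)]
      for (nx in adj[[cur]]) {
        if (nx == v && length(path) >= 3) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (nx > v && !(nx %in% path)) {
          dfs(c(path, nx))
        }
      }
    }
    dfs(v)
  }
  if (!length(cycles)) return(list())
  sig <- vapply(cycles, function(cc) paste(sort(cc), collapse = ","), "")
  cycles <- cycles[!duplicated(sig)]
  ekey <- paste(graph$edges$i, graph$edges$j, sep = "-")
  to_bits <- function(cc) {
    b <- logical(nrow(graph$edges))
    k <- length(cc)
    for (m in seq_len(k)) {
      a <- cc[m]; d <- cc[m %% k + 1]
      b[match(paste(min(a, d), max(a, d), sep = "-"), ekey)] <- TRUE
    }
    b
  }
  ord <- order(vapply(cycles, length, 0L))
  cycles <- cycles[ord]
  basis <- list(); piv <- integer(); chosen <- list()
  for (cc in cycles) {
    red <- to_bits(cc)
    for (r in seq_along(basis)) if (red[piv[r]]) red <- xor(red, basis[[r]])
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      piv <- c(piv, which(red)[1])
      chosen[[length(chosen) + 1L]] <- cc
    }
  }
  chosen
}

# --- oracle: interaction detection by plain exhaustive loops ----------------

oracle_dist <- function(a, i, j) {
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

oracle_da_flags <- function(a, rows, comps) {
  t(vapply(rows, function(r) {
    el <- a$element[r]
    if (!el %in% c("N", "O", "S")) return(c(FALSE, FALSE))
    if (el == "S") return(c(TRUE, TRUE))
    comp <- comps[[a$res_name[r]]]
    if (is.null(comp) || !any(comp$atoms$element == "H")) return(c(TRUE, TRUE))
    nb <- c(comp$bonds$a2[comp$bonds$a1 == a$name[r]],
            comp$bonds$a1[comp$bonds$a2 == a$name[r]])
    nh <- sum(comp$atoms$element[match(nb, comp$atoms$name)] == "H")
    if (el == "O") c(nh >= 1, TRUE) else c(nh >= 1, nh == 0)
  }, c(d = FALSE, a = FALSE)))
}

oracle_nearby <- function(struct, lig_rows, cutoff = 4.0) {
  a <- struct$atoms
  env <- setdiff(which(!a$is_het & !a$is_water & a$element != "H"), lig_rows)
  keys <- unique(paste(a$chain[env], a$res_seq[env], sep = "|"))
  out <- list()
  for (k in keys) {
    rows <- env[paste(a$chain[env], a$res_seq[env], sep = "|") == k]
    dm <- Inf
    for (i in lig_rows) for (j in rows) dm <- min(dm, oracle_dist(a, i, j))
    if (dm <= cutoff) out[[k]] <- dm
  }
  out
}

oracle_hbonds <- function(struct, lig_rows, comps, cutoff = 3.3, amax = 90,
                          rescut = 4.0) {
  a <- struct$atoms
  nb <- oracle_nearby(struct, lig_rows, max(rescut, cutoff))
  env <- which(!a$is_het & !a$is_water & a$element != "H" &
                 paste(a$chain, a$res_seq, sep = "|") %in% names(nb))
  env <- setdiff(env, lig_rows)
  fl <- oracle_da_flags(a, lig_rows, comps)
  fe <- oracle_da_flags(a, env, comps)
  cov_nbrs <- function(r, pool) {
    Filter(function(q) {
      thr <- if (a$element[r] == "S" || a$element[q] == "S") 2.4 else 1.9
      oracle_dist(a, r, q) < thr
    }, setdiff(pool, r))
  }
  found <- list()
  for (li in seq_along(lig_rows)) for (ei in seq_along(env)) {
    d <- oracle_dist(a, lig_rows[li], env[ei])
    if (d > cutoff) next
    for (dir in 1:2) {
      ok <- if (dir == 1) fl[li, 1] && fe[ei, 2] else fe[ei, 1] && fl[li, 2]
      if (!ok) next
      drow <- if (dir == 1) lig_rows[li] else env[ei]
      arow <- if (dir == 1) env[ei] else lig_rows[li]
      pool <- if (dir == 1) env else lig_rows
      aa <- cov_nbrs(arow, pool)
      pass <- !length(aa)
      if (length(aa)) {
        angs <- vapply(aa, function(q) {
          u <- c(a$x[drow] - a$x[arow], a$y[drow] - a$y[arow], a$z[drow] - a$z[arow])
          v <- c(a$x[q] - a$x[arow], a$y[q] - a$y[arow], a$z[q] - a$z[arow])
          acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        }, 0)
        pass <- min(angs) < amax
      }
      if (pass) found[[paste(min(drow, arow), max(drow, arow))]] <- d
    }
  }
  found
}

oracle_bridges <- function(struct, lig_rows, comps, radius = 3.3, maxw = 4) {
  a <- struct$atoms
  waters <- which(a$is_water & a$element == "O")
  fl <- oracle_da_flags(a, lig_rows, comps)
  lig_da <- lig_rows[fl[, 1] | fl[, 2]]
  env <- setdiff(which(!a$is_het & !a$is_water & a$element != "H"), lig_rows)
  fe <- oracle_da_flags(a, env, comps)
  env_da <- env[fe[, 1] | fe[, 2]]
  found <- character()
  seqs <- list(lapply(waters, function(w) w))
  # all ordered water sequences up to length maxw (waters are few in oracle
  # fixtures)
  all_seqs <- lapply(waters, function(w) c(w))
  if (maxw >= 2) for (len in 2:maxw) {
    new <- list()
    for (s in all_seqs[vapply(all_seqs, length, 0L) == len - 1L]) {
      for (w in setdiff(waters, s)) new[[length(new) + 1L]] <- c(s, w)
    }
    all_seqs <- c(all_seqs, new)
  }
  for (lrow in lig_da) for (erow in env_da) for (s in all_seqs) {
    pts <- c(lrow, s, erow)
    ok <- TRUE
    for (m in seq_len(length(pts) - 1L)) {
      if (oracle_dist(a, pts[m], pts[m + 1L]) > radius) { ok <- FALSE; break }
    }
    if (ok) found <- c(found, paste(lrow, paste(s, collapse = ","), erow))
  }
  sort(unique(found))
}
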