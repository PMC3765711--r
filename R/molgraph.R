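# The ligand as an undirected labelled graph: nodes are atoms (labels =
# atom name, element), edges are chemical bonds with an order. Bond orders
# come from the residue's component definition through an atom-name mapping,
# with an element-labelled isomorphism fallback for renamed atoms and a
# distance fallback for residues with no definition at all.

CHAIN_ELEMENTS <- c("C", "N", "O", "S")
MACROCYCLE_MIN <- 10L

#' Build the molecular graph of a ligand
#'
#' Intra-residue bonds and orders are copied from the residue's component
#' definition by atom-name mapping; hydrogens present only in the definition
#' are dropped. When atom names do not all match, an element-labelled
#' subgraph-isomorphism between the geometry-inferred residue graph and the
#' definition recovers the mapping. Inter-residue bonds come from LINK and
#' CONECT records and from heavy-atom pairs at covalent distance, with order
#' single.
#'
#' @param ligand a `ligand_instance`.
#' @param struct the parsed `pdb_structure`.
#' @param components named list of `component_def` keyed by residue name.
#' @param distance_fallback infer bonds from interatomic distances when a
#'   residue has no component definition (default TRUE; if FALSE, error).
#' @return a `molecular_graph`: list with `atoms` (data frame incl. original
#'   row index `idx`), `edges` (data frame: i, j, order; indices into
#'   `atoms`).
#' @export
build_graph <- function(ligand, struct, components = list(),
                        distance_fallback = TRUE) {
  at <- struct$atoms[ligand$atom_idx, , drop = FALSE]
  at$idx <- ligand$atom_idx
  rownames(at) <- NULL
  rk <- residue_key(at)
  edges <- list()

  for (key in unique(rk)) {
    rows <- which(rk == key)
    res_name <- at$res_name[rows[1]]
    comp <- components[[res_name]]
    if (is.null(comp)) {
      if (!distance_fallback) {
        stop(sprintf("no component definition for residue %s and distance fallback disabled",
                     res_name))
      }
      edges[[length(edges) + 1L]] <- distance_bonds(at, rows)
      next
    }
    mapped <- map_component(at, rows, comp)
    if (is.null(mapped)) {
      if (!distance_fallback) {
        stop(sprintf("cannot map residue %s onto its component definition", res_name))
      }
      warning(sprintf("residue %s: no name or isomorphism mapping; using distance bonds",
                      res_name))
      mapped <- distance_bonds(at, rows)
    }
    edges[[length(edges) + 1L]] <- mapped
  }

  # inter-residue bonds: LINK, CONECT, then covalent-distance pairs
  if (nrow(struct$links)) {
    for (i in seq_len(nrow(struct$links))) {
      l <- struct$links[i, ]
      i1 <- which(at$chain == l$chain1 & at$res_seq == l$res_seq1 &
                    at$res_name == l$res_name1 & at$name == l$name1)
      i2 <- which(at$chain == l$chain2 & at$res_seq == l$res_seq2 &
                    at$res_name == l$res_name2 & at$name == l$name2)
      if (length(i1) == 1L && length(i2) == 1L) {
        edges[[length(edges) + 1L]] <- data.frame(i = i1, j = i2, order = "single")
      }
    }
  }
  if (nrow(struct$conect)) {
    m <- struct$conect[struct$conect[, 1] < struct$conect[, 2], , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      i1 <- match(m[r, 1], at$serial)
      i2 <- match(m[r, 2], at$serial)
      if (!is.na(i1) && !is.na(i2)) {
        edges[[length(edges) + 1L]] <- data.frame(i = i1, j = i2, order = "single")
      }
    }
  }
  if (length(unique(rk)) > 1L) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    dd <- as.matrix(stats::dist(xyz))
    for (i in seq_len(nrow(at) - 1L)) {
      for (j in seq(i + 1L, nrow(at))) {
        if (rk[i] == rk[j]) next
        thr <- if (at$element[i] == "S" || at$element[j] == "S")
          COVALENT_DIST_S else COVALENT_DIST
        if (dd[i, j] < thr) {
          edges[[length(edges) + 1L]] <- data.frame(i = i, j = j, order = "single")
        }
      }
    }
  }

  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(i = integer(), j = integer(), order = character())
  if (nrow(e)) {
    swap <- e$i > e$j
    tmp <- e$i[swap]; e$i[swap] <- e$j[swap]; e$j[swap] <- tmp
    e <- e[!duplicated(e[, c("i", "j")]) & e$i != e$j, , drop = FALSE]
    e <- e[order(e$i, e$j), , drop = FALSE]
    rownames(e) <- NULL
  }
  structure(list(atoms = at, edges = e), class = "molecular_graph")
}

# Bonds from the component by atom-name mapping; NULL when names do not all
# match and the isomorphism fallback fails too.
map_component <- function(at, rows, comp) {
  nm <- at$name[rows]
  heavy_comp <- comp$atoms[comp$atoms$element != "H", , drop = FALSE]
  if (all(nm %in% comp$atoms$name)) {
    b <- comp$bonds[comp$bonds$a1 %in% nm & comp$bonds$a2 %in% nm, , drop = FALSE]
    if (!nrow(b)) return(empty_edges())
    return(data.frame(i = rows[match(b$a1, nm)], j = rows[match(b$a2, nm)],
                      order = b$order, stringsAsFactors = FALSE))
  }
  # element-labelled isomorphism between the geometry graph and the
  # definition's heavy-atom graph
  if (length(rows) != nrow(heavy_comp)) return(NULL)
  geo <- distance_bonds(at, rows)
  g1 <- igraph::make_graph(edges = rbind(match(geo$i, rows), match(geo$j, rows)),
                           n = length(rows), directed = FALSE)
  hb <- comp$bonds[comp$bonds$a1 %in% heavy_comp$name &
                     comp$bonds$a2 %in% heavy_comp$name, , drop = FALSE]
  g2 <- igraph::make_graph(edges = rbind(match(hb$a1, heavy_comp$name),
                                         match(hb$a2, heavy_comp$name)),
                           n = nrow(heavy_comp), directed = FALSE)
  elems <- sort(unique(c(at$element[rows], heavy_comp$element)))
  col1 <- match(at$element[rows], elems)
  col2 <- match(heavy_comp$element, elems)
  iso <- tryCatch(
    igraph::isomorphisms(g1, g2, method = "vf2", vertex.color1 = col1,
                         vertex.color2 = col2),
    error = function(e) list())
  if (!length(iso)) return(NULL)
  mp <- as.integer(iso[[1]])  # graph-node k (residue atom) -> comp heavy atom mp[k]
  comp_to_row <- rows[match(seq_along(mp), mp)]
  if (!nrow(hb)) return(empty_edges())
  data.frame(i = comp_to_row[match(hb$a1, heavy_comp$name)],
             j = comp_to_row[match(hb$a2, heavy_comp$name)],
             order = hb$order, stringsAsFactors = FALSE)
}

empty_edges <- function() data.frame(i = integer(), j = integer(),
                                     order = character(), stringsAsFactors = FALSE)

# canonical orientation (i < j) regardless of how the edges were supplied
normalise_edges <- function(e) {
  swap <- e$i > e$j
  if (any(swap)) {
    tmp <- e$i[swap]; e$i[swap] <- e$j[swap]; e$j[swap] <- tmp
  }
  e
}

distance_bonds <- function(at, rows) {
  if (length(rows) < 2L) return(empty_edges())
  xyz <- as.matrix(at[rows, c("x", "y", "z")])
  dd <- as.matrix(stats::dist(xyz))
  out <- list()
  for (i in seq_len(length(rows) - 1L)) {
    for (j in seq(i + 1L, length(rows))) {
      thr <- if (at$element[rows[i]] == "S" || at$element[rows[j]] == "S")
        COVALENT_DIST_S else COVALENT_DIST
      if (dd[i, j] < thr) {
        out[[length(out) + 1L]] <- data.frame(i = rows[i], j = rows[j],
                                              order = "single")
      }
    }
  }
  if (!length(out)) return(empty_edges())
  do.call(rbind, out)
}

as_igraph <- function(graph) {
  igraph::make_graph(edges = rbind(graph$edges$i, graph$edges$j),
                     n = nrow(graph$atoms), directed = FALSE)
}

graph_degree <- function(graph) {
  deg <- integer(nrow(graph$atoms))
  for (k in seq_len(nrow(graph$edges))) {
    deg[graph$edges$i[k]] <- deg[graph$edges$i[k]] + 1L
    deg[graph$edges$j[k]] <- deg[graph$edges$j[k]] + 1L
  }
  deg
}

adjacency_list <- function(graph) {
  adj <- vector("list", nrow(graph$atoms))
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d atoms, %d bonds\n",
              nrow(x$atoms), nrow(x$edges)))
  invisible(x)
}

#' Perceive the smallest set of smallest rings
#'
#' Returns a minimal cycle basis of the molecular graph: exactly
#' E - V + C rings (C = connected components), each among the smallest
#' cycles available. Candidate cycles are generated from per-vertex
#' shortest-path trees and selected greedily in order of length under
#' GF(2) independence, with deterministic tie-breaking by member atom
#' serials.
#'
#' @param graph a `molecular_graph`.
#' @return list of rings; each ring is an integer vector of atom indices in
#'   cyclic order.
#' @export
perceive_sssr <- function(graph) {
  graph$edges <- normalise_edges(graph$edges)
  nE <- nrow(graph$edges)
  nV <- nrow(graph$atoms)
  if (!nE) return(list())
  g <- as_igraph(graph)
  nC <- igraph::components(g)$no
  n_rings <- nE - nV + nC
  if (n_rings <= 0L) return(list())

  ekey <- paste(graph$edges$i, graph$edges$j, sep = "-")
  edge_id <- function(i, j) match(paste(min(i, j), max(i, j), sep = "-"), ekey)

  # Horton candidates: shortest paths from v to edge endpoints
  cands <- list()
  for (v in seq_len(nV)) {
    sp <- igraph::shortest_paths(g, from = v, to = igraph::V(g), mode = "all")
    paths <- lapply(sp$vpath, as.integer)
    for (k in seq_len(nE)) {
      x <- graph$edges$i[k]; y <- graph$edges$j[k]
      px <- paths[[x]]; py <- paths[[y]]
      if (!length(px) || !length(py)) next
      if (length(intersect(px, py)) != 1L) next  # must share only v
      verts <- c(px, rev(py)[-length(py)])       # v..x, y..(v excluded)
      if (length(verts) < 3L) next
      cyc_edges <- integer(length(verts))
      for (m in seq_along(verts)) {
        a <- verts[m]; b <- verts[m %% length(verts) + 1L]
        cyc_edges[m] <- edge_id(a, b)
      }
      if (any(is.na(cyc_edges))) next
      bits <- logical(nE); bits[cyc_edges] <- TRUE
      cands[[length(cands) + 1L]] <- list(verts = verts, bits = bits,
                                          len = length(verts))
    }
  }
  if (!length(cands)) return(list())
  sig <- vapply(cands, function(cc) paste(sort(cc$verts), collapse = ","), "")
  keep <- !duplicated(sig)
  cands <- cands[keep]
  serial_key <- vapply(cands, function(cc)
    paste(formatC(sort(graph$atoms$serial[cc$verts]), width = 8, flag = "0"),
          collapse = ","), "")
  ord <- order(vapply(cands, `[[`, 0L, "len"), serial_key)
  cands <- cands[ord]

  # greedy GF(2)-independent selection
  basis <- matrix(FALSE, nrow = 0, ncol = nE)
  pivots <- integer()
  rings <- list()
  for (cc in cands) {
    vec <- cc$bits
    red <- vec
    for (r in seq_len(nrow(basis))) {
      if (red[pivots[r]]) red <- xor(red, basis[r, ])
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      pivots <- c(pivots, which(red)[1])
      rings[[length(rings) + 1L]] <- order_ring(cc$verts, graph)
      if (length(rings) == n_rings) break
    }
  }
  rings[order(vapply(rings, length, 0L),
              vapply(rings, function(r) min(graph$atoms$serial[r]), 0))]
}

# return ring vertices in cyclic order starting from the smallest serial
order_ring <- function(verts, graph) {
  sub <- graph$edges[graph$edges$i %in% verts & graph$edges$j %in% verts, ]
  adj <- list()
  for (k in seq_len(nrow(sub))) {
    a <- as.character(sub$i[k]); b <- as.character(sub$j[k])
    adj[[a]] <- c(adj[[a]], sub$j[k]); adj[[b]] <- c(adj[[b]], sub$i[k])
  }
  start <- verts[which.min(graph$atoms$serial[verts])]
  ordered <- start
  prev <- -1L
  cur <- start
  repeat {
    nbrs <- setdiff(intersect(adj[[as.character(cur)]], verts), prev)
    nbrs <- setdiff(nbrs, if (length(ordered) < length(verts)) ordered[1] else integer())
    if (!length(nbrs)) break
    nxt <- nbrs[which.min(graph$atoms$serial[nbrs])]
    if (nxt %in% ordered) break
    ordered <- c(ordered, nxt)
    prev <- cur
    cur <- nxt
    if (length(ordered) == length(verts)) break
  }
  ordered
}

#' Flag macro-cycles among perceived rings
#'
#' A ring with at least `threshold` atoms (default 10) is flagged as a
#' macro-cycle; macro-cycles are drawn first, as one regular polygon.
#'
#' @param rings list of rings from [perceive_sssr()].
#' @param threshold minimum ring size.
#' @return the same list with a logical `is_macrocycle` attribute per ring.
#' @export
detect_macrocycles <- function(rings, threshold = MACROCYCLE_MIN) {
  lapply(rings, function(r) {
    attr(r, "is_macrocycle") <- length(r) >= threshold
    r
  })
}

#' Partition a ligand graph into structural elements
#'
#' Elements are: rings (the SSSR), chains of at least 3 connected
#' non-terminal C/N/O/S atoms outside rings, terminal atoms (degree 1) and
#' isolated atoms (everything left over). Chains are extracted longest
#' first.
#'
#' @param graph a `molecular_graph`.
#' @param rings perceived rings (pass through [detect_macrocycles()] to
#'   carry macro-cycle flags).
#' @return list of `structural_element`: list(kind, atoms, is_macrocycle).
#' @export
partition_elements <- function(graph, rings = NULL) {
  if (is.null(rings)) rings <- detect_macrocycles(perceive_sssr(graph))
  deg <- graph_degree(graph)
  n <- nrow(graph$atoms)
  ring_atoms <- unique(unlist(rings))
  elements <- lapply(rings, function(r) {
    structure(list(kind = "ring", atoms = as.integer(r),
                   is_macrocycle = isTRUE(attr(r, "is_macrocycle"))),
              class = "structural_element")
  })
  # order rings: macro-cycles first, then by size desc, then min serial
  if (length(elements)) {
    ord <- order(!vapply(elements, `[[`, TRUE, "is_macrocycle"),
                 -vapply(elements, function(e) length(e$atoms), 0L),
                 vapply(elements, function(e) min(graph$atoms$serial[e$atoms]), 0))
    elements <- elements[ord]
  }

  terminal <- which(deg == 1L)
  eligible <- setdiff(which(deg >= 2L & graph$atoms$element %in% CHAIN_ELEMENTS),
                      ring_atoms)
  adj <- adjacency_list(graph)
  chains <- list()
  remaining <- eligible
  while (length(remaining) >= 3L) {
    path <- longest_path(remaining, adj, graph$atoms$serial)
    if (length(path) < 3L) break
    chains[[length(chains) + 1L]] <- path
    remaining <- setdiff(remaining, path)
  }
  chains <- chains[order(-vapply(chains, length, 0L))]
  for (p in chains) {
    elements[[length(elements) + 1L]] <-
      structure(list(kind = "chain", atoms = as.integer(p), is_macrocycle = FALSE),
                class = "structural_element")
  }
  covered <- unique(c(ring_atoms, unlist(chains), terminal))
  isolated <- setdiff(seq_len(n), covered)
  for (a in isolated) {
    elements[[length(elements) + 1L]] <-
      structure(list(kind = "isolated_atom", atoms = a, is_macrocycle = FALSE),
                class = "structural_element")
  }
  for (a in terminal[!terminal %in% c(ring_atoms, unlist(chains))]) {
    elements[[length(elements) + 1L]] <-
      structure(list(kind = "terminal_atom", atoms = a, is_macrocycle = FALSE),
                class = "structural_element")
  }
  elements
}

# longest simple path within the vertex subset, deterministic (serial order);
# subsets here are small chain fragments, so exhaustive DFS is fine
longest_path <- function(subset, adj, serials) {
  best <- integer()
  subset <- subset[order(serials[subset])]
  dfs <- function(path, cur) {
    if (length(path) > length(best) ||
        (length(path) == length(best) && length(best) &&
         serials[path[1]] < serials[best[1]])) {
      if (length(path) > length(best)) best <<- path
    }
    nbrs <- intersect(adj[[cur]], subset)
    nbrs <- setdiff(nbrs, path)
    for (nx in nbrs[order(serials[nbrs])]) dfs(c(path, nx), nx)
  }
  for (v in subset) dfs(v, v)
  best
}

#' @export
print.structural_element <- function(x, ...) {
  cat(sprintf("<structural_element> %s (%d atoms)%s\n", x$kind,
              length(x$atoms), if (x$is_macrocycle) " [macrocycle]" else ""))
  invisible(x)
}
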