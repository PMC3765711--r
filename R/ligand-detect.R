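# Ligand and metal-ion detection. Candidate ligand residues are the HETATM
# residues that are not waters; residues joined by LINK/CONECT records or by
# inter-residue heavy-atom pairs at covalent distance merge into one
# composite ligand. Polymer residues covalently LINKed to a ligand are
# recorded as explicit residues, not ligand members.

COVALENT_DIST <- 1.9   # heavy-heavy bond inference threshold, angstrom
COVALENT_DIST_S <- 2.4 # when either atom is sulfur

#' Detect ligands and metal ions in a structure
#'
#' Non-water HETATM residues are candidate ligand residues. Residues
#' connected through LINK records, CONECT bonds or inter-residue heavy-atom
#' pairs within covalent distance (< 1.9 angstrom, 2.4 if sulfur is
#' involved) are merged into composite ligands. A single-atom residue whose
#' element is a common biological metal becomes a metal-ion ligand. Polymer
#' residues LINKed to a ligand are recorded as `explicit_residues`. HETATM
#' residues embedded in a polymer chain's residue range (modified polymer
#' residues) are not auto-detected; use [select_composite()] for those.
#'
#' @param struct a `pdb_structure`.
#' @return list of `ligand_instance` objects, each with `residues`
#'   (data frame: res_name, chain, res_seq), `atom_idx` (row indices into
#'   `struct$atoms`), `is_metal`, and `explicit_residues`.
#' @examples
#' fx <- make_site(shells = list(list(res = "ALA", dist = 3.9)))
#' detect_ligands(parse_pdb(fx$pdb))
#' @export
detect_ligands <- function(struct) {
  a <- struct$atoms
  cand <- which(a$is_het & !a$is_water & a$element != "H")
  if (!length(cand)) return(list())

  rkey <- residue_key(a)
  polymer_res <- unique(rkey[!a$is_het])
  # modified polymer residues: het residue inside a polymer chain's seq span
  poly_span <- by_chain_span(a[!a$is_het, , drop = FALSE])
  cand_res <- unique(rkey[cand])
  embedded <- vapply(cand_res, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    ch <- parts[1]; seq_ <- as.integer(parts[2])
    !is.null(poly_span[[ch]]) && seq_ >= poly_span[[ch]][1] && seq_ <= poly_span[[ch]][2]
  }, TRUE)
  cand_res <- cand_res[!embedded]
  if (!length(cand_res)) return(list())
  cand <- cand[rkey[cand] %in% cand_res]

  # residue-level merge graph
  g <- igraph::make_empty_graph(n = length(cand_res), directed = FALSE)
  igraph::V(g)$name <- sort(cand_res)
  cand_res <- sort(cand_res)
  add_edge <- function(g, k1, k2) {
    if (k1 %in% cand_res && k2 %in% cand_res && k1 != k2) {
      g <- igraph::add_edges(g, c(match(k1, cand_res), match(k2, cand_res)))
    }
    g
  }
  explicit <- list()
  if (nrow(struct$links)) {
    for (i in seq_len(nrow(struct$links))) {
      l <- struct$links[i, ]
      k1 <- paste(l$chain1, l$res_seq1, l$res_name1, sep = "|")
      k2 <- paste(l$chain2, l$res_seq2, l$res_name2, sep = "|")
      if (k1 %in% cand_res && k2 %in% cand_res) {
        g <- add_edge(g, k1, k2)
      } else if (k1 %in% cand_res && k2 %in% polymer_res) {
        explicit[[length(explicit) + 1L]] <- c(lig = k1, res = k2)
      } else if (k2 %in% cand_res && k1 %in% polymer_res) {
        explicit[[length(explicit) + 1L]] <- c(lig = k2, res = k1)
      }
    }
  }
  if (nrow(struct$conect)) {
    ser2row <- match(struct$conect, a$serial)
    m <- matrix(ser2row, ncol = 2)
    for (i in seq_len(nrow(m))) {
      if (any(is.na(m[i, ]))) next
      g <- add_edge(g, rkey[m[i, 1]], rkey[m[i, 2]])
    }
  }
  # distance-based inter-residue covalent inference among candidates
  cm <- as.matrix(a[cand, c("x", "y", "z")])
  ckey <- rkey[cand]
  celem <- a$element[cand]
  if (length(cand) > 1L) {
    dd <- as.matrix(stats::dist(cm))
    for (i in seq_len(length(cand) - 1L)) {
      for (j in seq(i + 1L, length(cand))) {
        if (ckey[i] == ckey[j]) next
        thr <- if (celem[i] == "S" || celem[j] == "S") COVALENT_DIST_S else COVALENT_DIST
        if (dd[i, j] < thr) g <- add_edge(g, ckey[i], ckey[j])
      }
    }
  }

  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(ci) {
    keys <- cand_res[comp$membership == ci]
    rows <- which(rkey %in% keys & a$element != "H")
    rows <- rows[order(a$serial[rows])]
    res_df <- unique(data.frame(
      res_name = a$res_name[rows], chain = a$chain[rows],
      res_seq = a$res_seq[rows], stringsAsFactors = FALSE))
    is_metal <- length(rows) == 1L && a$element[rows] %in% METAL_ELEMENTS
    expl <- unique(vapply(explicit[vapply(explicit, function(e) e["lig"] %in% keys, TRUE)],
                          `[[`, "", "res"))
    expl_df <- if (length(expl)) key_to_df(expl) else
      data.frame(res_name = character(), chain = character(),
                 res_seq = integer(), stringsAsFactors = FALSE)
    structure(list(residues = res_df, atom_idx = rows, is_metal = is_metal,
                   explicit_residues = expl_df),
              class = "ligand_instance")
  })
  # deterministic order: by first atom serial
  out[order(vapply(out, function(l) min(struct$atoms$serial[l$atom_idx]), 0))]
}

by_chain_span <- function(poly_atoms) {
  if (!nrow(poly_atoms)) return(list())
  sp <- split(poly_atoms$res_seq, poly_atoms$chain)
  lapply(sp, range)
}

key_to_df <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    res_name = vapply(parts, `[[`, "", 3),
    chain = vapply(parts, `[[`, "", 1),
    res_seq = as.integer(vapply(parts, `[[`, "", 2)),
    stringsAsFactors = FALSE
  )
}

#' Build a composite ligand from a user-specified residue range
#'
#' All residues of `chain` with sequence number in `first:last` (inclusive,
#' any record type) become one ligand instance.
#'
#' @param struct a `pdb_structure`.
#' @param chain chain identifier.
#' @param first,last first and last residue sequence numbers.
#' @return a `ligand_instance`.
#' @export
select_composite <- function(struct, chain, first, last) {
  if (last < first) stop("reversed residue range: last < first")
  a <- struct$atoms
  rows <- which(a$chain == chain & a$res_seq >= first & a$res_seq <= last &
                  a$element != "H" & !a$is_water)
  if (!length(rows)) {
    stop(sprintf("no residues found for range %s:%d-%d", chain, first, last))
  }
  found_seqs <- sort(unique(a$res_seq[rows]))
  missing <- setdiff(first:last, found_seqs)
  if (length(missing)) {
    stop(sprintf("residue %s:%d not present in structure", chain, missing[1]))
  }
  res_df <- unique(data.frame(
    res_name = a$res_name[rows], chain = a$chain[rows], res_seq = a$res_seq[rows],
    stringsAsFactors = FALSE))
  structure(list(residues = res_df, atom_idx = rows,
                 is_metal = FALSE,
                 explicit_residues = data.frame(res_name = character(),
                                                chain = character(),
                                                res_seq = integer(),
                                                stringsAsFactors = FALSE)),
            class = "ligand_instance")
}

#' @export
print.ligand_instance <- function(x, ...) {
  lab <- paste(sprintf("%s %s%d", x$residues$res_name, x$residues$chain,
                       x$residues$res_seq), collapse = ", ")
  cat(sprintf("<ligand_instance> %s%s (%d atoms)%s\n",
              if (x$is_metal) "[metal] " else "", lab, length(x$atom_idx),
              if (nrow(x$explicit_residues))
                paste0(" + explicit: ",
                       paste(sprintf("%s %s%d", x$explicit_residues$res_name,
                                     x$explicit_residues$chain,
                                     x$explicit_residues$res_seq), collapse = ", "))
              else ""))
  invisible(x)
}
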