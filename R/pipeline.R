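# End-to-end pipeline: structure -> ligand -> graph -> 2D layout ->
# conflict resolution -> explicit residues -> interaction layout -> labels.

#' Read a structure from a PDB file or text
#'
#' @param x a file path or PDB-format text (anything containing a newline
#'   is treated as text).
#' @return a `pdb_structure`.
#' @export
read_structure <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(parse_pdb(readLines(x, warn = FALSE)))
  }
  parse_pdb(x)
}

#' Produce the complete diagram scene for one ligand
#'
#' Runs the whole layout pipeline: the ligand graph is built and
#' partitioned, laid out in 2D, conflicts resolved by torsion flips,
#' explicit (LINKed) residues laid out and placed on their real-distance
#' circles, interactions detected and placed, and residue-name labels
#' added.
#'
#' @param struct a `pdb_structure` (or PDB text/path, passed through
#'   [read_structure()]).
#' @param components named list of `component_def`, or a directory path for
#'   [read_component_dir()].
#' @param ligand a `ligand_instance`; default: the first detected ligand.
#' @param layout_cfg a [layout_config()].
#' @param inter_cfg an [interaction_config()].
#' @param include_waters place water bridges on the diagram.
#' @return a `lig2d_scene` with labels placed.
#' @export
draw_diagram <- function(struct, components = list(), ligand = NULL,
                         layout_cfg = layout_config(),
                         inter_cfg = interaction_config(),
                         include_waters = FALSE) {
  if (!inherits(struct, "pdb_structure")) struct <- read_structure(struct)
  if (is.character(components)) components <- read_component_dir(components)
  if (is.null(ligand)) {
    ligs <- detect_ligands(struct)
    if (!length(ligs)) stop("no ligand detected in structure")
    ligand <- ligs[[1]]
  }
  graph <- build_graph(ligand, struct, components)
  elements <- partition_elements(graph)
  layout <- layout_ligand(graph, elements, layout_cfg)
  layout <- resolve_conflicts(layout, layout_cfg)

  explicit <- place_all_explicit(layout, ligand, struct, components, layout_cfg)
  interactions <- detect_interactions(ligand, struct, inter_cfg, components, graph)
  scene <- place_interactions(layout, interactions, struct, layout_cfg,
                              include_waters = include_waters,
                              explicit = explicit)
  place_labels(scene, layout_cfg)
}

# lay out each explicit residue independently and place it on the circle of
# the real 3D anchor distance
place_all_explicit <- function(layout, ligand, struct, components, config) {
  if (!nrow(ligand$explicit_residues)) return(list())
  a <- struct$atoms
  out <- list()
  for (i in seq_len(nrow(ligand$explicit_residues))) {
    er <- ligand$explicit_residues[i, ]
    rows <- which(a$chain == er$chain & a$res_seq == er$res_seq &
                    a$res_name == er$res_name & a$element != "H")
    if (!length(rows)) next
    link <- find_link(struct, ligand, er)
    if (is.null(link)) next
    pseudo <- structure(list(residues = er, atom_idx = rows, is_metal = FALSE,
                             explicit_residues = data.frame()),
                        class = "ligand_instance")
    rgraph <- build_graph(pseudo, struct, components)
    rlayout <- layout_ligand(rgraph, NULL, config)
    anchor_res <- match(link$res_row, rgraph$atoms$idx)
    anchor_lig <- match(link$lig_row, layout$graph$atoms$idx)
    if (is.na(anchor_res) || is.na(anchor_lig)) next
    d3 <- dist3(as.numeric(a[link$lig_row, c("x", "y", "z")]),
                as.numeric(a[link$res_row, c("x", "y", "z")]))
    pl <- place_explicit_residue(layout, rlayout, anchor_lig, anchor_res,
                                 d3, config)
    out[[length(out) + 1L]] <- list(
      res_name = er$res_name, chain = er$chain, res_seq = er$res_seq,
      graph = rgraph, pos = pl$res_pos, anchor_res = anchor_res,
      anchor_lig = anchor_lig, anchor_lig_pos = layout$pos[anchor_lig, ],
      angle = pl$angle, score = pl$score, trace = pl$trace)
  }
  out
}

# the LINK record joining the ligand to an explicit residue, resolved to
# structure rows
find_link <- function(struct, ligand, er) {
  a <- struct$atoms
  lig_keys <- paste(ligand$residues$chain, ligand$residues$res_seq,
                    ligand$residues$res_name, sep = "|")
  for (i in seq_len(nrow(struct$links))) {
    l <- struct$links[i, ]
    k1 <- paste(l$chain1, l$res_seq1, l$res_name1, sep = "|")
    k2 <- paste(l$chain2, l$res_seq2, l$res_name2, sep = "|")
    ek <- paste(er$chain, er$res_seq, er$res_name, sep = "|")
    hit <- NULL
    if (k1 %in% lig_keys && k2 == ek) hit <- list(lig = l[c("name1", "chain1", "res_seq1")], res = l[c("name2", "chain2", "res_seq2")])
    if (k2 %in% lig_keys && k1 == ek) hit <- list(lig = l[c("name2", "chain2", "res_seq2")], res = l[c("name1", "chain1", "res_seq1")])
    if (!is.null(hit)) {
      lig_row <- which(a$name == hit$lig[[1]] & a$chain == hit$lig[[2]] &
                         a$res_seq == hit$lig[[3]])[1]
      res_row <- which(a$name == hit$res[[1]] & a$chain == hit$res[[2]] &
                         a$res_seq == hit$res[[3]])[1]
      if (!is.na(lig_row) && !is.na(res_row)) {
        return(list(lig_row = lig_row, res_row = res_row))
      }
    }
  }
  NULL
}
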