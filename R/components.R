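# Chemical component definitions (CCD / PDBeChem mmCIF dialect).
#
# PDB coordinate files carry no bond orders; they are mapped in from
# per-residue component definitions with `_chem_comp_atom` and
# `_chem_comp_bond` loops.

#' Parse a chemical component definition block
#'
#' Reads the `_chem_comp_atom` and `_chem_comp_bond` loops of an mmCIF-style
#' component definition. Bond orders are normalised to
#' single/double/triple/aromatic. Hydrogens are retained in the definition
#' (they inform donor/acceptor typing) but are dropped when mapped onto
#' coordinates.
#'
#' @param text component definition text (single string or lines).
#' @return an object of class `component_def`: list with `comp_id`,
#'   `atoms` (data frame: name, element), `bonds` (data frame: a1, a2, order).
#' @examples
#' fx <- make_ligand("ring", n = 6)
#' cd <- parse_component(fx$components[[1]])
#' cd$bonds
#' @export
parse_component <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]

  comp_id <- NA_character_
  idl <- grep("^_chem_comp\\.id\\b", lines, value = TRUE)
  if (length(idl)) comp_id <- strip_quotes(strsplit(idl[1], "[[:space:]]+")[[1]][2])
  if (is.na(comp_id)) {
    dl <- grep("^data_", lines, value = TRUE)
    if (length(dl)) comp_id <- sub("^data_", "", dl[1])
  }

  atoms <- read_cif_loop(lines, "_chem_comp_atom")
  bonds <- read_cif_loop(lines, "_chem_comp_bond")
  if (is.null(atoms)) stop("component block has no _chem_comp_atom loop")

  atom_df <- data.frame(
    name = strip_quotes(atoms[["atom_id"]]),
    element = toupper(strip_quotes(atoms[["type_symbol"]])),
    stringsAsFactors = FALSE
  )
  if (is.na(comp_id) && !is.null(atoms[["comp_id"]])) comp_id <- atoms[["comp_id"]][1]

  if (is.null(bonds) || !length(bonds[[1]])) {
    bond_df <- data.frame(a1 = character(), a2 = character(),
                          order = character(), stringsAsFactors = FALSE)
  } else {
    bond_df <- data.frame(
      a1 = strip_quotes(bonds[["atom_id_1"]]),
      a2 = strip_quotes(bonds[["atom_id_2"]]),
      order = normalise_order(strip_quotes(bonds[["value_order"]])),
      stringsAsFactors = FALSE
    )
    unknown <- !(bond_df$a1 %in% atom_df$name) | !(bond_df$a2 %in% atom_df$name)
    if (any(unknown)) {
      stop(sprintf("component %s: bond references undefined atom(s): %s",
                   comp_id,
                   paste(unique(c(bond_df$a1[unknown], bond_df$a2[unknown])), collapse = ", ")))
    }
    ekey <- apply(bond_df[, c("a1", "a2")], 1L, function(r) paste(sort(r), collapse = "|"))
    bond_df <- bond_df[!duplicated(ekey), , drop = FALSE]
    rownames(bond_df) <- NULL
  }

  structure(list(comp_id = comp_id, atoms = atom_df, bonds = bond_df),
            class = "component_def")
}

normalise_order <- function(x) {
  x <- toupper(x)
  out <- rep("single", length(x))
  out[x %in% c("DOUB", "DOUBLE", "2")] <- "double"
  out[x %in% c("TRIP", "TRIPLE", "3")] <- "triple"
  out[x %in% c("AROM", "AROMATIC", "AR")] <- "aromatic"
  out
}

strip_quotes <- function(x) gsub('^["\']|["\']$', "", x)

# Extract one loop_ block whose tags share `prefix`; returns a named list of
# character vectors, or NULL when absent.
read_cif_loop <- function(lines, prefix) {
  loop_idx <- which(lines == "loop_")
  for (li in loop_idx) {
    tags <- character()
    i <- li + 1L
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i])
      i <- i + 1L
    }
    if (!length(tags) || !all(startsWith(tags, paste0(prefix, ".")))) next
    cols <- sub(paste0("^", prefix, "\\."), "", tags)
    rows <- list()
    while (i <= length(lines) && !startsWith(lines[i], "_") &&
           lines[i] != "loop_" && !startsWith(lines[i], "data_")) {
      fields <- scan(text = lines[i], what = "", quiet = TRUE)
      if (length(fields) == length(cols)) rows[[length(rows) + 1L]] <- fields
      i <- i + 1L
    }
    if (!length(rows)) {
      out <- rep(list(character()), length(cols))
      names(out) <- cols
      return(out)
    }
    m <- do.call(rbind, rows)
    out <- lapply(seq_along(cols), function(j) m[, j])
    names(out) <- cols
    return(out)
  }
  NULL
}

#' Load a directory of component definitions
#'
#' Files are keyed by component id taken from their contents; typical layout
#' is one `<COMP>.cif` per residue name.
#'
#' @param dir path containing `*.cif` files.
#' @return named list of `component_def`, keyed by comp_id.
#' @export
read_component_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.cif$", full.names = TRUE)
  defs <- lapply(files, function(f) parse_component(readLines(f, warn = FALSE)))
  names(defs) <- vapply(defs, `[[`, "", "comp_id")
  defs
}

#' @export
print.component_def <- function(x, ...) {
  cat(sprintf("<component_def> %s: %d atoms, %d bonds\n",
              x$comp_id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# Serialise a component definition (fixture generation).
format_component <- function(comp_id, atoms, bonds) {
  order_map <- c(single = "SING", double = "DOUB", triple = "TRIP", aromatic = "AROM")
  lines <- c(
    sprintf("data_%s", comp_id),
    sprintf("_chem_comp.id %s", comp_id),
    "loop_",
    "_chem_comp_atom.comp_id",
    "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    sprintf("%s %s %s", comp_id, atoms$name, atoms$element)
  )
  lines <- c(lines,
             "loop_",
             "_chem_comp_bond.comp_id",
             "_chem_comp_bond.atom_id_1",
             "_chem_comp_bond.atom_id_2",
             "_chem_comp_bond.value_order")
  if (nrow(bonds)) {
    lines <- c(lines, sprintf("%s %s %s %s", comp_id, bonds$a1, bonds$a2,
                              order_map[bonds$order]))
  }
  paste(c(lines, "#"), collapse = "\n")
}
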