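# PDB v3.3 fixed-column reading and minimal writing.
#
# Only MODEL 1 of multi-model files is read; for alternate locations the
# first alt-loc encountered per atom is kept. Waters are flagged by residue
# name (HOH/WAT/DOD). Hydrogens are parsed but all geometric stages operate
# on heavy atoms only.

WATER_NAMES <- c("HOH", "WAT", "DOD")

METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "MO", "CD", "HG")

# Two-letter element symbols that occur in biomolecular PDB files; used when
# columns 77-78 are blank and the element must be inferred from the name.
TWO_LETTER_ELEMENTS <- c(METAL_ELEMENTS[nchar(METAL_ELEMENTS) == 2L],
                         "CL", "BR", "SE", "SI", "AS")

#' Parse PDB-format text into a structure object
#'
#' Reads ATOM/HETATM coordinates plus the LINK, CONECT, HELIX and SHEET
#' records the diagram pipeline needs. Columns follow the PDB v3.3
#' fixed-width layout. Only the first MODEL of a multi-model file is kept,
#' and only the first alternate location of each atom. Waters (residue name
#' HOH, WAT or DOD) are flagged.
#'
#' @param text a single string or character vector of lines in PDB format.
#' @return an object of class `pdb_structure`: a list with
#'   `atoms` (data frame: serial, name, alt_loc, res_name, chain, res_seq,
#'   x, y, z, occupancy, element, is_het, is_water),
#'   `links` (data frame of LINK records), `conect` (two-column matrix of
#'   bonded serial pairs, symmetric), `helix` and `sheet`
#'   (data frames: chain, first, last).
#' @examples
#' fx <- make_ligand("ring", n = 6)
#' s <- parse_pdb(fx$pdb)
#' nrow(s$atoms)
#' @export
parse_pdb <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)

  # model 1 only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) >= 2L) {
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop1 <- if (length(endmdl)) endmdl[1] else model_starts[2]
    keep <- seq_along(lines) < model_starts[2] & seq_along(lines) <= stop1
    # records outside the MODEL blocks (e.g. trailing CONECT) are kept too
    keep <- keep | !(seq_along(lines) >= model_starts[2])
    keep[seq_along(lines) >= model_starts[2] & rec %in% c("CONECT", "LINK  ", "HELIX ", "SHEET ")] <- TRUE
    lines <- lines[keep]
    rec <- substr(lines, 1, 6)
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records found in input")

  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)

  serial <- suppressWarnings(as.integer(substr(atom_lines, 7, 11)))
  name <- substr(atom_lines, 13, 16)
  alt_loc <- substr(atom_lines, 17, 17)
  res_name <- trimws(substr(atom_lines, 18, 20))
  chain <- substr(atom_lines, 22, 22)
  res_seq <- suppressWarnings(as.integer(substr(atom_lines, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(atom_lines, 55, 60)))
  occ[is.na(occ)] <- 1
  elem_col <- toupper(trimws(substr(atom_lines, 77, 78)))

  bad <- is.na(serial) | is.na(res_seq) | is.na(x) | is.na(y) | is.na(z)
  if (any(bad)) {
    warning(sprintf("skipping %d malformed ATOM/HETATM record(s) at line(s) %s",
                    sum(bad), paste(atom_lineno[bad], collapse = ", ")))
  }
  keepi <- !bad
  atoms <- data.frame(
    serial = serial[keepi],
    name = trimws(name[keepi]),
    name_raw = name[keepi],
    alt_loc = alt_loc[keepi],
    res_name = res_name[keepi],
    chain = chain[keepi],
    res_seq = res_seq[keepi],
    x = x[keepi], y = y[keepi], z = z[keepi],
    occupancy = occ[keepi],
    element = elem_col[keepi],
    is_het = rec[is_atom][keepi] == "HETATM",
    stringsAsFactors = FALSE
  )

  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- vapply(atoms$name_raw[blank], infer_element, "")
  atoms$is_water <- atoms$res_name %in% WATER_NAMES

  # keep first alt-loc per atom identity
  key <- paste(atoms$chain, atoms$res_seq, atoms$res_name, atoms$name, sep = "|")
  atoms <- atoms[!duplicated(key) | atoms$alt_loc == " ", , drop = FALSE]
  key <- paste(atoms$chain, atoms$res_seq, atoms$res_name, atoms$name, sep = "|")
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  rownames(atoms) <- NULL

  links <- parse_link_records(lines[rec == "LINK  "])
  conect <- parse_conect_records(lines[rec == "CONECT"], atoms$serial)
  helix <- parse_ss(lines[rec == "HELIX "], 20, 22, 25, 34, 37)
  sheet <- parse_ss(lines[rec == "SHEET "], 22, 23, 26, 34, 37)

  structure(list(atoms = atoms, links = links, conect = conect,
                 helix = helix, sheet = sheet),
            class = "pdb_structure")
}

# Element from atom name per PDB convention: the raw 4-char name field is
# examined; a symbol starting in column 13 can be a two-letter element
# (FE, CL, ...), otherwise digits/primes are stripped and the first letter
# is the element.
infer_element <- function(name_raw) {
  two <- toupper(gsub("[^A-Za-z]", "", substr(name_raw, 1, 2)))
  if (substr(name_raw, 1, 1) != " " && nchar(two) == 2 && two %in% TWO_LETTER_ELEMENTS) {
    return(two)
  }
  letters_only <- gsub("[^A-Za-z]", "", name_raw)
  if (nchar(letters_only) == 0L) return("X")
  toupper(substr(letters_only, 1, 1))
}

parse_link_records <- function(lines) {
  if (!length(lines)) {
    return(data.frame(name1 = character(), res_name1 = character(),
                      chain1 = character(), res_seq1 = integer(),
                      name2 = character(), res_name2 = character(),
                      chain2 = character(), res_seq2 = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  lines <- formatC(lines, width = 80, flag = "-")
  out <- data.frame(
    name1 = trimws(substr(lines, 13, 16)),
    res_name1 = trimws(substr(lines, 18, 20)),
    chain1 = substr(lines, 22, 22),
    res_seq1 = suppressWarnings(as.integer(substr(lines, 23, 26))),
    name2 = trimws(substr(lines, 43, 46)),
    res_name2 = trimws(substr(lines, 48, 50)),
    chain2 = substr(lines, 52, 52),
    res_seq2 = suppressWarnings(as.integer(substr(lines, 53, 56))),
    distance = suppressWarnings(as.numeric(substr(lines, 74, 78))),
    stringsAsFactors = FALSE
  )
  out
}

parse_conect_records <- function(lines, known_serials) {
  if (!length(lines)) return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  pairs <- list()
  for (ln in lines) {
    ln <- formatC(ln, width = 31, flag = "-")
    a <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    if (is.na(a)) next
    for (cols in list(c(12, 16), c(17, 21), c(22, 26), c(27, 31))) {
      b <- suppressWarnings(as.integer(substr(ln, cols[1], cols[2])))
      if (!is.na(b)) pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  m <- do.call(rbind, pairs)
  m <- m[m[, 1] %in% known_serials & m[, 2] %in% known_serials, , drop = FALSE]
  # symmetrise and dedupe
  m <- rbind(m, m[, 2:1, drop = FALSE])
  m <- m[m[, 1] != m[, 2], , drop = FALSE]
  m <- unique(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("a", "b")
  m
}

parse_ss <- function(lines, chain_col, i1, i2, j1, j2) {
  if (!length(lines)) {
    return(data.frame(chain = character(), first = integer(), last = integer(),
                      stringsAsFactors = FALSE))
  }
  lines <- formatC(lines, width = 40, flag = "-")
  data.frame(
    chain = substr(lines, chain_col, chain_col),
    first = suppressWarnings(as.integer(substr(lines, i1, i2))),
    last = suppressWarnings(as.integer(substr(lines, j1, j2))),
    stringsAsFactors = FALSE
  )
}

#' Write a structure back to PDB text
#'
#' Minimal writer used for round-trip checks and fixture generation:
#' ATOM/HETATM, LINK and CONECT records only.
#'
#' @param struct a `pdb_structure`.
#' @return a single string of PDB-format text.
#' @export
write_pdb <- function(struct) {
  a <- struct$atoms
  rec <- ifelse(a$is_het, "HETATM", "ATOM  ")
  name_field <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$name[i]
    if (!is.null(a$name_raw) && !is.na(a$name_raw[i]) && nchar(a$name_raw[i]) == 4L) {
      a$name_raw[i]
    } else if (nchar(nm) >= 4L) {
      substr(nm, 1, 4)
    } else {
      sprintf(" %-3s", nm)
    }
  }, "")
  lines <- sprintf("%s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial, name_field, a$alt_loc, a$res_name, a$chain,
                   a$res_seq, a$x, a$y, a$z, a$occupancy, 0, a$element)
  link_lines <- character()
  if (nrow(struct$links)) {
    l <- struct$links
    dist_field <- ifelse(is.na(l$distance), "     ", sprintf("%5.2f", l$distance))
    link_lines <- sprintf("LINK        %4s %-3s %1s%4d                %4s %-3s %1s%4d     1555   1555 %5s",
                          substr(sprintf("%-4s", l$name1), 1, 4), l$res_name1, l$chain1, l$res_seq1,
                          substr(sprintf("%-4s", l$name2), 1, 4), l$res_name2, l$chain2, l$res_seq2,
                          dist_field)
  }
  conect_lines <- character()
  if (nrow(struct$conect)) {
    m <- struct$conect
    m <- m[m[, 1] < m[, 2], , drop = FALSE]
    by_a <- split(m[, 2], m[, 1])
    conect_lines <- unlist(lapply(names(by_a), function(a1) {
      bs <- by_a[[a1]]
      sprintf("CONECT%5d%s", as.integer(a1),
              paste(sprintf("%5d", bs), collapse = ""))
    }))
  }
  paste(c(lines, link_lines, conect_lines, "END"), collapse = "\n")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d atoms (%d het, %d waters), %d links, %d conect pairs\n",
              nrow(x$atoms), sum(x$atoms$is_het), sum(x$atoms$is_water),
              nrow(x$links), nrow(x$conect)))
  invisible(x)
}

residue_key <- function(atoms) paste(atoms$chain, atoms$res_seq, atoms$res_name, sep = "|")
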