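# Drawing. SVG is the canonical backend, written as deterministic text so
# that a fixed scene renders byte-identically; PNG draws the same placed
# geometry onto a grDevices raster device. The interaction list exports as
# a flat tab-separated table.

PX_PER_ANGSTROM <- 40
SVG_MARGIN <- 40

ELEMENT_COLOURS <- c(C = "#404040", N = "#3050F8", O = "#FF0D0D",
                     S = "#C8A000", P = "#FF8000", F = "#90E050",
                     CL = "#1FF01F", BR = "#A62929")

HYDROPHOBICITY_POLAR <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS")
HYDROPHOBICITY_NONPOLAR <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                             "MET", "TRP", "GLY")
CHARGE_ACIDIC <- c("ASP", "GLU")
CHARGE_BASIC <- c("LYS", "ARG", "HIS")

# Shapely-like amino-acid palette (approximated from the RasMol
# documentation values; overridable via the style palette)
SHAPELY_COLOURS <- c(
  ALA = "#8CFF8C", GLY = "#FFFFFF", LEU = "#455E45", SER = "#FF7042",
  VAL = "#FF8CFF", THR = "#B84C00", LYS = "#4747B8", ASP = "#A00042",
  ILE = "#004C00", ASN = "#FF7C70", GLU = "#660000", PRO = "#525252",
  ARG = "#00007C", PHE = "#534C42", GLN = "#FF4C4C", TYR = "#8C704C",
  HIS = "#7070FF", CYS = "#FFFF70", MET = "#B8A042", TRP = "#4F4600")

#' Diagram style configuration
#'
#' @param colour_mode `"standard_element"` (oxygen red, nitrogen blue, ...)
#'   or `"plain"` (ligand atoms take the bond colour).
#' @param residue_scheme oval colouring: `"hydrophobicity"` (polar pink,
#'   non-polar green, other grey), `"amino_acid"` (Shapely-like),
#'   `"charge"` (acidic red, basic blue, uncharged polar purple, non-polar
#'   grey) or `"secondary_structure"` (helix red, sheet yellow, coil grey).
#' @param show_atom_labels draw atom names next to atoms.
#' @param hbond_style hydrogen bonds as `"line"` or `"arrow"` (donor to
#'   acceptor).
#' @param show_hbond_distances annotate hydrogen bonds with the
#'   donor-acceptor distance in angstrom.
#' @param palette named character vector of colour overrides (residue name
#'   or element symbol -> colour).
#' @return a `style_config` list.
#' @export
style_config <- function(colour_mode = c("standard_element", "plain"),
                         residue_scheme = c("hydrophobicity", "amino_acid",
                                            "charge", "secondary_structure"),
                         show_atom_labels = FALSE,
                         hbond_style = c("line", "arrow"),
                         show_hbond_distances = FALSE,
                         palette = character()) {
  structure(list(colour_mode = match.arg(colour_mode),
                 residue_scheme = match.arg(residue_scheme),
                 show_atom_labels = show_atom_labels,
                 hbond_style = match.arg(hbond_style),
                 show_hbond_distances = show_hbond_distances,
                 palette = palette),
            class = "style_config")
}

#' Residue colour under a scheme
#'
#' Total over residue names: unknown residues get the scheme's fallback.
#'
#' @param res_name 3-letter residue name(s).
#' @param scheme one of the [style_config()] residue schemes.
#' @param chain,res_seq,struct needed by the secondary-structure scheme.
#' @param palette named overrides.
#' @return colour string(s).
#' @export
residue_colour <- function(res_name, scheme = "hydrophobicity",
                           chain = NULL, res_seq = NULL, struct = NULL,
                           palette = character()) {
  vapply(seq_along(res_name), function(i) {
    rn <- res_name[i]
    if (rn %in% names(palette)) return(unname(palette[rn]))
    switch(scheme,
      hydrophobicity = {
        if (rn %in% HYDROPHOBICITY_POLAR) "#FF9EC4"
        else if (rn %in% HYDROPHOBICITY_NONPOLAR) "#7BC47B"
        else "#BDBDBD"
      },
      amino_acid = {
        if (rn %in% names(SHAPELY_COLOURS)) unname(SHAPELY_COLOURS[rn])
        else "#BEA06E"
      },
      charge = {
        if (rn %in% CHARGE_ACIDIC) "#E04040"
        else if (rn %in% CHARGE_BASIC) "#4060E0"
        else if (rn %in% HYDROPHOBICITY_POLAR) "#9B59B6"
        else "#BDBDBD"
      },
      secondary_structure = {
        ss <- ss_type(struct, chain[i], res_seq[i])
        if (ss == "helix") "#E04040" else if (ss == "sheet") "#F0D050"
        else "#BDBDBD"
      },
      "#BDBDBD")
  }, "")
}

ss_type <- function(struct, chain, res_seq) {
  if (is.null(struct) || is.null(chain) || is.null(res_seq)) return("coil")
  hit <- function(d) {
    d <- d[!is.na(d$first) & !is.na(d$last), , drop = FALSE]
    nrow(d) > 0 && any(d$chain == chain & d$first <= res_seq & d$last >= res_seq)
  }
  if (hit(struct$helix)) "helix" else if (hit(struct$sheet)) "sheet" else "coil"
}

element_colour <- function(element, style) {
  if (style$colour_mode == "plain") return(rep("#000000", length(element)))
  vapply(element, function(e) {
    if (e %in% names(style$palette)) unname(style$palette[e])
    else if (e %in% names(ELEMENT_COLOURS)) unname(ELEMENT_COLOURS[e])
    else "#909090"
  }, "")
}

scene_bbox <- function(scene) {
  pts <- scene$layout$pos[!is.na(scene$layout$pos[, 1]), , drop = FALSE]
  for (el in scene$placed) {
    if (!is.null(el$position)) pts <- rbind(pts, el$position)
    if (!is.null(el$node_pos)) for (np in el$node_pos) pts <- rbind(pts, np)
  }
  for (ex in scene$explicit %||% list()) pts <- rbind(pts, ex$pos)
  for (lb in scene$labels %||% list()) pts <- rbind(pts, lb$position)
  pad <- OVAL_RADIUS + 0.6
  list(xmin = min(pts[, 1]) - pad, xmax = max(pts[, 1]) + pad,
       ymin = min(pts[, 2]) - pad, ymax = max(pts[, 2]) + pad)
}

#' Render a scene to SVG
#'
#' Bonds as lines (double/triple/aromatic as parallel strokes), hydrogen
#' bonds in blue (lines or donor-to-acceptor arrows, optionally with the
#' distance), nearby residues as ovals coloured by the residue scheme with
#' the chain identifier in brackets, water bridges in green labelled with
#' the water count, residue names at their placed label positions. Output
#' is deterministic: the same scene and style always produce the same
#' bytes.
#'
#' @param scene a `lig2d_scene` (ideally after [place_labels()]).
#' @param style a [style_config()].
#' @return single string: an SVG 1.1 document.
#' @export
render_svg <- function(scene, style = style_config()) {
  bb <- scene_bbox(scene)
  S <- PX_PER_ANGSTROM
  w <- (bb$xmax - bb$xmin) * S + 2 * SVG_MARGIN
  h <- (bb$ymax - bb$ymin) * S + 2 * SVG_MARGIN
  px <- function(p) c((p[1] - bb$xmin) * S + SVG_MARGIN,
                      (bb$ymax - p[2]) * S + SVG_MARGIN)
  fmt <- function(x) sprintf("%.2f", x)
  line_el <- function(p1, p2, stroke, width = 2, dash = NULL, marker = NULL, id = NULL) {
    a <- px(p1); b <- px(p2)
    sprintf('<line%s x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s%s />',
            if (is.null(id)) "" else sprintf(' id="%s"', id),
            fmt(a[1]), fmt(a[2]), fmt(b[1]), fmt(b[2]), stroke, fmt(width),
            if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash),
            if (is.null(marker)) "" else sprintf(' marker-end="url(#%s)"', marker))
  }
  text_el <- function(p, txt, size = 14, fill = "#000000", anchor = "middle") {
    a <- px(p)
    sprintf('<text x="%s" y="%s" font-family="Helvetica" font-size="%s" fill="%s" text-anchor="%s">%s</text>',
            fmt(a[1]), fmt(a[2]), fmt(size), fill, anchor, xml_escape(txt))
  }

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(w), fmt(h), fmt(w), fmt(h)),
    '<defs><marker id="hbarrow" markerWidth="10" markerHeight="8" refX="9" refY="4" orient="auto"><path d="M0,0 L10,4 L0,8 z" fill="#2050C8" /></marker></defs>',
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF" />', fmt(w), fmt(h))
  )

  lay <- scene$layout
  ga <- lay$graph$atoms
  # ligand bonds
  bid <- 0L
  for (k in seq_len(nrow(lay$graph$edges))) {
    e <- lay$graph$edges[k, ]
    p1 <- lay$pos[e$i, ]; p2 <- lay$pos[e$j, ]
    if (anyNA(c(p1, p2))) next
    bid <- bid + 1L
    out <- c(out, bond_lines_svg(p1, p2, e$order, line_el, sprintf("bond-%d", bid)))
  }
  # explicit residues: grey bonds, red connector
  for (ex in scene$explicit %||% list()) {
    for (k in seq_len(nrow(ex$graph$edges))) {
      e <- ex$graph$edges[k, ]
      out <- c(out, line_el(ex$pos[e$i, ], ex$pos[e$j, ], "#808080", 2))
    }
    out <- c(out, line_el(ex$anchor_lig_pos, ex$pos[ex$anchor_res, ],
                          "#C83232", 2, dash = "6,3"))
  }
  # placed interactions
  for (el in scene$placed) {
    if (el$kind == "hbond_partner") {
      marker <- if (style$hbond_style == "arrow") "hbarrow" else NULL
      p_from <- el$anchor; p_to <- el$position
      if (!is.null(marker) && !el$ligand_is_donor) { p_from <- el$position; p_to <- el$anchor }
      out <- c(out, line_el(p_from, p_to, "#2050C8", 2, dash = "5,4",
                            marker = marker))
      if (style$show_hbond_distances) {
        mid <- (el$anchor + el$position) / 2
        out <- c(out, text_el(mid + c(0, 0.18), sprintf("%.2f", el$distance),
                              size = 11, fill = "#2050C8"))
      }
      prow <- el$partner_row
      pa <- scene$struct$atoms[prow, ]
      out <- c(out, text_el(el$position + c(0, -0.35),
                            sprintf("%s", pa$name), size = 11, fill = "#2050C8"))
    } else if (el$kind == "residue_oval") {
      fill <- residue_colour(el$res_name, style$residue_scheme,
                             chain = el$chain, res_seq = el$res_seq,
                             struct = scene$struct, palette = style$palette)
      a <- px(el$position)
      out <- c(out, sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" fill="%s" stroke="#404040" stroke-width="1.5" fill-opacity="0.85" />',
                            fmt(a[1]), fmt(a[2]), fmt(OVAL_RADIUS * S),
                            fmt(0.62 * OVAL_RADIUS * S), fill))
      out <- c(out, text_el(el$position + c(0, -0.08),
                            sprintf("%s %d(%s)", el$res_name, el$res_seq, el$chain),
                            size = 12))
    } else if (el$kind == "water_bridge") {
      prev <- el$anchor
      for (np in el$node_pos) {
        out <- c(out, line_el(prev, np, "#1E8C3C", 2, dash = "4,4"))
        prev <- np
      }
      nw <- length(el$node_pos) - 1L  # last node is the residue endpoint
      if (nw >= 1L) {
        for (wi in seq_len(nw)) {
          a <- px(el$node_pos[[wi]])
          out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="#FFFFFF" stroke="#1E8C3C" stroke-width="1.5" />',
                                fmt(a[1]), fmt(a[2]), fmt(0.25 * S)))
        }
        lab_at <- el$node_pos[[max(1L, nw %/% 2L + nw %% 2L)]]
        out <- c(out, text_el(lab_at + c(0, 0.45),
                              sprintf("%d H2O", el$n_waters),
                              size = 11, fill = "#1E8C3C"))
      }
    }
  }
  # ligand atoms
  for (i in seq_len(nrow(ga))) {
    if (is.na(lay$pos[i, 1])) next
    a <- px(lay$pos[i, ])
    col <- element_colour(ga$element[i], style)
    out <- c(out, sprintf('<circle id="atom-%d" cx="%s" cy="%s" r="%s" fill="%s" />',
                          i, fmt(a[1]), fmt(a[2]), fmt(0.11 * S), col))
    if (style$show_atom_labels) {
      out <- c(out, text_el(lay$pos[i, ] + c(0.16, 0.16), ga$name[i],
                            size = 10, fill = col, anchor = "start"))
    }
  }
  for (ex in scene$explicit %||% list()) {
    for (i in seq_len(nrow(ex$pos))) {
      a <- px(ex$pos[i, ])
      out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="#808080" />',
                            fmt(a[1]), fmt(a[2]), fmt(0.10 * S)))
    }
  }
  # residue-name labels
  for (lb in scene$labels %||% list()) {
    out <- c(out, text_el(lb$position, lb$text, size = 13, fill = "#202020"))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

bond_lines_svg <- function(p1, p2, order, line_el, id) {
  if (order %in% c("double", "triple", "aromatic")) {
    u <- unit2(p2 - p1)
    nrm <- c(-u[2], u[1]) * 0.09
    if (order == "triple") {
      c(line_el(p1, p2, "#000000", 1.6, id = id),
        line_el(p1 + nrm, p2 + nrm, "#000000", 1.6),
        line_el(p1 - nrm, p2 - nrm, "#000000", 1.6))
    } else {
      dash <- if (order == "aromatic") "5,3" else NULL
      c(line_el(p1 + nrm, p2 + nrm, "#000000", 1.6, id = id),
        line_el(p1 - nrm, p2 - nrm, "#000000", 1.6, dash = dash))
    }
  } else {
    line_el(p1, p2, "#000000", 2, id = id)
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a scene to PNG
#'
#' Draws the same placed geometry as [render_svg()] onto a `grDevices` PNG
#' device at the requested resolution.
#'
#' @param scene a `lig2d_scene`.
#' @param file output path.
#' @param style a [style_config()].
#' @param dpi raster resolution; pixel dimensions scale linearly with it.
#' @return invisibly, the pixel dimensions c(width, height).
#' @export
render_png <- function(scene, file, style = style_config(), dpi = 96) {
  if (!capabilities("png")) {
    stop("PNG device unavailable in this R build; use render_svg() instead")
  }
  bb <- scene_bbox(scene)
  w_in <- (bb$xmax - bb$xmin) * PX_PER_ANGSTROM / 96 + 1
  h_in <- (bb$ymax - bb$ymin) * PX_PER_ANGSTROM / 96 + 1
  wpx <- round(w_in * dpi); hpx <- round(h_in * dpi)
  grDevices::png(file, width = wpx, height = hpx, res = dpi)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(bb$xmin, bb$xmax), ylim = c(bb$ymin, bb$ymax),
                        asp = 1)
  lay <- scene$layout
  for (k in seq_len(nrow(lay$graph$edges))) {
    e <- lay$graph$edges[k, ]
    p1 <- lay$pos[e$i, ]; p2 <- lay$pos[e$j, ]
    if (anyNA(c(p1, p2))) next
    graphics::segments(p1[1], p1[2], p2[1], p2[2], lwd = 2)
  }
  for (ex in scene$explicit %||% list()) {
    for (k in seq_len(nrow(ex$graph$edges))) {
      e <- ex$graph$edges[k, ]
      graphics::segments(ex$pos[e$i, 1], ex$pos[e$i, 2],
                         ex$pos[e$j, 1], ex$pos[e$j, 2], col = "grey50", lwd = 2)
    }
  }
  for (el in scene$placed) {
    if (el$kind == "hbond_partner") {
      graphics::segments(el$anchor[1], el$anchor[2], el$position[1],
                         el$position[2], col = "#2050C8", lty = 2, lwd = 2)
    } else if (el$kind == "residue_oval") {
      fill <- residue_colour(el$res_name, style$residue_scheme,
                             chain = el$chain, res_seq = el$res_seq,
                             struct = scene$struct, palette = style$palette)
      th <- seq(0, 2 * pi, length.out = 40)
      graphics::polygon(el$position[1] + OVAL_RADIUS * cos(th),
                        el$position[2] + 0.62 * OVAL_RADIUS * sin(th),
                        col = fill, border = "grey20")
      graphics::text(el$position[1], el$position[2],
                     sprintf("%s %d(%s)", el$res_name, el$res_seq, el$chain),
                     cex = 0.6)
    } else if (el$kind == "water_bridge") {
      prev <- el$anchor
      for (np in el$node_pos) {
        graphics::segments(prev[1], prev[2], np[1], np[2],
                           col = "#1E8C3C", lty = 3, lwd = 2)
        prev <- np
      }
    }
  }
  cols <- element_colour(lay$graph$atoms$element, style)
  ok <- !is.na(lay$pos[, 1])
  graphics::points(lay$pos[ok, 1], lay$pos[ok, 2], pch = 19, col = cols[ok],
                   cex = 0.9)
  for (lb in scene$labels %||% list()) {
    graphics::text(lb$position[1], lb$position[2], lb$text, cex = 0.7)
  }
  invisible(c(wpx, hpx))
}

#' Export the interaction list as flat text
#'
#' One tab-separated row per interaction: type, ligand atom, partner
#' atom/residue, chain, distance(s) in angstrom to 2 decimals (water
#' bridges list every step and the total).
#'
#' @param interactions an `interaction_set`.
#' @param struct the `pdb_structure` the rows index into.
#' @return single string (header plus data rows).
#' @export
export_interactions <- function(interactions, struct) {
  a <- struct$atoms
  rows <- c("type\tligand_atom\tpartner\tchain\tdistance")
  hb <- interactions$hbonds
  if (!is.null(hb) && nrow(hb)) {
    for (i in seq_len(nrow(hb))) {
      lrow <- if (hb$ligand_is_donor[i]) hb$donor_row[i] else hb$acceptor_row[i]
      prow <- if (hb$ligand_is_donor[i]) hb$acceptor_row[i] else hb$donor_row[i]
      rows <- c(rows, sprintf("hbond\t%s\t%s%d:%s\t%s\t%.2f",
                              a$name[lrow], a$res_name[prow], a$res_seq[prow],
                              a$name[prow], a$chain[prow], hb$distance[i]))
    }
  }
  nb <- interactions$nearby
  if (!is.null(nb) && nrow(nb)) {
    for (i in seq_len(nrow(nb))) {
      rows <- c(rows, sprintf("nearby_residue\t%s\t%s%d\t%s\t%.2f",
                              a$name[nb$lig_row[i]], nb$res_name[i],
                              nb$res_seq[i], nb$chain[i], nb$min_distance[i]))
    }
  }
  br <- interactions$bridges
  if (!is.null(br) && nrow(br)) {
    for (i in seq_len(nrow(br))) {
      steps <- paste(sprintf("%.2f", br$step_distances[[i]]), collapse = ",")
      rows <- c(rows, sprintf("water_bridge\t%s\t%s%d (%d H2O)\t%s\t%s (total %.2f)",
                              a$name[br$lig_row[i]], br$res_name[i],
                              br$res_seq[i], br$n_waters[i], br$chain[i],
                              steps, br$total_distance[i]))
    }
  }
  paste(rows, collapse = "\n")
}
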