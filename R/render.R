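# To-scale locus maps.  One horizontal row per locus/contig, glyph widths
# proportional to gene length in base pairs, serine-protease genes drawn at
# exactly twice the height of other genes so they stand out, strand shown by
# an arrow head on the 3' end of each glyph.  Output is plain SVG text,
# formatted deterministically (fixed number formatting, stable element
# order) so identical inputs render byte-identically.

#' Style settings for locus maps
#'
#' @param px_per_bp Horizontal scale, pixels per base pair.
#' @param gene_height Height in px of a non-protease glyph (proteases are
#'   drawn at exactly twice this).
#' @param row_gap Vertical gap between locus rows, px.
#' @param margin Outer margin, px.
#' @param font_size Label font size, px (0 suppresses labels).
#' @param colors Named vector of fill colours per category.
#' @return A list of class `map_style`.
#' @export
map_style <- function(px_per_bp = 0.01, gene_height = 14, row_gap = 30,
                      margin = 20, font_size = 10,
                      colors = c(protease = "#4477AA", marker = "#999999",
                                 other = "#DDDDDD")) {
  structure(list(px_per_bp = px_per_bp, gene_height = gene_height,
                 row_gap = row_gap, margin = margin, font_size = font_size,
                 colors = colors),
            class = "map_style")
}

fmt_px <- function(x) sprintf("%.3f", x)

#' Render to-scale locus maps as SVG
#'
#' @param loci A `locus_map` or list of them (one row each).
#' @param style A [map_style()].
#' @param path Optional file to write the SVG to.
#' @return The SVG document as a single character string (invisibly when
#'   `path` is given).
#' @export
render_scale_map <- function(loci, style = map_style(), path = NULL) {
  if (inherits(loci, "locus_map")) loci <- list(loci)
  if (length(loci) == 0L)
    abort("No loci to render.", class = "serprot_input_error")
  keep <- vapply(loci, function(l) {
    span <- max(l$genes$end) - min(l$genes$start)
    if (nrow(l$genes) == 0L || span <= 0) {
      warn(sprintf("Skipping zero-length locus '%s'.", l$name))
      FALSE
    } else TRUE
  }, logical(1))
  loci <- loci[keep]
  if (length(loci) == 0L)
    abort("All loci were zero-length.", class = "serprot_input_error")

  h2 <- 2 * style$gene_height            # protease glyph height
  row_h <- h2 + style$row_gap
  width <- max(vapply(loci, function(l)
    (max(l$genes$end) - min(l$genes$start)) * style$px_per_bp, numeric(1))) +
    2 * style$margin
  height <- length(loci) * row_h + 2 * style$margin

  body <- character()
  for (k in seq_along(loci)) {
    l <- loci[[k]]
    g <- dplyr::arrange(l$genes, .data$start)
    x0 <- min(g$start)
    base <- style$margin + (k - 1) * row_h + h2 / 2   # row midline y
    row <- sprintf('<g id="locus-%d" data-name="%s" data-contig="%s">',
                   k, l$name, l$contig)
    if (style$font_size > 0) {
      row <- c(row, sprintf(
        '<text x="%s" y="%s" font-size="%s">%s (%s)</text>',
        fmt_px(style$margin), fmt_px(base - h2 / 2 - 4),
        fmt_px(style$font_size), l$name, l$contig))
    }
    for (i in seq_len(nrow(g))) {
      gh <- if (g$category[i] == "protease") h2 else style$gene_height
      x <- style$margin + (g$start[i] - x0) * style$px_per_bp
      w <- (g$end[i] - g$start[i]) * style$px_per_bp
      y <- base - gh / 2
      fill <- unname(style$colors[g$category[i]] %|NA|% "#DDDDDD")
      arrow <- min(w * 0.25, gh / 2)   # arrow-head depth
      # arrowed glyph: rectangle with a triangular 3' end per strand
      xs <- if (g$strand[i] == "+") {
        c(x, x + w - arrow, x + w, x + w - arrow, x)
      } else {
        c(x + w, x + arrow, x, x + arrow, x + w)
      }
      ys <- c(y, y, y + gh / 2, y + gh, y + gh)
      pts <- paste(paste(fmt_px(xs), fmt_px(ys), sep = ","), collapse = " ")
      row <- c(row, sprintf(
        '<polygon class="gene %s" data-id="%s" data-width="%s" data-height="%s" points="%s" fill="%s" stroke="black" stroke-width="0.5"/>',
        g$category[i], g$gene_id[i], fmt_px(w), fmt_px(gh), pts, fill))
    }
    body <- c(body, row, "</g>")
  }
  svg <- paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s">',
    fmt_px(width), fmt_px(height)),
    body, "</svg>"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Plot a locus map with ggplot2
#'
#' A ggplot rendering of the same to-scale layout as [render_scale_map()]:
#' base-pair-proportional gene boxes, proteases double height.
#'
#' @param object A `locus_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.locus_map <- function(object, ...) {
  g <- compute_geometry(object)
  g$h <- ifelse(g$category == "protease", 1, 0.5)
  ggplot2::ggplot(g) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -.data$h, ymax = .data$h,
                                    fill = .data$category)) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = 1.4, label = .data$gene_id),
                       angle = 45, hjust = 0, size = 3) +
    ggplot2::scale_y_continuous(limits = c(-1.2, 2.5), breaks = NULL) +
    ggplot2::labs(x = sprintf("position on %s (bp)", object$contig), y = NULL,
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- ggplot2::autoplot
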