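# Synteny-based locus reconstruction: protease loci are identified by their
# bordering (marker) genes, which stay put across genomes while the protease
# genes between them duplicate, die and invert.  Coordinates are 0-based
# half-open internally; GFF3 (1-based inclusive) is converted on read.

#' Locus definitions
#'
#' A locus definition names the marker genes bordering a protease locus.
#' `locus_definitions()` loads the packaged defaults (chymase, met-ase, fish
#' chymase-related and granzyme A/K loci); `locus_definition()` builds one
#' programmatically.
#'
#' @param name Locus name.
#' @param left_markers,right_markers Character vectors of marker gene ids;
#'   at least one of the two must be non-empty.
#' @param center_markers Optional character vector of markers expected inside
#'   the locus.
#' @param aliases Named list mapping a canonical marker id to alternative
#'   names used by particular assemblies.
#' @param path Optional YAML file of definitions to load instead of the
#'   packaged one.
#' @return `locus_definition()`: an object of class `locus_definition`;
#'   `locus_definitions()`: a named list of them.
#' @export
locus_definition <- function(name, left_markers = character(),
                             right_markers = character(),
                             center_markers = character(),
                             aliases = list()) {
  left_markers <- as.character(left_markers %||% character())
  right_markers <- as.character(right_markers %||% character())
  center_markers <- as.character(center_markers %||% character())
  if (length(left_markers) + length(right_markers) == 0L)
    warn(sprintf("Locus definition '%s' has no bordering markers; it cannot be matched until markers are supplied.", name))
  structure(list(name = name, left_markers = left_markers,
                 right_markers = right_markers,
                 center_markers = center_markers,
                 aliases = aliases %||% list()),
            class = "locus_definition")
}

#' @rdname locus_definition
#' @export
locus_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "locus_definitions.yaml", package = "serprot")
  raw <- yaml::read_yaml(path)
  defs <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    suppressWarnings(
      locus_definition(nm, d$left_markers, d$right_markers,
                       d$center_markers, d$aliases))
  })
  setNames(defs, names(raw))
}

# canonicalise a gene name under a definition's alias table (lower-case)
canonical_marker <- function(ids, definition) {
  ids <- tolower(ids)
  for (canon in names(definition$aliases)) {
    hits <- ids %in% tolower(unlist(definition$aliases[[canon]]))
    ids[hits] <- tolower(canon)
  }
  ids
}

#' Read a genome annotation as gene records
#'
#' Reads GFF3 or BED into the internal gene-record table.  Coordinates are
#' normalised to 0-based half-open (GFF3 is 1-based inclusive on disk, BED is
#' already 0-based half-open).  Structurally malformed lines are rejected and
#' logged with their line numbers (warning); records whose end does not
#' exceed their start after normalisation are likewise rejected and logged.
#'
#' @param path Annotation file.
#' @param format `"gff3"`, `"bed"`, or `"auto"` (by extension).
#' @return Tibble with columns `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `category` (`protease`, `marker` or `other`; from a `category` attribute
#'   when present, else `other`) and `pseudogene` (logical display attribute
#'   carried from the annotation, never recomputed from sequence).
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- ifelse(body, lengths(strsplit(lines, "\t", fixed = TRUE)), NA)
  if (format == "gff3") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    okline <- body & nfield >= 8 &
      vapply(fields, function(f) length(f) >= 5 &&
               !is.na(suppressWarnings(as.numeric(f[4]))) &&
               !is.na(suppressWarnings(as.numeric(f[5]))) &&
               suppressWarnings(as.numeric(f[5]) >= as.numeric(f[4])),
             logical(1))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    okline <- body & nfield >= 3 &
      vapply(fields, function(f) length(f) >= 3 &&
               !is.na(suppressWarnings(as.numeric(f[2]))) &&
               !is.na(suppressWarnings(as.numeric(f[3]))) &&
               suppressWarnings(as.numeric(f[3]) > as.numeric(f[2])),
             logical(1))
  }
  bad <- which(body & !okline)
  if (length(bad))
    warn(sprintf("Rejected %d malformed line(s): %s", length(bad),
                 paste(bad, collapse = ", ")))
  keep <- lines[!body | okline]
  tmp <- tempfile(fileext = paste0(".", if (format == "bed") "bed" else "gff3"))
  on.exit(unlink(tmp), add = TRUE)
  writeLines(keep, tmp)
  gr <- rtracklayer::import(tmp, format = if (format == "bed") "bed" else "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(mc)) return(as.character(mc[[nm]]))
    rep(NA_character_, length(gr))
  }
  gene_id <- pick("Name", "name", "ID", "gene_id")
  if (anyNA(gene_id)) {
    fallback <- pick("ID")
    gene_id[is.na(gene_id)] <- fallback[is.na(gene_id)]
    gene_id[is.na(gene_id)] <- sprintf("gene_%d", which(is.na(gene_id)))
  }
  category <- pick("category")
  category[is.na(category) | !(category %in% c("protease", "marker", "other"))] <- "other"
  pseudo <- pick("pseudogene")
  pseudo <- !is.na(pseudo) & tolower(pseudo) %in% c("true", "1", "yes")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  out <- tibble(gene_id = gene_id,
                contig = as.character(GenomicRanges::seqnames(gr)),
                start = BiocGenerics::start(gr) - 1L,
                end = BiocGenerics::end(gr),
                strand = strand,
                category = category,
                pseudogene = pseudo)
  degenerate <- out$end <= out$start
  if (any(degenerate)) {
    warn(sprintf("Rejected %d record(s) with end <= start after normalisation: %s",
                 sum(degenerate), paste(out$gene_id[degenerate], collapse = ", ")))
    out <- out[!degenerate, ]
  }
  out
}

#' Write gene records as GFF3
#'
#' Inverse of [read_annotation()] for the internal table (0-based half-open
#' converted back to GFF3's 1-based inclusive).
#'
#' @param genes Gene-record tibble.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  pseudo <- if ("pseudogene" %in% names(genes)) genes$pseudogene else
    rep(FALSE, nrow(genes))
  attrs <- sprintf("ID=%s;Name=%s;category=%s%s",
                   genes$gene_id, genes$gene_id, genes$category,
                   ifelse(pseudo, ";pseudogene=true", ""))
  lines <- sprintf("%s\tserprot\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$contig, genes$start + 1L, genes$end,
                   genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

new_locus_map <- function(name, contig, genes, split = FALSE,
                          marker_count = NA_integer_, diagnostics = NULL) {
  genes <- dplyr::arrange(genes, .data$start)
  structure(list(name = name, contig = contig, genes = genes,
                 split = split, marker_count = marker_count,
                 diagnostics = diagnostics),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("<locus_map> %s on %s: %d genes (%d protease)%s\n",
              x$name, x$contig, nrow(x$genes),
              sum(x$genes$category == "protease"),
              if (x$split) " [split]" else ""))
  invisible(x)
}

#' Identify a protease locus from gene records
#'
#' Finds candidate loci as maximal runs of genes between the innermost
#' matched left and right markers of a [locus_definition()], on one contig.
#' Matching is case-insensitive and alias-resolved.  Flanking markers
#' immediately outside the innermost pair are absorbed into the map (they
#' border the locus in the figures).  A definition may match several regions
#' (paralogous loci); all candidates are returned ranked by matched-marker
#' count.  When left and right markers resolve only to different contigs the
#' locus is reported split, with partial maps for both contigs.
#'
#' @param genes Gene-record tibble from [read_annotation()].
#' @param definition A [locus_definition()].
#' @return List of `locus_map` objects, best candidate first.  When no
#'   marker matches, an empty list carrying a `diagnostics` attribute is
#'   returned (not an error).
#' @export
identify_locus <- function(genes, definition) {
  stopifnot(inherits(definition, "locus_definition"))
  genes <- as_tibble(genes)
  ids <- canonical_marker(genes$gene_id, definition)
  left <- tolower(definition$left_markers)
  right <- tolower(definition$right_markers)
  is_left <- ids %in% left
  is_right <- ids %in% right
  genes$category[is_left | is_right] <- "marker"
  if (!any(is_left) && !any(is_right)) {
    out <- list()
    attr(out, "diagnostics") <-
      sprintf("no marker of locus '%s' matched among %d genes",
              definition$name, nrow(genes))
    inform(attr(out, "diagnostics"))
    return(out)
  }
  candidates <- list()
  for (ctg in unique(genes$contig)) {
    sel <- genes$contig == ctg
    g <- dplyr::arrange(genes[sel, ], .data$start)
    gl <- canonical_marker(g$gene_id, definition)
    side <- ifelse(gl %in% left, "L", ifelse(gl %in% right, "R", NA))
    mk <- which(!is.na(side))
    if (length(mk) == 0L) next
    runs <- split(mk, cumsum(c(TRUE, diff(match(side[mk], c("L", "R"))) != 0)))
    # pair each run with the next run of the opposite side
    if (length(runs) >= 2L) {
      for (k in seq_len(length(runs) - 1L)) {
        a <- runs[[k]]; b <- runs[[k + 1L]]
        if (side[a[1]] == side[b[1]]) next
        inner_a <- a[length(a)]   # innermost marker of the first run
        inner_b <- b[1]
        lo <- inner_a; hi <- inner_b
        # absorb contiguous same-side markers immediately outside the pair
        while (lo - 1L >= 1L && !is.na(side[lo - 1L]) &&
               side[lo - 1L] == side[inner_a]) lo <- lo - 1L
        while (hi + 1L <= nrow(g) && !is.na(side[hi + 1L]) &&
               side[hi + 1L] == side[inner_b]) hi <- hi + 1L
        gg <- g[lo:hi, ]
        candidates[[length(candidates) + 1L]] <-
          new_locus_map(definition$name, ctg, gg, split = FALSE,
                        marker_count = sum(!is.na(side[lo:hi])))
      }
    }
  }
  if (length(candidates) == 0L) {
    # markers found but never both sides on one contig -> split locus
    parts <- list()
    for (ctg in unique(genes$contig)) {
      sel <- genes$contig == ctg
      g <- dplyr::arrange(genes[sel, ], .data$start)
      gl <- canonical_marker(g$gene_id, definition)
      lidx <- which(gl %in% left); ridx <- which(gl %in% right)
      if (length(lidx)) {
        gg <- g[min(lidx):nrow(g), ]
        parts[[length(parts) + 1L]] <-
          new_locus_map(definition$name, ctg, gg, split = TRUE,
                        marker_count = length(lidx))
      } else if (length(ridx)) {
        gg <- g[1:max(ridx), ]
        parts[[length(parts) + 1L]] <-
          new_locus_map(definition$name, ctg, gg, split = TRUE,
                        marker_count = length(ridx))
      }
    }
    candidates <- parts
  }
  ord <- order(vapply(candidates, function(x) x$marker_count, integer(1)),
               decreasing = TRUE)
  candidates[ord]
}

#' Gene and intergene geometry of a locus
#'
#' Sizes are `end - start`; intergenic distances are `next start - previous
#' end`, clamped to 0 with an overlap flag when genes overlap.  For
#' non-overlapping loci the sizes and distances sum to the locus span.
#'
#' @param locus A `locus_map` from [identify_locus()] (or any gene-record
#'   tibble).
#' @return Tibble: `gene_id`, `category`, `strand`, `start`, `end`, `size`,
#'   `distance_to_next` (NA for the last gene), `overlaps_next`.
#' @export
compute_geometry <- function(locus) {
  genes <- if (inherits(locus, "locus_map")) locus$genes else as_tibble(locus)
  if (nrow(genes) == 0L)
    abort("Empty locus.", class = "serprot_input_error")
  genes <- dplyr::arrange(genes, .data$start)
  nxt_start <- c(genes$start[-1], NA_integer_)
  gap <- nxt_start - genes$end
  tibble(gene_id = genes$gene_id, category = genes$category,
         strand = genes$strand, start = genes$start, end = genes$end,
         size = genes$end - genes$start,
         distance_to_next = pmax(gap, 0L),
         overlaps_next = !is.na(gap) & gap < 0L)
}

#' Detect marker inversions against a reference orientation
#'
#' Flags each marker whose strand differs from its stated reference
#' orientation (the opossum-style signal that an inversion broke the locus).
#'
#' @param locus A `locus_map`.
#' @param reference_orientation Named character vector, marker id ->
#'   `"+"`/`"-"`.
#' @return Tibble: `marker`, `strand`, `reference_strand`, `inverted`.
#'   Markers present in the locus but absent from the reference map are
#'   skipped with a warning.
#' @export
detect_inversion <- function(locus, reference_orientation) {
  genes <- if (inherits(locus, "locus_map")) locus$genes else as_tibble(locus)
  markers <- genes[genes$category == "marker", ]
  if (nrow(markers) == 0L)
    return(tibble(marker = character(), strand = character(),
                  reference_strand = character(), inverted = logical()))
  ref_names <- tolower(names(reference_orientation))
  known <- tolower(markers$gene_id) %in% ref_names
  if (any(!known))
    warn(sprintf("No reference orientation for marker(s) %s; skipped.",
                 paste(markers$gene_id[!known], collapse = ", ")))
  if (!any(known))
    abort("Reference orientation covers no marker present in the locus.",
          class = "serprot_input_error")
  m <- markers[known, ]
  ref <- unname(reference_orientation[match(tolower(m$gene_id), ref_names)])
  tibble(marker = m$gene_id, strand = m$strand, reference_strand = ref,
         inverted = m$strand != ref)
}
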