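# Newick IO.  A small recursive-descent reader/writer is used instead of the
# usual tree readers because the round-trip contract here includes quoted
# labels containing spaces and parse errors that report the character
# offset.  Trees are carried as ape "phylo" objects throughout.

#' Read and write Newick trees
#'
#' `read_newick()` parses a Newick string (or the first line of a file) into
#' an ape `phylo` object; `write_newick()` is its inverse.  Round trips
#' preserve topology, branch lengths (to 1e-9), labels (including quoted
#' labels with spaces) and support values, which are written as internal
#' node labels.  Malformed input raises a parse error naming the character
#' offset.
#'
#' @param x Newick string, or path to a file containing one.
#' @param tree An ape `phylo` object.
#' @param path Optional output file.
#' @param digits Significant digits for branch lengths on write.
#' @return `read_newick()`: a `phylo`; `write_newick()`: the Newick string
#'   (invisibly if `path` is given).
#' @examples
#' tr <- read_newick("(A:1,B:1,(C:1,D:1)95:2);")
#' write_newick(tr)
#' @export
read_newick <- function(x) {
  if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
    x <- readLines(x, warn = FALSE)[1]
  if (!is.character(x) || length(x) != 1L)
    abort("Expected a single Newick string or file path.",
          class = "serprot_input_error")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L
  perr <- function(msg, at = pos)
    abort(sprintf("Newick parse error at character %d: %s", at, msg),
          class = "serprot_parse_error")
  skip_ws <- function() while (pos <= n && chars[pos] %in% c(" ", "\t", "\n")) pos <<- pos + 1L
  read_label <- function() {
    skip_ws()
    if (pos <= n && chars[pos] == "'") {
      start <- pos; pos <<- pos + 1L
      out <- character()
      repeat {
        if (pos > n) perr("unterminated quoted label", start)
        if (chars[pos] == "'") {
          if (pos + 1L <= n && chars[pos + 1L] == "'") { # escaped quote
            out <- c(out, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { out <- c(out, chars[pos]); pos <<- pos + 1L }
      }
      paste(out, collapse = "")
    } else {
      out <- character()
      while (pos <= n && !(chars[pos] %in% c(",", ":", ";", "(", ")", " ", "\t", "\n")))
        { out <- c(out, chars[pos]); pos <<- pos + 1L }
      paste(out, collapse = "")
    }
  }
  read_length <- function() {
    skip_ws()
    if (pos <= n && chars[pos] == ":") {
      pos <<- pos + 1L; skip_ws()
      start <- pos
      while (pos <= n && (chars[pos] %in% c(0:9, ".", "-", "+", "e", "E")))
        pos <<- pos + 1L
      if (pos == start) perr("expected a branch length after ':'")
      v <- suppressWarnings(as.numeric(paste(chars[start:(pos - 1L)], collapse = "")))
      if (is.na(v)) perr("invalid branch length", start)
      v
    } else NA_real_
  }
  read_clade <- function() {
    skip_ws()
    if (pos > n) perr("unexpected end of input")
    if (chars[pos] == "(") {
      open_at <- pos; pos <<- pos + 1L
      kids <- list(read_clade())
      repeat {
        skip_ws()
        if (pos > n) perr("unmatched '('", open_at)
        if (chars[pos] == ",") { pos <<- pos + 1L; kids <- c(kids, list(read_clade())) }
        else if (chars[pos] == ")") { pos <<- pos + 1L; break }
        else perr(sprintf("expected ',' or ')' but found '%s'", chars[pos]))
      }
      lab <- read_label()
      len <- read_length()
      list(children = kids, label = lab, length = len)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) perr("expected a taxon label")
      len <- read_length()
      list(children = NULL, label = lab, length = len)
    }
  }
  root <- read_clade()
  skip_ws()
  if (pos > n || chars[pos] != ";") perr("expected ';'")
  clade_to_phylo(root)
}

clade_to_phylo <- function(root) {
  tip_label <- character(); node_label <- character()
  edges <- list(); elen <- numeric()
  n_tip <- 0L; n_node <- 0L
  # first pass: count
  count <- function(cl) {
    if (is.null(cl$children)) n_tip <<- n_tip + 1L
    else { n_node <<- n_node + 1L; for (k in cl$children) count(k) }
  }
  count(root)
  tip_i <- 0L; node_i <- 0L
  # two passes so the edge list comes out in preorder (parent edges first,
  # the cladewise order downstream traversals rely on)
  annotate <- function(cl) {
    if (is.null(cl$children)) {
      tip_i <<- tip_i + 1L
      tip_label[tip_i] <<- cl$label
      cl$id <- tip_i
    } else {
      node_i <<- node_i + 1L
      cl$id <- n_tip + node_i
      node_label[node_i] <<- cl$label %||% ""
      cl$children <- lapply(cl$children, annotate)
    }
    cl
  }
  walk <- function(cl) {
    if (is.null(cl$children)) return(invisible())
    for (k in cl$children) {
      edges[[length(edges) + 1L]] <<- c(cl$id, k$id)
      elen[length(elen) + 1L] <<- k$length
    }
    for (k in cl$children) walk(k)
  }
  if (is.null(root$children))
    abort("A tree needs at least two taxa.", class = "serprot_parse_error")
  walk(annotate(root))
  tr <- list(edge = do.call(rbind, edges), Nnode = n_node,
             tip.label = tip_label)
  if (any(!is.na(elen))) tr$edge.length <- elen
  if (any(nzchar(node_label))) tr$node.label <- node_label
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(l) {
    if (grepl("[][ ,:;()'\"\t]", l))
      paste0("'", gsub("'", "''", l, fixed = TRUE), "'")
    else l
  }
  fmt_len <- function(i) {
    if (is.null(tree$edge.length) || is.na(tree$edge.length[i])) ""
    else paste0(":", format(tree$edge.length[i], digits = digits,
                            scientific = FALSE, trim = TRUE))
  }
  rec <- function(node) {
    if (node <= ntip) return(quote_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r)
      paste0(rec(tree$edge[r, 2]), fmt_len(r)), character(1))
    lab <- if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - ntip]
      if (is.na(l) || !nzchar(l)) "" else quote_label(l)
    } else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}
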