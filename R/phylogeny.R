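# Distance-based phylogenetics: pairwise protein distances, neighbor
# joining, column-resampling bootstrap and majority-rule consensus -- the
# classic distance arm (sequence bootstrap -> distances -> NJ -> consensus).
# Tie-breaking is lowest-index everywhere so runs are bit-reproducible.

#' Pairwise protein distance
#'
#' Distances are computed over comparable columns only (both residues
#' non-gap and non-X).  `p-distance` is the mismatch fraction; `poisson`
#' applies the correction d = -ln(1 - p).  Saturated pairs (p at or above
#' `saturation_cap`) are capped at the distance of the cap with a warning.
#' Triangle inequality is not guaranteed under the Poisson correction.
#'
#' @param a,b Aligned amino-acid strings of equal length (gaps `-`, unknown
#'   `X` allowed).
#' @param model `"poisson"` (default) or `"p-distance"`.
#' @param saturation_cap Proportion above which distances are capped.
#' @return Non-negative distance (scalar).
#' @export
protein_distance <- function(a, b, model = c("poisson", "p-distance"),
                             saturation_cap = 0.95) {
  model <- match.arg(model)
  check_aa_string(a, "a", allow_gap = TRUE)
  check_aa_string(b, "b", allow_gap = TRUE)
  if (nchar(a) != nchar(b))
    abort("Aligned sequences must have equal length.", class = "serprot_input_error")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  comparable <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  nc <- sum(comparable)
  if (nc == 0L)
    abort("No comparable columns; distance undefined.",
          class = "serprot_undefined_distance")
  p <- sum(ca[comparable] != cb[comparable]) / nc
  if (model == "p-distance") return(p)
  if (p >= saturation_cap) {
    warn(sprintf("p = %.3f at or above saturation cap %.2f; distance capped.",
                 p, saturation_cap))
    p <- saturation_cap
  }
  -log(1 - p)
}

#' Pairwise distance matrix for an alignment
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, `AAStringSet`, or FASTA path.
#' @inheritParams protein_distance
#' @return Symmetric numeric matrix with zero diagonal and taxa as
#'   dimnames; the model name is stored in the `model` attribute.
#' @export
distance_matrix <- function(alignment, model = c("poisson", "p-distance"),
                            saturation_cap = 0.95) {
  model <- match.arg(model)
  seqs <- as_aa_set(alignment)
  ids <- names(seqs)
  r <- length(seqs)
  d <- matrix(0, r, r, dimnames = list(ids, ids))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    d[i, j] <- d[j, i] <- protein_distance(seqs[[i]], seqs[[j]], model,
                                           saturation_cap)
  }
  attr(d, "model") <- model
  d
}

#' Neighbor joining
#'
#' Standard neighbor joining: iteratively joins the pair minimising the
#' Q-criterion, with branch lengths from the NJ formulas.  On an additive
#' matrix the unique generating topology is recovered with exact branch
#' lengths.  Ties are broken towards the lowest index pair; negative branch
#' lengths are clamped to 0 with a warning.
#'
#' @param m Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted ape `phylo` tree.
#' @examples
#' m <- matrix(c(0,2,4, 2,0,4, 4,4,0), 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(m)$edge.length  # 1, 1, 3
#' @export
neighbor_joining <- function(m) {
  m <- as.matrix(m)
  r <- nrow(m)
  if (r < 3L)
    abort("Neighbor joining needs at least 3 taxa.", class = "serprot_input_error")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(r))
  if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0) || any(m < 0) ||
      any(!is.finite(m)))
    abort("Distance matrix must be symmetric, finite, non-negative with zero diagonal.",
          class = "serprot_input_error")
  labels <- rownames(m)
  # each active node carries a growing newick fragment
  frag <- vapply(labels, function(l) {
    if (grepl("[][ ,:;()'\"\t]", l)) paste0("'", gsub("'", "''", l, fixed = TRUE), "'") else l
  }, character(1))
  clamped <- FALSE
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  clamp <- function(x) { if (x < 0) { clamped <<- TRUE; 0 } else x }
  D <- m
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest-index tie-break: scan upper triangle row-major
    best <- c(NA, NA); bq <- Inf
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep],
                                      paste0("int", nrow(D2)))
    D <- D2
  }
  # final three-point join
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped) warn("Negative branch length(s) clamped to 0.")
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb), ",",
                frag[3], ":", fmt(lc), ");")
  read_newick(nwk)
}

# Canonical bipartition keys of a phylo tree: for each internal edge, the
# leaf-name set on the side not containing the first taxon (sorted, pasted).
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- vector("list", ntip + tree$Nnode)
  fill <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    out <- unlist(lapply(kids[[as.character(node)]], fill))
    desc[[node]] <<- out
    out
  }
  fill(ntip + 1L)
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  keys <- vapply(internal_children, function(node) {
    side <- desc[[node]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) return(NA_character_)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and scores each internal edge of the full-data tree by
#' the percentage of replicate trees containing the same bipartition.  One
#' master seed drives independent per-replicate substreams, so results are
#' reproducible and replicate i never depends on how many replicates run.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (>= 3), `AAStringSet`, or FASTA path.
#' @param replicates Number of bootstrap replicates (default 100, the
#'   standard protocol for this analysis).
#' @param seed Integer seed.
#' @param model,saturation_cap Passed to [distance_matrix()].
#' @return The full-data NJ tree (`phylo`, subclass `protease_tree`) with
#'   integer percentage supports as `node.label` and metadata attributes
#'   (`model`, `replicates`, `seed`).
#' @export
bootstrap_support <- function(alignment, replicates = 100, seed = 1,
                              model = c("poisson", "p-distance"),
                              saturation_cap = 0.95) {
  model <- match.arg(model)
  seqs <- as_aa_set(alignment)
  if (length(seqs) < 3L)
    abort("Need at least 3 sequences.", class = "serprot_input_error")
  if (replicates < 1L)
    abort("`replicates` must be >= 1.", class = "serprot_input_error")
  len <- unique(nchar(unlist(seqs)))
  if (length(len) != 1L)
    abort("Aligned sequences must have equal length.", class = "serprot_input_error")
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  full <- neighbor_joining(distance_matrix(unlist(seqs), model, saturation_cap))
  bip_full <- bipartitions(full)
  counts <- setNames(numeric(length(bip_full)), bip_full)
  rep_seeds <- withr::with_seed(derive_seed(seed, "bootstrap"),
                                sample.int(2^31 - 1L, replicates))
  for (b in seq_len(replicates)) {
    cols <- withr::with_seed(rep_seeds[b],
                             sample.int(len, len, replace = TRUE))
    res <- vapply(chars, function(x) paste(x[cols], collapse = ""), character(1))
    tb <- tryCatch(
      suppressWarnings(neighbor_joining(distance_matrix(res, model, saturation_cap))),
      error = function(e) NULL)
    if (is.null(tb)) next
    hits <- bipartitions(tb)
    seen <- bip_full %in% hits
    counts[seen] <- counts[seen] + 1
  }
  support <- round(100 * counts / replicates)
  # attach supports as internal node labels of the full tree
  ntip <- length(full$tip.label)
  kids <- split(full$edge[, 2], full$edge[, 1])
  desc <- function(node) {
    if (node <= ntip) return(full$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  ref <- sort(full$tip.label)[1]
  labs <- vapply(seq_len(full$Nnode) + ntip, function(node) {
    side <- desc(node)
    if (length(side) <= 1L || length(side) >= ntip - 1L) return("")
    if (ref %in% side) side <- setdiff(full$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) as.character(as.integer(support[key])) else ""
  }, character(1))
  full$node.label <- labs
  class(full) <- c("protease_tree", "phylo")
  attr(full, "model") <- model
  attr(full, "replicates") <- as.integer(replicates)
  attr(full, "seed") <- as.integer(seed)
  full
}

#' Majority-rule consensus of trees
#'
#' Keeps exactly the non-trivial bipartitions whose frequency across the
#' input trees strictly exceeds `threshold` (no greedy completion) and
#' assembles them into a tree; support percentages are attached as internal
#' node labels.
#'
#' @param trees List of `phylo` objects on an identical leaf set.
#' @param threshold Frequency a bipartition must exceed (default 0.5).
#' @return A `phylo` consensus tree.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (!length(trees) || !all(vapply(trees, inherits, logical(1), "phylo")))
    abort("`trees` must be a non-empty list of phylo objects.",
          class = "serprot_input_error")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets, identical, logical(1), leafsets[[1]])))
    abort("All trees must share an identical leaf set.",
          class = "serprot_input_error")
  taxa <- leafsets[[1]]
  all_bips <- unlist(lapply(trees, bipartitions))
  freq <- table(all_bips) / length(trees)
  keep <- names(freq)[freq > threshold]
  # bipartition key -> clade on the side away from the reference taxon
  clades <- lapply(keep, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  ord <- order(lengths(clades))
  clades <- clades[ord]
  supports <- as.integer(round(100 * as.numeric(freq[keep])))[ord]
  # build rooted containment tree: root holds all taxa
  node <- function(members, support = NA) list(members = members,
                                               support = support,
                                               children = list())
  root <- node(taxa)
  insert <- function(tree_node, cl, sup) {
    for (i in seq_along(tree_node$children)) {
      ch <- tree_node$children[[i]]
      if (all(cl %in% ch$members)) {
        tree_node$children[[i]] <- insert(ch, cl, sup)
        return(tree_node)
      }
    }
    # adopt children that are subsets of the new clade
    newn <- node(cl, sup)
    keep_idx <- logical(length(tree_node$children))
    for (i in seq_along(tree_node$children)) {
      ch <- tree_node$children[[i]]
      if (all(ch$members %in% cl)) newn$children <- c(newn$children, list(ch))
      else keep_idx[i] <- TRUE
    }
    tree_node$children <- c(tree_node$children[keep_idx], list(newn))
    tree_node
  }
  for (i in rev(seq_along(clades)))   # largest first
    root <- insert(root, clades[[i]], supports[i])
  to_newick <- function(nd) {
    covered <- unlist(lapply(nd$children, function(ch) ch$members))
    singles <- setdiff(nd$members, covered)
    parts <- c(vapply(nd$children, to_newick, character(1)),
               vapply(singles, function(l) {
                 if (grepl("[][ ,:;()'\"\t]", l))
                   paste0("'", gsub("'", "''", l, fixed = TRUE), "'") else l
               }, character(1)))
    lab <- if (is.na(nd$support)) "" else as.character(nd$support)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  read_newick(paste0(to_newick(root), ";"))
}

#' Tidy a bootstrap tree into its bipartition table
#'
#' @param x A `protease_tree` from [bootstrap_support()].
#' @param ... Unused.
#' @return Tibble: `bipartition` (taxa on the side away from the
#'   alphabetically first taxon, `|`-separated), `support` (percent).
#' @exportS3Method generics::tidy
tidy.protease_tree <- function(x, ...) {
  ntip <- length(x$tip.label)
  keys <- bipartitions(x)
  # recover support from node labels
  kids <- split(x$edge[, 2], x$edge[, 1])
  desc <- function(node) {
    if (node <= ntip) return(x$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  ref <- sort(x$tip.label)[1]
  rows <- lapply(seq_len(x$Nnode) + ntip, function(node) {
    side <- desc(node)
    if (length(side) <= 1L || length(side) >= ntip - 1L) return(NULL)
    if (ref %in% side) side <- setdiff(x$tip.label, side)
    tibble(bipartition = paste(sort(side), collapse = "|"),
           support = as.integer(x$node.label[node - ntip]))
  })
  bind_rows(rows)
}

#' @rdname tidy.protease_tree
#' @exportS3Method generics::glance
glance.protease_tree <- function(x, ...) {
  tb <- tidy(x)
  tibble(n_taxa = length(x$tip.label),
         n_internal_edges = nrow(tb),
         replicates = attr(x, "replicates"),
         model = attr(x, "model"),
         mean_support = if (nrow(tb)) mean(tb$support) else NA_real_,
         min_support = if (nrow(tb)) min(tb$support) else NA_real_)
}
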