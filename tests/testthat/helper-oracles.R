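# Independent oracles used across the suite.  These are deliberately
# separate implementations (plain R, different algorithmic shape) of the
# quantities the package computes.

# --- exhaustive affine-gap global alignment score (no traceback) ----------
# gap of length L costs open + (L-1)*ext, same scoring definition as the
# package but recomputed from scratch.
oracle_align_score <- function(q, r, mat, open, ext) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  M <- matrix(-Inf, n + 1, m + 1)
  GU <- matrix(-Inf, n + 1, m + 1)  # gap consuming query
  GL <- matrix(-Inf, n + 1, m + 1)  # gap consuming reference
  M[1, 1] <- 0
  for (i in seq_len(n)) GU[i + 1, 1] <- open + (i - 1) * ext
  for (j in seq_len(m)) GL[1, j + 1] <- open + (j - 1) * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[qc[i], rc[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], GU[i, j], GL[i, j])
      GU[i + 1, j + 1] <- max(M[i, j + 1] + open,
                              GU[i, j + 1] + ext,
                              GL[i, j + 1] + open)
      GL[i + 1, j + 1] <- max(M[i + 1, j] + open,
                              GU[i + 1, j] + open,
                              GL[i + 1, j] + ext)
    }
  }
  max(M[n + 1, m + 1], GU[n + 1, m + 1], GL[n + 1, m + 1])
}

random_aa <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# --- exhaustive unrooted topology enumeration + least-squares fit ---------
# topologies as edge matrices over leaves 1..n and internal nodes n+1, ...
enum_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- cbind(c(n + 1, n + 1, n + 1), c(1, 2, 3))
  tops <- list(base)
  if (n == 3) return(tops)
  for (k in 4:n) {
    newint <- n + (k - 2)
    out <- list()
    for (tp in tops) {
      for (e in seq_len(nrow(tp))) {
        a <- tp[e, 1]; b <- tp[e, 2]
        t2 <- rbind(tp[-e, , drop = FALSE],
                    c(a, newint), c(newint, b), c(newint, k))
        out[[length(out) + 1]] <- t2
      }
    }
    tops <- out
  }
  tops
}

# edges on the path between two leaves (BFS on the unrooted tree)
path_edges <- function(edges, from, to) {
  adj <- list()
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
    adj[[a]] <- rbind(adj[[a]], c(edges[e, 2], e))
    adj[[b]] <- rbind(adj[[b]], c(edges[e, 1], e))
  }
  prev <- list(); seen <- as.character(from); queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (row in seq_len(nrow(adj[[as.character(v)]] %||0% matrix(0, 0, 2)))) {
      nb <- adj[[as.character(v)]][row, 1]; ee <- adj[[as.character(v)]][row, 2]
      if (!(as.character(nb) %in% seen)) {
        seen <- c(seen, as.character(nb))
        prev[[as.character(nb)]] <- c(v, ee)
        queue <- c(queue, nb)
      }
    }
  }
  path <- integer(); v <- to
  while (v != from) {
    st <- prev[[as.character(v)]]
    path <- c(path, st[2]); v <- st[1]
  }
  path
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# least-squares SSE of fitting branch lengths of a topology to a distance
# matrix over leaves 1..n (unconstrained LS)
ls_sse <- function(edges, d) {
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    A[p, path_edges(edges, pairs[p, 1], pairs[p, 2])] <- 1
  }
  y <- d[pairs]
  fit <- lm.fit(A, y)
  sum(fit$residuals^2)
}

# canonical bipartition keys of a topology over leaf names
topo_bipartitions <- function(edges, leaf_names) {
  n <- length(leaf_names)
  keys <- character()
  for (e in seq_len(nrow(edges))) {
    # leaves reachable from edges[e,2] without crossing edge e
    side <- integer(); queue <- edges[e, 2]; seen <- edges[e, 2]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v <= n) side <- c(side, v)
      nbr <- c(edges[edges[, 1] == v & seq_len(nrow(edges)) != e, 2],
               edges[edges[, 2] == v & seq_len(nrow(edges)) != e, 1])
      nbr <- setdiff(nbr, seen)
      seen <- c(seen, nbr); queue <- c(queue, nbr)
    }
    if (length(side) <= 1 || length(side) >= n - 1) next
    lab <- leaf_names[side]
    if (leaf_names[1] %in% lab) lab <- setdiff(leaf_names, lab)
    keys <- c(keys, paste(sort(lab), collapse = "|"))
  }
  sort(unique(keys))
}

# bipartition keys of a phylo tree, via ape machinery (independent of the
# package's internal bipartition code)
phylo_bipartitions_ape <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (length(side) <= 1 || length(side) >= n - 1) return(NA_character_)
    if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

# direct re-application of the packaged rule table (classifier oracle)
oracle_classify <- function(triplet, triad_intact, rules) {
  if (!triad_intact) return(c("unknown", "inactive"))
  if (grepl("-", triplet, fixed = TRUE)) return(c("unknown", "unassigned"))
  hit <- which(rules$type == "triplet" & rules$pattern == triplet)
  if (length(hit)) return(c(rules$label[hit[1]], rules$tier[hit[1]]))
  fb <- which(rules$type == "pos189" & rules$pattern == substr(triplet, 1, 1))
  if (length(fb)) return(c(rules$label[fb[1]], rules$tier[fb[1]]))
  c("unknown", "unassigned")
}

# brute-force locus scan: all (left, right) marker index pairs on a contig,
# locus = genes between the closest valid pair (either orientation),
# extended over contiguous same-side markers
oracle_locus_genes <- function(genes, left, right) {
  best <- NULL; best_len <- Inf
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, ]
    g <- g[order(g$start), ]
    ids <- tolower(g$gene_id)
    li <- which(ids %in% tolower(left)); ri <- which(ids %in% tolower(right))
    for (i in li) for (j in ri) {
      lo <- min(i, j); hi <- max(i, j)
      inner <- if (hi > lo + 1) (lo + 1):(hi - 1) else integer()
      # innermost pair: no other marker of either side strictly inside
      if (any(ids[inner] %in% tolower(c(left, right)))) next
      span <- hi - lo
      if (span < best_len) { best_len <- span; best <- g$gene_id[lo:hi] }
    }
  }
  best
}
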