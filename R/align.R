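#' Global alignment of a query protease to the reference scaffold
#'
#' Needleman-Wunsch global alignment with affine gap penalties, used to carry
#' canonical chymotrypsinogen numbering from the reference scaffold onto a
#' query sequence.  The dynamic program is exact (optimal score) and the
#' traceback is deterministic, preferring diagonal over up (query-consuming
#' gap) over left, so repeated runs are bit-identical.
#'
#' @param query Amino-acid string (20 canonical letters, X allowed).
#' @param reference A [reference_scaffold()] object.
#' @param params An [alignment_params()] object.
#' @return Object of class `protease_alignment`: `aligned_query`,
#'   `aligned_reference` (gapped strings of equal length), `score`, and the
#'   `reference` used.
#' @examples
#' sc <- scaffold_default()
#' aln <- align_global(sc$residues, sc)
#' aln$score
#' @export
align_global <- function(query, reference = scaffold_default(),
                         params = alignment_params()) {
  check_aa_string(query, "query")
  stopifnot(inherits(reference, "protease_scaffold"),
            inherits(params, "alignment_params"))
  m <- params$substitution_matrix
  alpha <- rownames(m)
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  rc <- strsplit(reference$residues, "", fixed = TRUE)[[1]]
  qi <- match(qc, alpha) - 1L
  ri <- match(rc, alpha) - 1L
  if (anyNA(qi))
    abort(sprintf("Query contains residue '%s' absent from the substitution matrix.",
                  qc[which(is.na(qi))[1]]), class = "serprot_input_error")
  if (anyNA(ri))
    abort("Reference contains residues absent from the substitution matrix.",
          class = "serprot_input_error")
  res <- .nw_affine(qi, ri, m, params$gap_open, params$gap_extend)
  ops <- res$ops
  aq <- character(length(ops)); ar <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == 0L) { i <- i + 1L; j <- j + 1L; aq[k] <- qc[i]; ar[k] <- rc[j] }
    else if (op == 1L) { i <- i + 1L; aq[k] <- qc[i]; ar[k] <- "-" }
    else { j <- j + 1L; aq[k] <- "-"; ar[k] <- rc[j] }
  }
  structure(list(aligned_query = paste(aq, collapse = ""),
                 aligned_reference = paste(ar, collapse = ""),
                 score = res$score,
                 reference = reference,
                 params = params),
            class = "protease_alignment")
}

#' @export
print.protease_alignment <- function(x, ...) {
  cat(sprintf("<protease_alignment> score %.1f, %d columns\n",
              x$score, nchar(x$aligned_query)))
  invisible(x)
}
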