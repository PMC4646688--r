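#' Assign canonical chymotrypsinogen numbering from an alignment
#'
#' Reads a pairwise alignment produced by [align_global()] column by column:
#' every reference column carrying canonical label L that is aligned to a
#' non-gap query residue maps L to that query position.  Query residues
#' falling in reference gaps (insertions) receive no label; insertion codes
#' (95A-style) are not used.  Labels falling in query gaps (deletions) are
#' absent from the map.
#'
#' @param alignment A `protease_alignment` from [align_global()].
#' @param reference The scaffold the alignment was made against; defaults to
#'   the one stored in the alignment.  Supplying a different scaffold is a
#'   contract error.
#' @return Object of class `numbered_protease`: `sequence` (ungapped query),
#'   `numbering` (named integer vector, canonical label -> 1-based query
#'   index), `alignment_score`.
#' @examples
#' sc <- scaffold_default()
#' ns <- assign_numbering(align_global(sc$residues, sc))
#' residue_at(ns, 195)
#' @export
assign_numbering <- function(alignment, reference = NULL) {
  stopifnot(inherits(alignment, "protease_alignment"))
  if (is.null(reference)) reference <- alignment$reference
  if (!identical(reference$residues, alignment$reference$residues) ||
      !identical(reference$labels, alignment$reference$labels))
    abort("`reference` differs from the scaffold used to build the alignment.",
          class = "serprot_contract_error")
  aq <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  ar <- strsplit(alignment$aligned_reference, "", fixed = TRUE)[[1]]
  qpos <- cumsum(aq != "-")
  rpos <- cumsum(ar != "-")
  both <- aq != "-" & ar != "-"
  numbering <- setNames(as.integer(qpos[both]),
                        reference$labels[rpos[both]])
  structure(list(sequence = gsub("-", "", alignment$aligned_query, fixed = TRUE),
                 numbering = numbering,
                 alignment_score = alignment$score,
                 labels = reference$labels,
                 site_registry = reference$site_registry),
            class = "numbered_protease")
}

#' Residue at a canonical position
#'
#' @param numbered A `numbered_protease` from [assign_numbering()].
#' @param label Canonical position label (integer scalar).  Must be one of
#'   the scaffold's labels; unknown labels are an error.
#' @return One-letter residue, or `NA_character_` when the label falls in a
#'   query gap (absent).
#' @export
residue_at <- function(numbered, label) {
  stopifnot(inherits(numbered, "numbered_protease"))
  if (!is_scalar_number(label))
    abort("`label` must be a single number.", class = "serprot_input_error")
  label <- as.integer(label)
  if (!(label %in% numbered$labels))
    abort(sprintf("Unknown canonical label %d.", label),
          class = "serprot_input_error")
  idx <- numbered$numbering[as.character(label)]
  if (is.na(idx)) return(NA_character_)
  substr(numbered$sequence, idx, idx)
}

#' @export
print.numbered_protease <- function(x, ...) {
  cat(sprintf("<numbered_protease> %d residues, %d labelled, score %.1f\n",
              nchar(x$sequence), length(x$numbering), x$alignment_score))
  invisible(x)
}

#' Number a set of sequences and tabulate the result
#'
#' Convenience wrapper running [align_global()] + [assign_numbering()] over a
#' named set of sequences and returning the long-format numbering report.
#'
#' @param sequences Named character vector of amino-acid strings, or an
#'   `AAStringSet`, or a path to a FASTA file.
#' @param reference,params As in [align_global()].
#' @return A tibble with columns `seq_id`, `label`, `query_index` (0-based,
#'   matching the on-disk report convention) and `residue`, one row per
#'   mapped label, plus a `numbered` attribute holding the
#'   `numbered_protease` objects.
#' @export
number_sequences <- function(sequences, reference = scaffold_default(),
                             params = alignment_params()) {
  seqs <- as_aa_set(sequences)
  numbered <- lapply(seqs, function(s)
    assign_numbering(align_global(s, reference, params)))
  tab <- purrr::imap(numbered, function(ns, id) {
    tibble(seq_id = id,
           label = as.integer(names(ns$numbering)),
           query_index = unname(ns$numbering) - 1L,
           residue = vapply(unname(ns$numbering), function(i)
             substr(ns$sequence, i, i), character(1)))
  }) %>% bind_rows()
  attr(tab, "numbered") <- numbered
  tab
}

#' Write a numbering report as TSV
#'
#' @param numbering_table Output of [number_sequences()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_numbering_tsv <- function(numbering_table, path) {
  readr::write_tsv(numbering_table[, c("seq_id", "label", "query_index", "residue")],
                   path)
  invisible(path)
}
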