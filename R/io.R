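# FASTA IO (Biostrings) and input coercion

#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings.  `write_fasta()` wraps sequence lines at
#' 60 columns.
#'
#' @param path File path.
#' @param sequences Named character vector of amino-acid strings.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# accept a named character vector, AAStringSet, or FASTA path
as_aa_set <- function(sequences) {
  if (inherits(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (!is.character(sequences))
    abort("Expected a named character vector, AAStringSet or FASTA path.",
          class = "serprot_input_error")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    abort("Sequences must carry unique names.", class = "serprot_input_error")
  as.list(sequences)
}
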