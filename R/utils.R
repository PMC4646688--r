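# shared small helpers

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# validate an amino-acid string; X allowed, gaps optionally
check_aa_string <- function(x, name = "sequence", allow_gap = FALSE, allow_x = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    abort(sprintf("`%s` must be a single character string.", name), class = "serprot_input_error")
  if (nchar(x) == 0L)
    abort(sprintf("`%s` is empty.", name), class = "serprot_input_error")
  ok <- AA20
  if (allow_x) ok <- c(ok, "X")
  if (allow_gap) ok <- c(ok, "-")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% ok))
  if (length(bad)) {
    abort(sprintf("Illegal character '%s' at position %d of `%s`.",
                  chars[bad[1]], bad[1], name),
          class = "serprot_input_error")
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic substream seeds derived from one master seed; keeps streams
# for different purposes independent so adding a draw in one never shifts another
derive_seed <- function(seed, stream) {
  stopifnot(is_scalar_number(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 999983L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
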