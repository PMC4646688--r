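# Reference scaffold for canonical chymotrypsinogen numbering.
#
# The scaffold is a synthetic chymotrypsinogen-like anchor, not a database
# sequence: a fixed 245-residue string with the canonical functional residues
# planted at their chymotrypsinogen positions (His57, Asp102, Ser195 triad;
# Ser189/Gly216/Gly226 chymotrypsin-like S1 pocket; Cys191/Cys220 bridge; a
# non-cysteine at 93).  Canonical numbering is defined relative to
# chymotrypsinogen, so any anchor carrying the registry sites at the stated
# labels defines the same coordinate system.

.SCAFFOLD_SEQ <- paste0(
  "TRWLNKPWLRIIACQCGFWQWRSVEQLWMIGIHAWVICEAESEPDVETDTFPAIQTHMNS",
  "YYGTTKYPAHDLTDSGVVFDFLAIAVNQTYMENQFVYRWCEDKDPSTEPYMVHYLYAGAW",
  "DLSLCIGHMPNLALEQQHKGKVCWWPNNAVMEATHGMVRPREKFEEGPHRDSGFVFKVKS",
  "KIADKDVASHCDAVSEKFRSNRHRCKYWWIVNEDIGSCTCQFFIEGIRNEQVNDPVWVGK",
  "WGKKR"
)

.SITE_REGISTRY <- c(
  triad_his    = 57L,
  triad_asp    = 102L,
  triad_ser    = 195L,
  s1_a         = 189L,
  s1_b         = 216L,
  s1_c         = 226L,
  dimer_cys    = 93L,
  bridge_cys_a = 191L,
  bridge_cys_b = 220L
)

#' Reference scaffold for chymotrypsinogen numbering
#'
#' A reference scaffold anchors the canonical coordinate system: every
#' residue carries a strictly increasing canonical position label, and a site
#' registry names the functionally important labels (catalytic triad 57, 102,
#' 195; S1 pocket 189, 216, 226; dimerisation cysteine 93; cysteine bridge
#' 191, 220).  `scaffold_default()` returns the bundled synthetic
#' chymotrypsinogen-like anchor; `reference_scaffold()` builds one from any
#' sequence and label vector (used heavily in tests and simulations).
#'
#' @param residues Amino-acid string (one-letter codes).
#' @param labels Integer vector of canonical labels, one per residue,
#'   strictly increasing.  Defaults to `1:nchar(residues)`.
#' @param site_registry Named integer vector of canonical sites; every value
#'   must occur in `labels`.
#' @return An object of class `protease_scaffold` with elements `residues`,
#'   `labels`, `site_registry`.
#' @examples
#' sc <- scaffold_default()
#' substr(sc$residues, sc$site_registry[["triad_ser"]], sc$site_registry[["triad_ser"]])
#' @export
reference_scaffold <- function(residues, labels = NULL,
                               site_registry = .SITE_REGISTRY) {
  check_aa_string(residues, "residues")
  n <- nchar(residues)
  if (is.null(labels)) labels <- seq_len(n)
  labels <- as.integer(labels)
  if (length(labels) != n)
    abort("`labels` must have one entry per residue.", class = "serprot_input_error")
  if (any(diff(labels) <= 0L))
    abort("`labels` must be strictly increasing.", class = "serprot_input_error")
  site_registry <- vapply(site_registry, as.integer, integer(1))
  missing <- site_registry[!(site_registry %in% labels)]
  if (length(missing))
    abort(sprintf("Registry site(s) %s not present in `labels`.",
                  paste(names(missing), collapse = ", ")),
          class = "serprot_input_error")
  structure(list(residues = residues, labels = labels,
                 site_registry = site_registry),
            class = "protease_scaffold")
}

#' @rdname reference_scaffold
#' @export
scaffold_default <- function() {
  reference_scaffold(.SCAFFOLD_SEQ)
}

#' @export
print.protease_scaffold <- function(x, ...) {
  cat(sprintf("<protease_scaffold> %d residues, labels %d..%d\n",
              nchar(x$residues), x$labels[1], x$labels[length(x$labels)]))
  reg <- x$site_registry
  cat("  registry:", paste(sprintf("%s=%d", names(reg), reg), collapse = " "), "\n")
  invisible(x)
}

#' Alignment parameters for global numbering alignments
#'
#' Scoring used by [align_global()]: a symmetric 20+X substitution matrix and
#' affine gap penalties.  A gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (first gapped residue pays the opening
#' penalty).  The default matrix is BLOSUM62 restricted to the 20 canonical
#' residues plus X, with X rescored to 0 against everything so that unknown
#' residues neither reward nor punish the alignment.
#'
#' @param substitution_matrix Symmetric numeric matrix with the 20 amino
#'   acids (and optionally X) as dimnames.
#' @param gap_open,gap_extend Negative numbers, `gap_open <= gap_extend < 0`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = blosum62x(),
                             gap_open = -11, gap_extend = -1) {
  m <- as.matrix(substitution_matrix)
  if (is.null(dimnames(m)) || !identical(rownames(m), colnames(m)))
    abort("`substitution_matrix` needs identical row/column names.",
          class = "serprot_input_error")
  if (!isTRUE(all.equal(m, t(m))))
    abort("`substitution_matrix` must be symmetric.", class = "serprot_input_error")
  if (!all(AA20 %in% rownames(m)))
    abort("`substitution_matrix` must cover the 20 canonical residues.",
          class = "serprot_input_error")
  if (!(is_scalar_number(gap_open) && is_scalar_number(gap_extend) &&
        gap_open <= gap_extend && gap_extend < 0))
    abort("Require gap_open <= gap_extend < 0.", class = "serprot_input_error")
  structure(list(substitution_matrix = m,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "alignment_params")
}

#' BLOSUM62 over the 20 residues plus X
#'
#' BLOSUM62 (from Biostrings) restricted to the 20 canonical amino acids and
#' X, with the X row/column set to 0.
#'
#' @return A 21 x 21 symmetric integer matrix.
#' @export
blosum62x <- function() {
  b <- get_blosum62()
  keep <- c(AA20, "X")
  m <- b[keep, keep]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
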