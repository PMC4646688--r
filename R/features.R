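# S1-pocket triplet, catalytic-triad and cysteine-feature extraction.
#
# The three S1-pocket residues at canonical positions 189, 216 and 226 line
# the pocket that accepts the substrate's P1 side chain and are the main
# determinants of primary cleavage specificity; 189 sits at the bottom of the
# pocket and dominates.  The His57/Asp102/Ser195 triad performs catalysis, so
# a broken triad marks a proteolytically inactive family member (azurocidin
# style).  An unpaired cysteine at 93 drives granzyme A-style dimerisation;
# cysteines at both 191 and 220 mark the extra disulfide bridge seen in fish
# proteases.

#' Extract the S1-pocket specificity triplet
#'
#' Concatenates the residues at canonical labels 189, 216 and 226 (in that
#' order), writing `-` for labels lost to deletions.
#'
#' @param numbered A `numbered_protease` from [assign_numbering()].
#' @return A 3-character string over residues and `-`.
#' @export
extract_triplet <- function(numbered) {
  reg <- numbered$site_registry
  r <- vapply(c(reg[["s1_a"]], reg[["s1_b"]], reg[["s1_c"]]),
              function(l) residue_at(numbered, l), character(1))
  r[is.na(r)] <- "-"
  paste(r, collapse = "")
}

#' Check the catalytic triad
#'
#' The triad is intact exactly when labels 57, 102 and 195 map to H, D and S
#' respectively; no conservative substitutions are accepted (triad loss is
#' treated as inactivity, a binary call).
#'
#' @inheritParams extract_triplet
#' @return List with `triad_intact` (logical) and `triad_residues`
#'   (3-character string over residues and `-`).
#' @export
check_triad <- function(numbered) {
  reg <- numbered$site_registry
  r <- vapply(c(reg[["triad_his"]], reg[["triad_asp"]], reg[["triad_ser"]]),
              function(l) residue_at(numbered, l), character(1))
  intact <- !anyNA(r) && identical(unname(r), c("H", "D", "S"))
  r[is.na(r)] <- "-"
  list(triad_intact = intact, triad_residues = paste(r, collapse = ""))
}

#' Cysteine features: dimerisation site and 191-220 bridge
#'
#' `oligomer_call` is a sequence-level heuristic: `dimer` when label 93
#' carries a cysteine (granzyme A pattern), `monomer` when 93 is mapped to a
#' non-cysteine (granzyme K pattern), `indeterminate` when the label is lost
#' to a gap.  The bridge flag only records that both cysteines are present;
#' it is not a structural disulfide assignment.
#'
#' @inheritParams extract_triplet
#' @return List with `has_cys93`, `has_bridge_191_220`, `oligomer_call`.
#' @export
cysteine_features <- function(numbered) {
  reg <- numbered$site_registry
  c93 <- residue_at(numbered, reg[["dimer_cys"]])
  c191 <- residue_at(numbered, reg[["bridge_cys_a"]])
  c220 <- residue_at(numbered, reg[["bridge_cys_b"]])
  has93 <- isTRUE(c93 == "C")
  call <- if (is.na(c93)) "indeterminate" else if (has93) "dimer" else "monomer"
  list(has_cys93 = has93,
       has_bridge_191_220 = isTRUE(c191 == "C") && isTRUE(c220 == "C"),
       oligomer_call = call)
}

#' Full specificity profile of a numbered sequence
#'
#' @inheritParams extract_triplet
#' @return Object of class `specificity_profile`: `triplet`, `triad_intact`,
#'   `triad_residues`, `has_cys93`, `has_bridge_191_220`, `oligomer_call`.
#' @export
specificity_profile <- function(numbered) {
  tri <- check_triad(numbered)
  cys <- cysteine_features(numbered)
  structure(c(list(triplet = extract_triplet(numbered)), tri, cys),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat(sprintf("<specificity_profile> triplet %s, triad %s (%s), cys93 %s, bridge %s, %s\n",
              x$triplet, if (x$triad_intact) "intact" else "broken",
              x$triad_residues, x$has_cys93, x$has_bridge_191_220,
              x$oligomer_call))
  invisible(x)
}

#' Profile a set of sequences
#'
#' Numbers every sequence against the scaffold and extracts its specificity
#' profile.
#'
#' @inheritParams number_sequences
#' @return A tibble with one row per sequence: `seq_id`, `triplet`,
#'   `triad_intact`, `triad_residues`, `has_cys93`, `has_bridge_191_220`,
#'   `oligomer_call`.
#' @examples
#' sc <- scaffold_default()
#' profile_sequences(c(anchor = sc$residues))
#' @export
profile_sequences <- function(sequences, reference = scaffold_default(),
                              params = alignment_params()) {
  seqs <- as_aa_set(sequences)
  purrr::imap(seqs, function(s, id) {
    p <- specificity_profile(assign_numbering(align_global(s, reference, params)))
    tibble(seq_id = id, triplet = p$triplet, triad_intact = p$triad_intact,
           triad_residues = p$triad_residues, has_cys93 = p$has_cys93,
           has_bridge_191_220 = p$has_bridge_191_220,
           oligomer_call = p$oligomer_call)
  }) %>% bind_rows()
}

#' Write a profile table as TSV
#'
#' @param profile_table Output of [profile_sequences()].
#' @param path Output file.
#' @export
write_profiles_tsv <- function(profile_table, path) {
  readr::write_tsv(profile_table, path)
  invisible(path)
}
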