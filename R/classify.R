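# Rule-based primary cleavage-specificity prediction from the S1 triplet.
#
# Lookup order: a broken catalytic triad overrides everything (the protein is
# not an enzyme, so its triplet carries no specificity information); then the
# literal triplet table; then a fallback keyed on position 189 alone, which
# dominates specificity (226 is secondary -- it can be shielded by
# neighbouring residues -- and 216 is least informative); anything else is
# unassigned.  Duodenases (dual tryptic/chymotryptic activity) carry no
# triplet rule: their S1 triplets do not separate them, so no rule is
# shipped for them.

#' Load the specificity rule table
#'
#' The packaged default encodes the literal triplet-to-specificity rules
#' (tryptase DGG/DGA/GSD, chymase SGA and the putative SGG/SGN, asp-ase
#' SGR/TGR/AGR and putative SGK, cathepsin G-like SGE/AGE, met-ase ASP/AST,
#' elastase GVD/GID/NVA/NVS and putative SVN, plus NGE and seven
#' fish-specific triplets shipped as unassigned) and the position-189
#' fallbacks (D -> tryptase, S -> chymase, both putative).  Users may point
#' `path` at an edited copy to extend the table.
#'
#' @param path Optional path to a TSV with columns `pattern`, `type`
#'   (`triplet` or `pos189`), `label`, `tier`, `note`.
#' @return A tibble of rules.
#' @export
specificity_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "specificity_rules.tsv", package = "serprot")
  rules <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c("pattern", "type", "label", "tier")
  if (!all(need %in% names(rules)))
    abort("Rule table must have columns pattern, type, label, tier.",
          class = "serprot_input_error")
  bad <- rules$type == "triplet" & nchar(rules$pattern) != 3L
  if (any(bad))
    abort("Literal rules must be 3-character triplets.", class = "serprot_input_error")
  rules
}

check_triplet_string <- function(triplet) {
  if (!is.character(triplet) || length(triplet) != 1L || is.na(triplet) ||
      nchar(triplet) != 3L)
    abort("`triplet` must be a single 3-character string.",
          class = "serprot_input_error")
  chars <- strsplit(triplet, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% c(AA20, "X", "-")))
  if (length(bad))
    abort(sprintf("Illegal triplet character '%s' at position %d.",
                  chars[bad[1]], bad[1]), class = "serprot_input_error")
  invisible(triplet)
}

#' Classify an S1 triplet
#'
#' Deterministic lookup mapping a specificity triplet (residues at canonical
#' positions 189, 216, 226) and the catalytic-triad status to a predicted
#' primary cleavage specificity with a confidence tier.  A broken triad
#' yields tier `inactive` regardless of the triplet; an incomplete triplet
#' (containing `-`) or one matched by no rule yields tier `unassigned` with
#' label `unknown`.
#'
#' @param triplet 3-character string over the 20 residues and `-` (an `X`
#'   is tolerated; it matches no rule).
#' @param triad_intact Logical; is His57/Asp102/Ser195 intact?
#' @param rules Rule table from [specificity_rules()].
#' @return One-row tibble: `triplet`, `label`, `tier`, `matched_rule`.
#' @examples
#' classify_triplet("DGG", TRUE)$label   # tryptase
#' classify_triplet("SGA", TRUE)$label   # chymase
#' classify_triplet("DGG", FALSE)$tier   # inactive
#' @export
classify_triplet <- function(triplet, triad_intact = TRUE,
                             rules = specificity_rules()) {
  check_triplet_string(triplet)
  if (!isTRUE(triad_intact) && !isFALSE(triad_intact))
    abort("`triad_intact` must be TRUE or FALSE.", class = "serprot_input_error")
  if (!triad_intact)
    return(tibble(triplet = triplet, label = "unknown", tier = "inactive",
                  matched_rule = "triad_broken"))
  if (grepl("-", triplet, fixed = TRUE))
    return(tibble(triplet = triplet, label = "unknown", tier = "unassigned",
                  matched_rule = NA_character_))
  lit <- rules[rules$type == "triplet" & rules$pattern == triplet, ]
  if (nrow(lit) >= 1L)
    return(tibble(triplet = triplet, label = lit$label[1], tier = lit$tier[1],
                  matched_rule = lit$pattern[1]))
  p189 <- substr(triplet, 1L, 1L)
  fb <- rules[rules$type == "pos189" & rules$pattern == p189, ]
  if (nrow(fb) >= 1L)
    return(tibble(triplet = triplet, label = fb$label[1], tier = fb$tier[1],
                  matched_rule = paste0("pos189_", p189)))
  tibble(triplet = triplet, label = "unknown", tier = "unassigned",
         matched_rule = NA_character_)
}

#' Classify a batch of specificity profiles
#'
#' One classification per row of a profile table, order preserved; a summary
#' count per predicted label is reported as a message.
#'
#' @param profiles Tibble from [profile_sequences()] (needs columns `triplet`
#'   and `triad_intact`; `seq_id` carried through if present).
#' @param rules Rule table from [specificity_rules()].
#' @param quiet Suppress the summary message.
#' @return Tibble: `seq_id` (if present), `triplet`, `label`, `tier`,
#'   `matched_rule`.
#' @export
classify_profiles <- function(profiles, rules = specificity_rules(),
                              quiet = FALSE) {
  profiles <- as_tibble(profiles)
  if (nrow(profiles) == 0L)
    return(tibble(seq_id = character(), triplet = character(),
                  label = character(), tier = character(),
                  matched_rule = character()))
  if (!all(c("triplet", "triad_intact") %in% names(profiles)))
    abort("`profiles` needs columns triplet and triad_intact.",
          class = "serprot_input_error")
  out <- purrr::map2(profiles$triplet, profiles$triad_intact,
                     classify_triplet, rules = rules) %>% bind_rows()
  if ("seq_id" %in% names(profiles))
    out <- dplyr::bind_cols(tibble(seq_id = profiles$seq_id), out)
  if (!quiet) {
    counts <- table(out$label)
    inform(paste0("classified ", nrow(out), " profiles: ",
                  paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                        collapse = ", ")))
  }
  out
}

#' Write classifications as TSV
#'
#' @param classification_table Output of [classify_profiles()].
#' @param path Output file.
#' @export
write_classification_tsv <- function(classification_table, path) {
  readr::write_tsv(classification_table, path)
  invisible(path)
}
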