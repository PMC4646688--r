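# Synthetic-data generator.  Emulates the two kinds of input the annotation
# pipeline consumes: (i) protease families evolving along a tree from a
# scaffold-derived root with planted canonical sites, under a uniform
# 20-state (Jukes-Cantor-like) substitution model with registry sites frozen
# by default; (ii) chromosome annotations in which protease genes sit
# between bordering marker genes, with duplications, losses, inversions and
# contig splits.  Every run is driven by one master seed through named
# substreams, and every emitted artifact is accompanied by an event log that
# replays exactly.

#' Simulation configuration
#'
#' @param tree Optional ape `phylo` with branch lengths; when `NULL` a
#'   random topology with `n_leaves` leaves is drawn (uniform branch lengths
#'   on `[0.05, 0.5]` substitutions-per-site units).
#' @param n_leaves Leaf count when sampling a tree.
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length (uniform 20-state model).
#' @param frozen_sites Canonical labels never mutated; default the full site
#'   registry (triad, S1 triplet, cysteine sites).
#' @param indel_rate Indel events per site per unit branch length.  Indels
#'   are never placed within 3 residues of a frozen site, so planted-site
#'   recovery stays exact.
#' @param event_rates Named numeric: expected `duplication`, `loss`,
#'   `inversion` events per locus lineage.
#' @param seed Master seed; named substreams are derived from it, so adding
#'   draws in one stream never perturbs another.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(tree = NULL, n_leaves = 6,
                              substitution_rate = 0.05,
                              frozen_sites = NULL,
                              indel_rate = 0,
                              event_rates = c(duplication = 0, loss = 0,
                                              inversion = 0),
                              seed = 1) {
  if (!is.null(tree)) stopifnot(inherits(tree, "phylo"))
  if (is.null(frozen_sites))
    frozen_sites <- unname(.SITE_REGISTRY)
  stopifnot(substitution_rate >= 0, indel_rate >= 0, all(event_rates >= 0))
  er <- c(duplication = 0, loss = 0, inversion = 0)
  er[names(event_rates)] <- event_rates
  structure(list(tree = tree, n_leaves = as.integer(n_leaves),
                 substitution_rate = substitution_rate,
                 frozen_sites = as.integer(frozen_sites),
                 indel_rate = indel_rate, event_rates = er,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node] else paste0("node", node)
}

# root sequence: scaffold with a chosen S1 triplet / triad / cysteine layout
plant_root <- function(reference, triplet = "SGG", triad_intact = TRUE,
                       cys93 = FALSE, bridge = TRUE) {
  check_triplet_string(triplet)
  if (grepl("-", triplet, fixed = TRUE))
    abort("Cannot plant an incomplete triplet.", class = "serprot_input_error")
  s <- strsplit(reference$residues, "", fixed = TRUE)[[1]]
  reg <- reference$site_registry
  at <- function(lab) match(lab, reference$labels)
  tri <- strsplit(triplet, "", fixed = TRUE)[[1]]
  s[at(reg[["s1_a"]])] <- tri[1]
  s[at(reg[["s1_b"]])] <- tri[2]
  s[at(reg[["s1_c"]])] <- tri[3]
  s[at(reg[["triad_his"]])] <- "H"
  s[at(reg[["triad_asp"]])] <- "D"
  s[at(reg[["triad_ser"]])] <- if (triad_intact) "S" else "A"
  s[at(reg[["dimer_cys"]])] <- if (cys93) "C" else "N"
  s[at(reg[["bridge_cys_a"]])] <- if (bridge) "C" else "S"
  s[at(reg[["bridge_cys_b"]])] <- if (bridge) "C" else "T"
  paste(s, collapse = "")
}

#' Simulate an evolving protease family
#'
#' Draws (or takes) a tree, plants a root sequence on the reference scaffold
#' with the requested S1 triplet / triad / cysteine layout, and evolves it
#' along the tree: per branch, per non-frozen site, a Poisson number of
#' substitutions (rate x branch length), each replacing the residue with one
#' of the other 19 uniformly.  Optional indels are placed away from frozen
#' sites.  The event log replays to exactly the emitted sequences.
#'
#' @param config A [simulation_config()].
#' @param reference A [reference_scaffold()].
#' @param planted_triplet S1 triplet planted at the root (kept in all
#'   descendants when the registry is frozen).
#' @param triad_intact,cys93,bridge Root layout of the canonical sites.
#' @return Object of class `simulated_family`: `root_sequence`,
#'   `sequences` (named, one per leaf), `tree`, `events` (tibble:
#'   `branch`, `type`, `position`, `length`, `from`, `to`),
#'   `label_tracks` (per-leaf canonical label of every residue), `config`.
#' @export
simulate_family <- function(config, reference = scaffold_default(),
                            planted_triplet = "SGG", triad_intact = TRUE,
                            cys93 = FALSE, bridge = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- config$tree
  if (is.null(tree)) {
    tree <- withr::with_seed(derive_seed(config$seed, "tree"), {
      t <- ape::rtree(config$n_leaves, br = NULL)
      t$edge.length <- stats::runif(nrow(t$edge), 0.05, 0.5)
      t
    })
  }
  root_seq <- plant_root(reference, planted_triplet, triad_intact, cys93, bridge)
  root_chars <- strsplit(root_seq, "", fixed = TRUE)[[1]]
  root_labels <- reference$labels
  frozen <- config$frozen_sites
  ntip <- length(tree$tip.label)
  rootn <- ntip + 1L

  seqs <- vector("list", ntip + tree$Nnode)
  labs <- vector("list", ntip + tree$Nnode)
  seqs[[rootn]] <- root_chars
  labs[[rootn]] <- root_labels
  events <- list()

  withr::with_seed(derive_seed(config$seed, "sequences"), {
    # preorder over edges (cladewise edge order is already parent-first)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      t_len <- tree$edge.length[e]
      s <- seqs[[par]]; l <- labs[[par]]
      bname <- node_name(tree, chl)

      # substitutions
      mutable <- which(!(l %in% frozen))
      k <- stats::rpois(length(mutable), config$substitution_rate * t_len)
      for (idx in mutable[k > 0]) {
        for (rep_i in seq_len(k[match(idx, mutable)])) {
          old <- s[idx]
          new <- sample(setdiff(AA20, old), 1L)
          events[[length(events) + 1L]] <-
            list(branch = bname, type = "substitution", position = idx,
                 length = 1L, from = old, to = new)
          s[idx] <- new
        }
      }

      # indels (never within 3 residues of a frozen site)
      if (config$indel_rate > 0) {
        n_ind <- stats::rpois(1L, config$indel_rate * t_len * length(s))
        for (ii in seq_len(n_ind)) {
          fpos <- which(l %in% frozen)
          zone <- unique(unlist(lapply(fpos, function(p)
            max(1L, p - 3L):min(length(s), p + 3L))))
          ilen <- 1L + stats::rpois(1L, 1)
          is_del <- stats::runif(1) < 0.5
          ok <- NULL
          for (try_i in 1:20) {
            p <- sample.int(length(s) - (if (is_del) ilen else 0L), 1L)
            span <- if (is_del) p:(p + ilen - 1L) else p
            if (!any(span %in% zone)) { ok <- p; break }
          }
          if (is.null(ok)) next
          if (is_del) {
            events[[length(events) + 1L]] <-
              list(branch = bname, type = "deletion", position = ok,
                   length = ilen,
                   from = paste(s[ok:(ok + ilen - 1L)], collapse = ""), to = "")
            keep <- setdiff(seq_along(s), ok:(ok + ilen - 1L))
            s <- s[keep]; l <- l[keep]
          } else {
            ins <- sample(AA20, ilen, replace = TRUE)
            events[[length(events) + 1L]] <-
              list(branch = bname, type = "insertion", position = ok,
                   length = ilen, from = "", to = paste(ins, collapse = ""))
            s <- append(s, ins, after = ok)
            l <- append(l, rep(NA_integer_, ilen), after = ok)
          }
        }
      }
      seqs[[chl]] <- s
      labs[[chl]] <- l
    }
  })

  leaves <- setNames(
    vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), character(1)),
    tree$tip.label)
  structure(list(root_sequence = root_seq,
                 sequences = leaves,
                 tree = tree,
                 events = bind_rows(lapply(events, as_tibble)),
                 label_tracks = setNames(labs[seq_len(ntip)], tree$tip.label),
                 planted_triplet = planted_triplet,
                 config = config),
            class = "simulated_family")
}

#' Replay a family's event log
#'
#' Applies the recorded events to the root sequence along the tree and
#' returns the reconstructed leaf sequences; by construction these must
#' equal the emitted ones exactly (a correctness check on the generator).
#'
#' @param family A `simulated_family`.
#' @return Named character vector of leaf sequences.
#' @export
replay_family <- function(family) {
  tree <- family$tree
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- strsplit(family$root_sequence, "", fixed = TRUE)[[1]]
  ev <- family$events
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    s <- seqs[[par]]
    bname <- node_name(tree, chl)
    if (nrow(ev)) {
      bev <- ev[ev$branch == bname, ]
      for (i in seq_len(nrow(bev))) {
        p <- bev$position[i]; ln <- bev$length[i]
        switch(bev$type[i],
          substitution = { s[p] <- bev$to[i] },
          deletion = { s <- s[setdiff(seq_along(s), p:(p + ln - 1L))] },
          insertion = {
            s <- append(s, strsplit(bev$to[i], "", fixed = TRUE)[[1]], after = p)
          })
      }
    }
    seqs[[chl]] <- s
  }
  setNames(vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1)), tree$tip.label)
}

#' Expected sequence identity under the uniform 20-state model
#'
#' Closed form for the probability that a site is identical after total
#' path length `t` at rate `r`: `1/20 + 19/20 * exp(-20/19 * r * t)`.
#' Used to check simulated divergences against theory.
#'
#' @param rate Substitution rate per site per unit length.
#' @param t Total path length separating the two sequences.
#' @return Expected per-site identity probability.
#' @export
expected_identity <- function(rate, t) {
  1 / 20 + 19 / 20 * exp(-20 / 19 * rate * t)
}

#' Simulate a protease locus annotation
#'
#' Lays out a contig carrying the definition's left markers, `n_proteases`
#' protease genes and the right markers, then applies duplication / loss /
#' inversion (and optional split) events.  Counts are Poisson with the
#' configured rates unless `forced_events` prescribes the exact events.
#'
#' @param config A [simulation_config()] (uses `event_rates` and `seed`).
#' @param definition A [locus_definition()].
#' @param n_proteases Number of protease genes in the seed locus.
#' @param contig Contig name.
#' @param forced_events Optional list of events applied instead of random
#'   ones; each a list with `type` (`duplication`, `loss`, `inversion`,
#'   `split`) and `target` (gene id; for `split`, the gene after which the
#'   contig breaks).  `inversion` flips the target gene's strand.
#' @return List of class `simulated_locus`: `genes` (gene-record tibble),
#'   `events` (tibble), `definition`.
#' @export
simulate_locus <- function(config, definition, n_proteases = 4,
                           contig = "sim_contig_1", forced_events = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(definition, "locus_definition"))
  withr::with_seed(derive_seed(config$seed, "locus"), {
    mk <- function(ids, category) tibble(gene_id = ids, category = category)
    layout <- bind_rows(
      mk(definition$left_markers, "marker"),
      mk(sprintf("PROT%d", seq_len(n_proteases)), "protease"),
      mk(definition$right_markers, "marker"))
    n <- nrow(layout)
    sizes <- ifelse(layout$category == "marker",
                    sample(5000:40000, n, replace = TRUE),
                    sample(2000:6000, n, replace = TRUE))
    gaps <- sample(1000:50000, n, replace = TRUE)
    start <- cumsum(c(10000L, (sizes + gaps)[-n]))
    genes <- tibble(gene_id = layout$gene_id, contig = contig,
                    start = as.integer(start),
                    end = as.integer(start + sizes),
                    strand = ifelse(layout$category == "marker", "+",
                                    sample(c("+", "-"), n, replace = TRUE)),
                    category = layout$category,
                    pseudogene = FALSE)

    events <- list()
    apply_event <- function(genes, type, target) {
      i <- match(tolower(target), tolower(genes$gene_id))
      if (is.na(i)) return(genes)
      if (type == "duplication") {
        copy <- genes[i, ]
        size <- copy$end - copy$start
        gap <- 2000L
        copy$gene_id <- paste0(copy$gene_id, "_dup")
        copy$start <- genes$end[i] + gap
        copy$end <- copy$start + size
        shift <- size + 2L * gap
        later <- genes$start > genes$start[i] & genes$contig == genes$contig[i]
        genes$start[later] <- genes$start[later] + shift
        genes$end[later] <- genes$end[later] + shift
        genes <- bind_rows(genes, copy)
      } else if (type == "loss") {
        genes <- genes[-i, ]
      } else if (type == "inversion") {
        genes$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
      } else if (type == "split") {
        second <- genes$start > genes$start[i]
        off <- min(genes$start[second]) - 10000L
        genes$contig[second] <- paste0(contig, "_part2")
        genes$start[second] <- genes$start[second] - off
        genes$end[second] <- genes$end[second] - off
      }
      events[[length(events) + 1L]] <<- list(type = type, target = target)
      genes
    }

    if (is.null(forced_events)) {
      er <- config$event_rates
      prot_ids <- function() genes$gene_id[genes$category == "protease"]
      for (k in seq_len(stats::rpois(1L, er[["duplication"]]))) {
        ids <- prot_ids(); if (!length(ids)) break
        genes <- apply_event(genes, "duplication", sample(ids, 1L))
      }
      for (k in seq_len(stats::rpois(1L, er[["loss"]]))) {
        ids <- prot_ids(); if (!length(ids)) break
        genes <- apply_event(genes, "loss", sample(ids, 1L))
      }
      mk_ids <- genes$gene_id[genes$category == "marker"]
      for (k in seq_len(stats::rpois(1L, er[["inversion"]]))) {
        pool <- c(mk_ids, prot_ids())
        genes <- apply_event(genes, "inversion", sample(pool, 1L))
      }
    } else {
      for (ev in forced_events)
        genes <- apply_event(genes, ev$type, ev$target)
    }
    genes <- dplyr::arrange(genes, .data$contig, .data$start)
    structure(list(genes = genes,
                   events = if (length(events)) bind_rows(lapply(events, as_tibble))
                            else tibble(type = character(), target = character()),
                   definition = definition),
              class = "simulated_locus")
  })
}

#' Generate the packaged fixture suite
#'
#' Writes a deterministic set of small fixtures: one FASTA sequence per
#' literal classifier rule (plus a broken-triad sequence), a simulated
#' 6-taxon family (FASTA + true tree in Newick), a chymase-style locus GFF3
#' with a forced marker inversion, a split locus GFF3, and a JSON manifest
#' recording every planted truth.  Regenerating with the same seed gives
#' byte-identical files.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the truth manifest.
#' @export
make_fixture_suite <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- scaffold_default()
  rules <- specificity_rules()
  lit <- rules[rules$type == "triplet", ]

  # one planted sequence per literal rule + one broken-triad sequence
  seqs <- setNames(
    vapply(lit$pattern, function(tr) plant_root(reference, tr), character(1)),
    paste0("rule_", lit$pattern))
  seqs <- c(seqs, inactive_DGG = plant_root(reference, "DGG", triad_intact = FALSE))
  fasta_rules <- file.path(dir, "classifier_rules.fasta")
  write_fasta(seqs, fasta_rules)

  # 6-taxon family on a fixed tree with a long internal branch
  tree <- read_newick(
    "((A:0.1,B:0.1):0.6,(C:0.1,D:0.1):0.6,(E:0.1,F:0.1):0.6);")
  cfg <- simulation_config(tree = tree, substitution_rate = 0.3,
                           seed = derive_seed(seed, "fixture_family"))
  fam <- simulate_family(cfg, reference, planted_triplet = "DGG")
  fasta_family <- file.path(dir, "family.fasta")
  write_fasta(fam$sequences, fasta_family)
  nwk_family <- file.path(dir, "family_true.nwk")
  write_newick(tree, nwk_family)

  # chymase-style locus with a forced STXBP6 inversion; and a split locus
  defs <- locus_definitions()
  cfg_l <- simulation_config(seed = derive_seed(seed, "fixture_locus"))
  loc <- simulate_locus(cfg_l, defs$chymase, n_proteases = 3,
                        forced_events = list(list(type = "inversion",
                                                  target = "STXBP6")))
  gff_locus <- file.path(dir, "locus.gff3")
  write_gff3(loc$genes, gff_locus)
  cfg_s <- simulation_config(seed = derive_seed(seed, "fixture_split"))
  spl <- simulate_locus(cfg_s, defs$chymase, n_proteases = 3,
                        forced_events = list(list(type = "split",
                                                  target = "PROT1")))
  gff_split <- file.path(dir, "split_locus.gff3")
  write_gff3(spl$genes, gff_split)

  manifest <- list(
    seed = seed,
    classifier_rules = setNames(as.list(lit$label), paste0("rule_", lit$pattern)),
    inactive_sequence = "inactive_DGG",
    family = list(planted_triplet = "DGG",
                  true_tree = write_newick(tree),
                  taxa = tree$tip.label),
    locus = list(definition = "chymase",
                 protease_genes = loc$genes$gene_id[loc$genes$category == "protease"],
                 inverted_markers = "STXBP6"),
    split_locus = list(definition = "chymase",
                       contigs = unique(spl$genes$contig)))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(paths = list(classifier_rules = fasta_rules,
                              family = fasta_family,
                              family_tree = nwk_family,
                              locus = gff_locus,
                              split_locus = gff_split,
                              manifest = manifest_path),
                 manifest = manifest,
                 family = fam, locus = loc, split_locus = spl))
}
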