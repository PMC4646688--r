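# synthetic-data generator

test_that("zero substitution rate leaves every leaf identical to the root", {
  cfg <- simulation_config(n_leaves = 4, substitution_rate = 0, seed = 1)
  fam <- simulate_family(cfg)
  expect_true(all(fam$sequences == fam$root_sequence))
  expect_equal(nrow(fam$events), 0L)
})

test_that("the same seed reproduces the family exactly", {
  cfg <- simulation_config(n_leaves = 5, substitution_rate = 0.2, seed = 99)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(f1$events, f2$events)
  f3 <- simulate_family(simulation_config(n_leaves = 5,
                                          substitution_rate = 0.2, seed = 100))
  expect_false(identical(f1$sequences, f3$sequences))
})

test_that("registry sites never mutate when frozen", {
  cfg <- simulation_config(n_leaves = 6, substitution_rate = 1.0, seed = 17)
  fam <- simulate_family(cfg, planted_triplet = "GVD", cys93 = TRUE)
  reg <- scaffold_default()$site_registry
  expect_false(any(fam$events$position %in% unname(reg) &
                     fam$events$type == "substitution"))
  for (s in fam$sequences) {
    chars <- strsplit(s, "")[[1]]
    expect_identical(paste(chars[c(189, 216, 226)], collapse = ""), "GVD")
    expect_identical(chars[57], "H")
    expect_identical(chars[93], "C")
  }
})

test_that("observed divergence matches the 20-state closed form within 3 SE", {
  tree <- read_newick("(A:5,B:5);")   # total path length 10
  rate <- 0.1
  # 1000 sites: evolve a long random root by disabling freezing on a long
  # scaffold built for this test
  sc <- withr::with_seed(2, reference_scaffold(random_aa(1000)))
  cfg <- simulation_config(tree = tree, substitution_rate = rate,
                           frozen_sites = integer(), seed = 123)
  fam <- simulate_family(cfg, reference = sc, planted_triplet = "DGG")
  p_obs <- protein_distance(fam$sequences[["A"]], fam$sequences[["B"]],
                            "p-distance")
  p_exp <- 1 - expected_identity(rate, 10)
  se <- sqrt(p_exp * (1 - p_exp) / 1000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("the event log replays to the emitted sequences exactly", {
  cfg <- simulation_config(n_leaves = 6, substitution_rate = 0.5,
                           indel_rate = 0.002, seed = 71)
  fam <- simulate_family(cfg)
  expect_identical(replay_family(fam), fam$sequences)
  expect_true(any(fam$events$type %in% c("insertion", "deletion")))
})

test_that("indels never come within 3 residues of a frozen site", {
  cfg <- simulation_config(n_leaves = 8, substitution_rate = 0.3,
                           indel_rate = 0.004, seed = 29)
  fam <- simulate_family(cfg, planted_triplet = "ASP")
  # every leaf still shows the planted profile after indels
  tab <- profile_sequences(fam$sequences)
  expect_true(all(tab$triplet == "ASP"))
  expect_true(all(tab$triad_intact))
})

test_that("all event rates zero yields exactly the seed locus", {
  defs <- locus_definitions()
  cfg <- simulation_config(seed = 3)
  loc <- simulate_locus(cfg, defs$chymase, n_proteases = 4)
  expect_equal(nrow(loc$genes), 4L + 5L)     # 4 proteases + 5 markers
  expect_equal(nrow(loc$events), 0L)
  expect_true(all(diff(loc$genes$start) > 0))
  expect_true(all(loc$genes$start >= 0))
})

test_that("a forced inversion is detected downstream", {
  defs <- locus_definitions()
  cfg <- simulation_config(seed = 3)
  loc <- simulate_locus(cfg, defs$chymase, n_proteases = 4,
                        forced_events = list(list(type = "inversion",
                                                  target = "CBLN3")))
  cand <- identify_locus(loc$genes, defs$chymase)
  ref <- c(RIPK3 = "+", NYNRIN = "+", CBLN3 = "+", SDR39U1 = "+", STXBP6 = "+")
  flags <- detect_inversion(cand[[1]], ref)
  expect_identical(flags$marker[flags$inverted], "CBLN3")
})

test_that("high duplication rates increase the mean gene count", {
  defs <- locus_definitions()
  n_genes <- function(rate, seed) {
    cfg <- simulation_config(event_rates = c(duplication = rate), seed = seed)
    nrow(simulate_locus(cfg, defs$chymase, n_proteases = 3)$genes)
  }
  base <- vapply(1:40, function(s) n_genes(0, s), numeric(1))
  dup <- vapply(1:40, function(s) n_genes(3, s), numeric(1))
  expect_gt(mean(dup), mean(base))
  expect_true(all(base == 8))
})

test_that("the fixture suite covers every rule and regenerates identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_fixture_suite(seed = 5, dir = d1)
  fx2 <- make_fixture_suite(seed = 5, dir = d2)
  for (nm in names(fx1$paths)) {
    expect_identical(readLines(fx1$paths[[nm]]), readLines(fx2$paths[[nm]]),
                     label = nm)
  }
  rules <- specificity_rules()
  lit <- rules[rules$type == "triplet", ]
  seqs <- read_fasta(fx1$paths$classifier_rules)
  expect_gte(length(seqs), nrow(lit) + 1L)    # >= 20 exact rules + extras
  expect_true(all(paste0("rule_", lit$pattern) %in% names(seqs)))
  # triad-broken fixture classifies inactive end-to-end
  prof <- profile_sequences(seqs["inactive_DGG"])
  cls <- classify_profiles(prof, quiet = TRUE)
  expect_identical(cls$tier, "inactive")
})

test_that("fixture classifier sequences recover their planted rules end-to-end", {
  fx <- make_fixture_suite(seed = 11, dir = withr::local_tempdir())
  seqs <- read_fasta(fx$paths$classifier_rules)
  planted <- sub("rule_", "", names(seqs))
  keep <- names(seqs) != "inactive_DGG"
  prof <- profile_sequences(seqs[keep])
  expect_identical(prof$triplet, planted[keep])
  cls <- classify_profiles(prof, quiet = TRUE)
  expect_identical(cls$label,
                   unname(unlist(fx$manifest$classifier_rules[names(seqs)[keep]])))
})

test_that("NJ recovers the true topology of simulated families", {
  # long internal branches relative to terminal ones
  tree <- read_newick("((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.5,(E:0.1,F:0.1):0.5);")
  truth <- serprot:::bipartitions(tree)
  hits <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(tree = tree, substitution_rate = 0.3, seed = s)
    fam <- simulate_family(cfg)
    nj <- neighbor_joining(distance_matrix(fam$sequences, "poisson"))
    if (setequal(serprot:::bipartitions(nj), truth)) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})
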