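# distances, neighbor joining, bootstrap, consensus, newick

test_that("protein distances follow the closed forms", {
  expect_equal(protein_distance("ACDE", "ACDE", "p-distance"), 0)
  expect_equal(protein_distance("ACDE", "ACDE", "poisson"), 0)
  expect_equal(protein_distance("AAAAAAAAAA", "AAAWWWAAAA", "p-distance"), 0.3)
  # p = 0.5 -> poisson -ln(0.5)
  expect_equal(protein_distance("AAAA", "AAWW", "poisson"), -log(0.5))
  # gaps and X excluded from comparable columns
  expect_equal(protein_distance("AC-XE", "ACD-E", "p-distance"), 0)
  expect_error(protein_distance("--", "AA", "poisson"),
               class = "serprot_undefined_distance")
  expect_warning(d <- protein_distance("AAAAAAAAAAAAAAAAAAAA",
                                       "WWWWWWWWWWWWWWWWWWWW", "poisson"),
                 "cap")
  expect_equal(d, -log(0.05))
})

test_that("three-taxon NJ solves the three-point formulas", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(m)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(neighbor_joining(m[1:2, 1:2]), class = "serprot_input_error")
})

test_that("NJ on a 4-taxon additive matrix beats the other two topologies", {
  withr::with_seed(5, {
    for (trial in 1:10) {
      true <- ape::rtree(4, br = NULL)
      true$edge.length <- stats::runif(nrow(true$edge), 0.3, 1.5)
      d <- as.matrix(stats::cophenetic(true))
      d <- d[order(rownames(d)), order(colnames(d))]
      nj <- neighbor_joining(d)
      # exhaustive: all 3 unrooted 4-taxon topologies, least-squares fit
      tops <- enum_topologies(4)
      sse <- vapply(tops, ls_sse, numeric(1), d = d)
      best <- tops[[which.min(sse)]]
      expect_lt(min(sse), 1e-12)
      expect_identical(serprot:::bipartitions(nj),
                       topo_bipartitions(best, rownames(d)))
    }
  })
})

test_that("NJ agrees with an independent implementation on random matrices", {
  withr::with_seed(23, {
    for (trial in 1:10) {
      n <- sample(4:9, 1)
      tr <- ape::rtree(n, br = NULL)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
      d <- as.matrix(stats::cophenetic(tr))
      mine <- neighbor_joining(d)
      theirs <- ape::nj(d)
      expect_setequal(serprot:::bipartitions(mine),
                      phylo_bipartitions_ape(theirs))
      # additive input: path lengths reproduce the matrix
      coph <- as.matrix(stats::cophenetic(mine))[rownames(d), colnames(d)]
      expect_equal(coph, d, tolerance = 1e-8)
    }
  })
})

test_that("an all-equal matrix joins the lowest-index pair deterministically", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  t1 <- suppressWarnings(neighbor_joining(m))
  t2 <- suppressWarnings(neighbor_joining(m))
  expect_identical(write_newick(t1), write_newick(t2))
  # a and b (the first pair) end up as sisters
  expect_identical(serprot:::bipartitions(t1), "c|d")
})

test_that("negative branch lengths are clamped with a warning", {
  # violates the triangle inequality: the three-point formula goes negative
  m <- matrix(c(0, 1, 1,
                1, 0, 3,
                1, 3, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_warning(tr <- neighbor_joining(m), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("newick IO round-trips plain, supported and quoted trees", {
  for (s in c("(A:1,B:1,(C:1,D:1):2);",
              "(A:1,B:1,(C:1,D:1)95:2);",
              "((A:0.1,B:0.2)90:0.3,C:0.4,(D:0.5,E:0.6)55:0.7);")) {
    tr <- read_newick(s)
    expect_identical(write_newick(tr), s)
  }
  # quoted labels with spaces
  s <- "('taxon one':1,'O''Brien sp.':2,(C:1,D:1):2);"
  tr <- read_newick(s)
  expect_true("taxon one" %in% tr$tip.label)
  expect_true("O'Brien sp." %in% tr$tip.label)
  expect_identical(write_newick(tr), s)
  # agreement with ape on unquoted trees
  tr2 <- read_newick("(A:1,B:2,(C:3,D:4)77:5);")
  ape2 <- ape::read.tree(text = "(A:1,B:2,(C:3,D:4)77:5);")
  expect_setequal(serprot:::bipartitions(tr2), phylo_bipartitions_ape(ape2))
  expect_equal(sort(tr2$edge.length), sort(ape2$edge.length))
})

test_that("newick fuzz: write/read is stable for random trees", {
  withr::with_seed(77, {
    for (i in 1:15) {
      n <- sample(3:10, 1)
      tr <- ape::rtree(n)
      tr$tip.label <- paste("tax", seq_len(n), sample(letters, n, TRUE))
      s1 <- write_newick(tr)
      s2 <- write_newick(read_newick(s1))
      expect_identical(s2, s1)
      back <- read_newick(s1)
      expect_setequal(back$tip.label, tr$tip.label)
      expect_equal(sort(back$edge.length), sort(tr$edge.length),
                   tolerance = 1e-9)
    }
  })
})

test_that("malformed newick reports the character offset", {
  err <- tryCatch(read_newick("(A:1,B:2;"), error = identity)
  expect_s3_class(err, "serprot_parse_error")
  expect_match(conditionMessage(err), "character [0-9]+")
  expect_error(read_newick("(A:1,B:xx);"), class = "serprot_parse_error")
})

test_that("a uniform alignment gives full support everywhere", {
  aln <- c(a = strrep("A", 30), b = strrep("C", 30),
           c = strrep("D", 30), d = strrep("E", 30))
  bs <- suppressWarnings(
    bootstrap_support(aln, replicates = 20, seed = 1, model = "p-distance"))
  tb <- tidy(bs)
  expect_true(all(tb$support == 100))
})

test_that("bootstrap supports are reproducible for a fixed seed", {
  cfg <- simulation_config(n_leaves = 6, substitution_rate = 0.3, seed = 33)
  fam <- simulate_family(cfg)
  b1 <- bootstrap_support(fam$sequences, replicates = 30, seed = 9)
  b2 <- bootstrap_support(fam$sequences, replicates = 30, seed = 9)
  expect_identical(write_newick(b1), write_newick(b2))
  expect_identical(tidy(b1), tidy(b2))
  b3 <- bootstrap_support(fam$sequences, replicates = 30, seed = 10)
  expect_s3_class(b3, "protease_tree")  # different seed still valid
  tb <- tidy(b1)
  expect_true(all(tb$support >= 0 & tb$support <= 100))
  # support percentages correspond to whole replicate counts
  expect_true(all(abs(tb$support * 30 / 100 -
                        round(tb$support * 30 / 100)) < 0.5 + 1e-9))
})

test_that("the true bipartition outscores the alternatives on a long branch", {
  tree <- read_newick("((A:0.05,B:0.05):0.8,(C:0.05,D:0.05):0.8);")
  cfg <- simulation_config(tree = tree, substitution_rate = 0.4, seed = 44)
  fam <- simulate_family(cfg)
  bs <- bootstrap_support(fam$sequences, replicates = 50, seed = 3)
  tb <- tidy(bs)
  # the full-data NJ tree has one internal edge; it must be AB|CD, whose
  # canonical key (side away from taxon A) is C|D
  expect_identical(tb$bipartition, "C|D")
  expect_gt(tb$support, 60)
})

test_that("majority consensus keeps exactly the majority bipartitions", {
  t1 <- read_newick("((A,B),(C,D),E);")
  # identical trees -> the same tree back with 100% support
  cons <- majority_consensus(list(t1, t1, t1))
  expect_setequal(serprot:::bipartitions(cons), serprot:::bipartitions(t1))
  expect_true(all(stats::na.omit(as.integer(cons$node.label)) == 100))
  # 2-of-3 bipartition included at threshold 0.5
  t2 <- read_newick("((A,B),(C,E),D);")
  t3 <- read_newick("((A,C),(B,D),E);")
  cons2 <- majority_consensus(list(t1, t1, t2))
  expect_true("A|B" %in% serprot:::bipartitions(cons2) ||
              "C|D|E" %in% serprot:::bipartitions(cons2))
  # mismatched leaf sets are an input error
  t4 <- read_newick("((A,B),(C,F),E);")
  expect_error(majority_consensus(list(t1, t4)), class = "serprot_input_error")
  expect_error(majority_consensus(list()), class = "serprot_input_error")
  # strictness: a bipartition in exactly half the trees is excluded
  consHalf <- majority_consensus(list(t1, t3))
  expect_length(serprot:::bipartitions(consHalf), 0L)
})

test_that("consensus bipartition frequencies match brute-force counting", {
  withr::with_seed(55, {
    for (trial in 1:8) {
      trees <- replicate(5, {
        tr <- ape::rtree(6)
        tr$tip.label <- LETTERS[1:6]
        read_newick(write_newick(tr))
      }, simplify = FALSE)
      cons <- majority_consensus(trees)
      # oracle: count canonical keys across trees via ape machinery
      keys <- unlist(lapply(trees, phylo_bipartitions_ape))
      freq <- table(keys) / length(trees)
      want <- sort(names(freq)[freq > 0.5])
      expect_identical(sort(serprot:::bipartitions(cons)), want)
    }
  })
})
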