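# annotation IO, locus identification, geometry, inversions

defs <- locus_definitions()

toy_gff <- function(lines, ext = ".gff3") {
  f <- tempfile(fileext = ext)
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 coordinates are converted to 0-based half-open", {
  f <- toy_gff("chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=g1;category=protease")
  g <- read_annotation(f)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_identical(g$category, "protease")
})

test_that("BED coordinates pass through unchanged", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg1\t0\t-", f)
  g <- read_annotation(f)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_identical(g$strand, "-")
})

test_that("malformed lines are rejected and logged, the rest parsed", {
  good <- sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g%d;Name=g%d",
                  (1:9) * 1000, (1:9) * 1000 + 500, 1:9, 1:9)
  f <- toy_gff(c(good[1:5], "chr1\tbroken line without fields", good[6:9]))
  expect_warning(g <- read_annotation(f), "malformed")
  expect_equal(nrow(g), 9L)
})

test_that("records with end <= start after normalisation are rejected", {
  f <- toy_gff(c(
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=ok;Name=ok",
    "chr1\tsrc\tgene\t300\t250\t.\t+\t.\tID=bad;Name=bad"))
  expect_warning(g <- read_annotation(f), "end <= start|malformed")
  expect_identical(g$gene_id, "ok")
})

test_that("a planted locus between markers is identified", {
  cfg <- simulation_config(seed = 2)
  loc <- simulate_locus(cfg, defs$chymase, n_proteases = 2)
  cand <- identify_locus(loc$genes, defs$chymase)
  expect_gte(length(cand), 1L)
  best <- cand[[1]]
  expect_equal(sum(best$genes$category == "protease"), 2L)
  expect_equal(best$marker_count, 5L)  # 4 left + 1 right
  expect_false(best$split)
})

test_that("marker matching is case-insensitive and alias-aware", {
  genes <- tibble::tibble(
    gene_id = c("ripk3", "P1", "rnf17"),   # RNF17 aliases STXBP6 (mouse)
    contig = "c1", start = c(0L, 1000L, 2000L),
    end = c(500L, 1500L, 2500L), strand = "+",
    category = c("other", "protease", "other"), pseudogene = FALSE)
  cand <- identify_locus(genes, defs$chymase)
  expect_equal(length(cand), 1L)
  expect_identical(cand[[1]]$genes$gene_id, c("ripk3", "P1", "rnf17"))
})

test_that("markers on two contigs give a split locus with partial maps", {
  cfg <- simulation_config(seed = 4)
  spl <- simulate_locus(cfg, defs$chymase, n_proteases = 3,
                        forced_events = list(list(type = "split", target = "PROT1")))
  expect_equal(length(unique(spl$genes$contig)), 2L)
  cand <- identify_locus(spl$genes, defs$chymase)
  expect_equal(length(cand), 2L)
  expect_true(all(vapply(cand, function(x) x$split, logical(1))))
  expect_setequal(unlist(lapply(cand, function(x) x$contig)),
                  unique(spl$genes$contig))
})

test_that("no matched marker yields an empty diagnostic result, not an error", {
  genes <- tibble::tibble(gene_id = c("foo", "bar"), contig = "c1",
                          start = c(0L, 100L), end = c(50L, 150L),
                          strand = "+", category = "other", pseudogene = FALSE)
  expect_message(cand <- identify_locus(genes, defs$chymase), "no marker")
  expect_length(cand, 0L)
  expect_match(attr(cand, "diagnostics"), "no marker")
})

test_that("identified locus content matches a brute-force marker-pair scan", {
  def <- locus_definition("toy", left_markers = "LM", right_markers = "RM")
  withr::with_seed(31, {
    for (trial in 1:25) {
      n <- sample(10:50, 1)
      ids <- sprintf("g%02d", seq_len(n))
      li <- sample(n - 4, 1); ri <- li + sample(2:4, 1)
      ids[li] <- "LM"; ids[ri] <- "RM"
      starts <- sort(sample.int(1e6, n))
      genes <- tibble::tibble(
        gene_id = ids, contig = "c1", start = starts,
        end = starts + sample(100:900, n, replace = TRUE),
        strand = sample(c("+", "-"), n, replace = TRUE),
        category = "other", pseudogene = FALSE)
      cand <- identify_locus(genes, def)
      got <- cand[[1]]$genes$gene_id
      want <- oracle_locus_genes(genes, "LM", "RM")
      expect_identical(got, want)
    }
  })
})

test_that("geometry arithmetic: sizes, gaps, adjacency, overlaps", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    contig = "c1",
    start = c(100L, 500L, 800L, 840L),
    end   = c(200L, 800L, 850L, 900L),
    strand = "+", category = "other", pseudogene = FALSE)
  geo <- compute_geometry(genes)
  expect_equal(geo$size, c(100L, 300L, 50L, 60L))
  expect_equal(geo$distance_to_next[1], 300L)
  expect_equal(geo$distance_to_next[2], 0L)   # adjacent
  expect_false(geo$overlaps_next[2])
  expect_equal(geo$distance_to_next[3], 0L)   # overlapping, clamped
  expect_true(geo$overlaps_next[3])
})

test_that("sizes plus gaps equal the span for non-overlapping loci", {
  cfg <- simulation_config(seed = 8)
  loc <- simulate_locus(cfg, defs$met_ase, n_proteases = 5)
  geo <- compute_geometry(loc$genes)
  span <- max(geo$end) - min(geo$start)
  expect_equal(sum(geo$size) + sum(geo$distance_to_next, na.rm = TRUE), span)
})

test_that("inversions are flagged against a reference orientation", {
  cfg <- simulation_config(seed = 12)
  loc <- simulate_locus(cfg, defs$chymase, n_proteases = 2,
                        forced_events = list(list(type = "inversion",
                                                  target = "STXBP6")))
  cand <- identify_locus(loc$genes, defs$chymase)
  ref <- c(RIPK3 = "+", NYNRIN = "+", CBLN3 = "+", SDR39U1 = "+", STXBP6 = "+")
  flags <- detect_inversion(cand[[1]], ref)
  expect_identical(flags$marker[flags$inverted], "STXBP6")
  # all markers matching the reference -> no flags
  loc2 <- simulate_locus(simulation_config(seed = 12), defs$chymase,
                         n_proteases = 2)
  flags2 <- detect_inversion(identify_locus(loc2$genes, defs$chymase)[[1]], ref)
  expect_false(any(flags2$inverted))
})

test_that("markers without reference orientation are skipped with a warning", {
  cfg <- simulation_config(seed = 13)
  loc <- simulate_locus(cfg, defs$chymase, n_proteases = 1)
  cand <- identify_locus(loc$genes, defs$chymase)
  expect_warning(flags <- detect_inversion(cand[[1]], c(STXBP6 = "+")),
                 "skipped")
  expect_identical(flags$marker, "STXBP6")
  expect_error(suppressWarnings(detect_inversion(cand[[1]], c(NOPE = "+"))),
               class = "serprot_input_error")
})

test_that("GFF3 writing round-trips the gene table", {
  cfg <- simulation_config(seed = 19)
  loc <- simulate_locus(cfg, defs$chymase, n_proteases = 3)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(loc$genes, f)
  back <- read_annotation(f)
  expect_equal(back[order(back$gene_id), ],
               loc$genes[order(loc$genes$gene_id), ],
               ignore_attr = TRUE)
})
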