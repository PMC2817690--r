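test_that("every block yields two breakpoints with orientation-aware pairing", {
  blocks <- data.frame(
    block_id = c("b1", "b2"), chrom_a = "chr1",
    start_a = c(100, 5000), end_a = c(2000, 9000),
    chrom_b = "chrB1", start_b = c(300, 7000), end_b = c(2200, 11000),
    orientation = c("+", "-"), stringsAsFactors = FALSE
  )
  bps <- blocks_to_breakpoints(blocks)
  expect_equal(nrow(bps), 2 * nrow(blocks))
  b1 <- bps[bps$source_block == "b1", ]
  expect_equal(b1$pos_b[b1$which_end == "left"], 300)    # + : left <-> left
  expect_equal(b1$pos_b[b1$which_end == "right"], 2200)
  b2 <- bps[bps$source_block == "b2", ]
  expect_equal(b2$pos_b[b2$which_end == "left"], 11000)  # - : left <-> right
  expect_equal(b2$pos_b[b2$which_end == "right"], 7000)

  set.seed(19)
  n <- 565
  many <- data.frame(
    block_id = sprintf("b%03d", 1:n), chrom_a = "chr1",
    start_a = (1:n) * 1e4, end_a = (1:n) * 1e4 + 5e3,
    chrom_b = "chrB1", start_b = (1:n) * 1e4, end_b = (1:n) * 1e4 + 5e3,
    orientation = sample(c("+", "-"), n, TRUE), stringsAsFactors = FALSE
  )
  expect_equal(nrow(blocks_to_breakpoints(many)), 1130)
})

test_that("breakpoint enrichment chi-square matches the textbook formula", {
  # the published chicken counts: 253 of 1130 breakpoints in regions
  # covering 10% of the genome
  rep1 <- ridgescan:::enrichment_from_counts(253, 1130, 0.10)
  expect_equal(rep1$expected, 113)
  expect_equal(rep1$chi_square, chisq_formula(253, 1130, 0.10), tolerance = 1e-12)
  expect_equal(rep1$chi_square, 192.72, tolerance = 1e-4)
  expect_lt(rep1$p_value, 1e-15)
  expect_equal(rep1$direction, "enriched")

  # observed exactly expected
  rep2 <- ridgescan:::enrichment_from_counts(10, 100, 0.10)
  expect_equal(rep2$chi_square, 0)
  expect_equal(rep2$p_value, 1)

  # total depletion
  rep3 <- ridgescan:::enrichment_from_counts(0, 100, 0.10)
  expect_equal(rep3$chi_square, chisq_formula(0, 100, 0.10), tolerance = 1e-12)
  expect_equal(rep3$chi_square, 100 / 9, tolerance = 1e-10)
  expect_equal(rep3$direction, "depleted")

  # random-count property: formula oracle and complement-swap invariance
  set.seed(29)
  for (i in 1:25) {
    n <- sample(50:2000, 1)
    f <- runif(1, 0.05, 0.95)
    k <- rbinom(1, n, runif(1, 0.05, 0.95))
    r <- ridgescan:::enrichment_from_counts(k, n, f)
    expect_equal(r$chi_square, chisq_formula(k, n, f), tolerance = 1e-9)
    swapped <- ridgescan:::enrichment_from_counts(n - k, n, 1 - f)
    expect_equal(swapped$chi_square, r$chi_square, tolerance = 1e-9)
    expect_equal(r$expected + (n - r$expected), n)
  }
})

test_that("breakpoint membership uses half-open point-in-interval positions", {
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                        kind = "RIDGE", stringsAsFactors = FALSE)
  bps <- data.frame(chrom_a = "chr1", pos_a = c(999, 1000, 1999, 2000),
                    chrom_b = "x", pos_b = 0,
                    source_block = "b", which_end = "left")
  r <- breakpoint_enrichment(bps, regions, genome_length = 10000)
  expect_equal(r$n_in_regions, 2)    # 1000 and 1999 in; 999 and 2000 out
  expect_error(breakpoint_enrichment(bps, regions[0, ], 10000), "degenerate")
})

test_that("cross-species classification labels region-to-region breakpoints", {
  regions_a <- data.frame(chrom = "chr1", start = c(0, 5000),
                          end = c(1000, 6000),
                          kind = c("RIDGE", "antiRIDGE"), stringsAsFactors = FALSE)
  regions_b <- data.frame(chrom = "chrB1", start = c(0, 5000),
                          end = c(1000, 6000),
                          kind = c("RIDGE", "antiRIDGE"), stringsAsFactors = FALSE)
  bps <- data.frame(
    chrom_a = "chr1", pos_a = c(500, 500, 5500, 3000),
    chrom_b = "chrB1", pos_b = c(500, 3000, 5500, 3000),
    source_block = sprintf("b%d", 1:4), which_end = "left",
    stringsAsFactors = FALSE
  )
  cls <- classify_cross_species(bps, regions_a, regions_b)
  expect_equal(cls$table$kind_a, c("RIDGE", "RIDGE", "antiRIDGE", "none"))
  expect_equal(cls$table$kind_b, c("RIDGE", "none", "antiRIDGE", "none"))
  expect_equal(cls$ridge_to_ridge$observed, 1)
  expect_equal(cls$anti_to_anti$observed, 1)
  expect_equal(cls$ridge_to_ridge$expected, 4 * (2 / 4) * (1 / 4))
  expect_error(classify_cross_species(bps, NULL, regions_b), "both genomes")
})

test_that("biased breakpoint placement is detected as enrichment", {
  sim <- simulate_dataset(simulation_config(seed = 33, n_chromosomes = 6,
                                            chrom_length_range = c(3e7, 8e7)))
  bps <- blocks_to_breakpoints(sim$blocks)
  tr <- truth_regions(sim$truth)
  high <- tr[tr$kind == "RIDGE", ]
  gl <- sum(sim$truth$chrom_lengths)
  r <- breakpoint_enrichment(bps, high, gl)
  expect_equal(r$direction, "enriched")
  expect_lt(r$p_value, 0.05)
  # and region-to-region cuts survive the rearrangement into genome B
  cls <- classify_cross_species(bps, tr, truth_regions(sim$truth_b))
  expect_gt(cls$ridge_to_ridge$observed, cls$ridge_to_ridge$expected)
  expect_lt(cls$ridge_to_ridge$p_value, 0.05)
})

test_that("homolog overlap reproduces the published worked example", {
  fx <- make_overlap_fixture(n_pairs = 11407, n_in_a = 1351, n_both = 361)
  ov <- homolog_region_overlap(fx$pairs, fx$regions_a, fx$regions_b,
                               fx$genes_a, fx$genes_b)
  expect_equal(ov$n_a_in_ridge, 1351)
  expect_equal(ov$n_both_in_ridge, 361)
  expect_equal(round(ov$percent_overlap), 27)
  expect_lt(ov$p_value, 1e-15)   # far above the independence expectation
})

test_that("homolog overlap flags a zero denominator and matches null placement", {
  fx <- make_overlap_fixture(n_pairs = 100, n_in_a = 10, n_both = 5)
  no_a <- fx$regions_a; no_a$start <- 9e8; no_a$end <- 9e8 + 10
  ov0 <- homolog_region_overlap(fx$pairs, no_a, fx$regions_b,
                                fx$genes_a, fx$genes_b)
  expect_true(ov0$degenerate)
  expect_true(is.na(ov0$percent_overlap))

  expect_error(
    homolog_region_overlap(data.frame(gene_id_a = "zz", gene_id_b = "b00001"),
                           fx$regions_a, fx$regions_b, fx$genes_a, fx$genes_b),
    "unknown gene id"
  )

  # random B placement: overlap percentage approaches 100 x B fraction
  set.seed(41)
  n <- 4000
  b_in <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.3, 0.7))
  spacing <- 1000
  genes_a <- make_genes((seq_len(n) - 1) * spacing, len = 100, chrom = "chrA",
                        ids = sprintf("a%05d", seq_len(n)))
  # B genes inside [0, ridge_end) iff b_in; others far away
  b_pos <- ifelse(b_in, (cumsum(b_in) - 1) * spacing,
                  5e7 + (seq_len(n)) * spacing)
  genes_b <- make_genes(b_pos, len = 100, chrom = "chrB",
                        ids = sprintf("b%05d", seq_len(n)))
  regions_a <- data.frame(chrom = "chrA", start = 0, end = 1000 * spacing,
                          kind = "RIDGE", stringsAsFactors = FALSE)
  regions_b <- data.frame(chrom = "chrB", start = 0, end = sum(b_in) * spacing,
                          kind = "RIDGE", stringsAsFactors = FALSE)
  pairs <- data.frame(gene_id_a = sprintf("a%05d", seq_len(n)),
                      gene_id_b = sprintf("b%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
  ov <- homolog_region_overlap(pairs, regions_a, regions_b, genes_a, genes_b)
  expect_lt(abs(ov$percent_overlap - 30), 2 * sqrt(0.3 * 0.7 / 1000) * 100 * 1.5)
})
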