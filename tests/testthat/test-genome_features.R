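test_that("gene density counts midpoints per 100 kb with end clipping", {
  # 5 genes clustered within one 100-kb window on a long chromosome
  genes <- make_genes(c(0, 1e6, 1.01e6, 1.02e6, 1.03e6, 1.04e6, 2.2e6, 4e6),
                      len = 1000)
  tr <- gene_density(genes, window_bp = 1e5, window = 1)
  centre <- which(tr$gene_id == genes$gene_id[4])
  expect_equal(tr$raw[centre], 5)
  # interior isolated gene, neighbours > 50 kb away
  expect_equal(tr$raw[tr$midpoint == 2200500], 1)

  # a gene 10 kb from the chromosome start: window clipped to 60 kb,
  # count rescaled by 100/60
  genes2 <- make_genes(c(0, 10000, 3e5), len = 100)
  tr2 <- gene_density(genes2, window_bp = 1e5, window = 1)
  g2 <- which(tr2$midpoint == 10050)
  # clipped window [0, 60050] of width 60050 holds 2 midpoints
  expect_equal(tr2$raw[g2], 2 * 1e5 / 60050)
  expect_error(gene_density(genes2, window_bp = 0), "positive")
})

test_that("mean density times span recovers the gene count on uniform genomes", {
  set.seed(9)
  genes <- make_genes(sort(sample(0:2e6, 1000)), len = 200)
  tr <- gene_density(genes, window_bp = 1e5, window = 1)
  span <- max(genes$end) - min(genes$start)
  est <- mean(tr$raw) / 1e5 * span
  expect_lt(abs(est - 1000) / 1000, 0.10)
})

test_that("average intron length is the two-level transcript mean", {
  genes <- make_genes(c(0, 2000, 4000), len = 1000,
                      introns = list(list(c(100, 200), 300),
                                     list(),
                                     list(c(50, 150))))
  a <- avg_intron_length(genes)
  expect_equal(a[1], 225)        # mean(mean(100,200), 300)
  expect_true(is.na(a[2]))       # intronless -> missing, not zero
  expect_equal(a[3], 100)
})

test_that("minimal introns use inclusive 50-150 bp bounds", {
  genes <- make_genes(c(0, 6e5), len = 1000,
                      introns = list(list(c(49, 50, 150, 151)), list()))
  tr <- minimal_intron_density(genes, window_bp = 5e5, window = 1)
  # gene 1: clipped window [0, 250500] holds only gene 1's introns: 2 qualify
  g1 <- which(tr$gene_id == genes$gene_id[1])
  width <- 250500
  expect_equal(tr$raw[g1], 2 * 5e5 / width)
  # no qualifying introns anywhere -> all-zero track
  none <- make_genes(c(0, 1e5), len = 1000)
  expect_equal(minimal_intron_density(none, window = 1)$raw, c(0, 0))
})

test_that("feature tracks are invariant to input row order", {
  set.seed(31)
  genes <- make_genes(sort(sample(0:1e6, 80)), len = 300,
                      gc = runif(80, 0.3, 0.6))
  for (f in c("gene_density", "gc_fraction", "gene_length")) {
    a <- feature_track(genes, f, window = 5)
    b <- feature_track(genes[sample(80), ], f, window = 5)
    expect_equal(b, a)
  }
})

test_that("map-track correlation is exact on self and negated tracks", {
  set.seed(13)
  genes <- make_genes(sort(sample(0:1e6, 100)), len = 200)
  expr <- make_expr(genes$gene_id, rnorm(100, 7))
  map <- build_map(genes, expr, window = 5)
  self_track <- feature_track(genes, "gene_length", window = 5)
  self_track$smoothed <- map$smoothed
  expect_equal(map_feature_correlation(map, self_track)$rho, 1)
  self_track$smoothed <- -map$smoothed
  expect_equal(map_feature_correlation(map, self_track)$rho, -1)
  expect_error(map_feature_correlation(map, self_track[1:10, ]), "not aligned")
})

test_that("independent tracks correlate near zero, and the permutation p agrees", {
  set.seed(17)
  rhos <- replicate(20, {
    genes <- make_genes(sort(sample(0:1e8, 500)), len = 200,
                        gc = runif(500, 0.3, 0.6))
    expr <- make_expr(genes$gene_id, rnorm(500, 7))
    map <- build_map(genes, expr, window = 5)
    tr <- feature_track(genes, "gc_fraction", window = 5, map = map)
    map_feature_correlation(map, tr)$rho
  })
  expect_gt(mean(abs(rhos) < 0.25), 0.9)

  genes <- make_genes(sort(sample(0:1e6, 60)), len = 100,
                      gc = runif(60, 0.3, 0.6))
  expr <- make_expr(genes$gene_id, rnorm(60, 7))
  map <- build_map(genes, expr, window = 5)
  tr <- feature_track(genes, "gc_fraction", window = 5, map = map)
  approx_p <- map_feature_correlation(map, tr)$p_value
  perm_p <- map_feature_correlation(map, tr, exact_perm = TRUE,
                                    n_perm = 2000, seed = 4)$p_value
  expect_lt(abs(approx_p - perm_p), 0.12)
})

test_that("rank-sum statistic matches brute-force enumeration on small groups", {
  set.seed(23)
  for (i in 1:20) {
    x <- sample(1:20, sample(3:8, 1), replace = TRUE)
    y <- sample(1:20, sample(3:8, 1), replace = TRUE)
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(unname(w$statistic), brute_rank_sum_W(x, y))
  }
})

test_that("region feature comparison reports groups, medians and contrasts", {
  # 30 RIDGE genes short, 30 anti-RIDGE genes long, by construction
  genes <- make_genes(c((0:29) * 1e4, 1e6 + (0:29) * 1e4),
                      len = rep(c(1000, 8000), each = 30))
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 1e6), end = c(3e5, 1.3e6),
                        kind = c("RIDGE", "antiRIDGE"), stringsAsFactors = FALSE)
  r <- compare_region_features(genes, regions, "gene_length")
  expect_equal(unname(r$n[c("RIDGE", "antiRIDGE")]), c(30, 30))
  expect_lt(r$medians["RIDGE"], r$medians["antiRIDGE"])
  expect_lt(r$tests$ridge_vs_antiridge$p_value, 0.01)

  # identical value multisets in both groups: no location shift
  genes_eq <- make_genes(c((0:9) * 1e4, 1e6 + (0:9) * 1e4),
                         len = rep((1:10) * 1000, 2))
  r_eq <- compare_region_features(genes_eq, regions, "gene_length")
  expect_equal(r_eq$medians[["RIDGE"]], r_eq$medians[["antiRIDGE"]])
  expect_gt(r_eq$tests$ridge_vs_antiridge$p_value, 0.99)

  tiny <- data.frame(chrom = "chr1", start = 0, end = 1e4, kind = "RIDGE",
                     stringsAsFactors = FALSE)
  tiny <- rbind(tiny, data.frame(chrom = "chr1", start = 2e6, end = 2.1e6,
                                 kind = "antiRIDGE"))
  expect_error(compare_region_features(genes_eq, tiny, "gene_length"),
               "fewer than 2 genes")
})
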