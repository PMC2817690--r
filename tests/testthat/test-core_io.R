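test_that("gene table TSV reads with 1-based to 0-based conversion and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tchrom\tstart\tend\tstrand\tgc_fraction\tintron_lengths",
    "g1\tchr1\t100\t500\t+\t0.45\t100,200;300",
    "g2\tchr1\t900\t1200\t-\t0.5\t",
    "g3\tchr2\t1\t50\t+\t0.2\t80"
  ), path)
  g <- read_gene_table(path, "tsv")
  expect_equal(g$gene_id, c("g1", "g2", "g3"))
  expect_equal(g$start[g$gene_id == "g1"], 99)   # 1-based inclusive shifted
  expect_equal(g$end[g$gene_id == "g1"], 500)
  expect_equal(g$gc_fraction[1], 0.45)
  expect_equal(g$introns[[1]], list(c(100, 200), 300))
  expect_equal(g$introns[[2]], list())
  # round trip is the identity
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g, path2)
  g2 <- read_gene_table(path2, "tsv")
  expect_equal(g2, g)
})

test_that("BED dialect passes coordinates through, including start 0", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t400\tg1\t0\t+",
               "chr1\t1000\t1500\tg2\t0\t-"), path)
  g <- read_gene_table(path, "bed")
  expect_equal(g$start, c(0, 1000))
  expect_equal(g$end, c(400, 1500))
  expect_equal(g$strand, c("+", "-"))
})

test_that("gene table validation rejects bad records with their position", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               "g1\tchr1\t100\t100\t+"), path)
  expect_error(read_gene_table(path, "tsv"), "start >= end.*record 1")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tstrand", "g1\tchr1\t100\t+"), path2)
  expect_error(read_gene_table(path2, "tsv"), "missing required column.*end")
})

test_that("expression reader computes cross-tissue medians and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1\tt2\tt3", "g1\t2\t4\t6"), path)
  expect_equal(unname(read_expression(path)$summary), 4)

  path_even <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1\tt2", "g1\t2\t4"), path_even)
  expect_equal(unname(read_expression(path_even)$summary), 3)

  path_dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1", "g1\t2", "g1\t3"), path_dup)
  expect_error(read_expression(path_dup), "duplicate gene id")

  path_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1\tt2", "g1\t2\tNaNo"), path_bad)
  expect_error(read_expression(path_bad), "row 1.*column 't2'")
})

test_that("probe collapsing averages per gene and reports dropped probes", {
  pv <- matrix(c(6, 8, 5,
                 1, 2, 9), ncol = 2,
               dimnames = list(c("p1", "p2", "p3"), c("t1", "t2")))
  map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("g1", "g1"))
  res <- collapse_probes(pv, map)
  expect_equal(unname(res$table$values["g1", "t1"]), 7)  # mean(6, 8)
  expect_equal(res$report$n_dropped_unmapped, 1)         # p3 has no mapping

  pv3 <- matrix(c(1, 2, 9), ncol = 1, dimnames = list(c("p1", "p2", "p3"), "t1"))
  map3 <- data.frame(probe_id = c("p1", "p2", "p3"), gene_id = "g1")
  expect_equal(unname(collapse_probes(pv3, map3)$table$values["g1", "t1"]), 4)

  # probe mapping to two genes is dropped and counted, not assigned
  map_multi <- data.frame(probe_id = c("p1", "p1", "p2"),
                          gene_id = c("g1", "g2", "g3"))
  res2 <- collapse_probes(pv3[1:2, , drop = FALSE], map_multi)
  expect_equal(res2$report$n_dropped_multi_gene, 1)
  expect_equal(res2$table$gene_ids, "g3")

  # an exact duplicate probe->gene row is an annotation error
  map_dup <- data.frame(probe_id = c("p1", "p1"), gene_id = c("g1", "g1"))
  expect_error(collapse_probes(pv3, map_dup), "duplicate probe-to-gene")
  expect_error(collapse_probes(pv3, data.frame(probe_id = "q9", gene_id = "g1")),
               "no probe")
})

test_that("region BED round-trips, including the empty set", {
  regions <- data.frame(
    chrom = c("chr1", "chr2"), start = c(1000, 0), end = c(5000, 800),
    kind = c("RIDGE", "antiRIDGE"), mean_smoothed = c(8.25, 5.5),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions(regions, path)
  lines <- readLines(path)
  expect_match(lines[1], "^chr1\t1000\t5000\tRIDGE\t")
  expect_equal(read_regions(path), regions)

  empty <- regions[0, ]
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_regions(empty, path2)
  expect_true(file.exists(path2))
  expect_equal(nrow(read_regions(path2)), 0)
})

test_that("synteny and homolog tables validate and round-trip", {
  blocks <- data.frame(
    block_id = c("b1", "b2"), chrom_a = "chr1",
    start_a = c(0, 5000), end_a = c(4000, 9000),
    chrom_b = "chrB1", start_b = c(100, 6000), end_b = c(4100, 10000),
    orientation = c("+", "-"), stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_synteny(blocks, path)
  expect_equal(read_synteny(path), blocks)

  bad <- blocks; bad$end_a[1] <- 0
  path_bad <- withr::local_tempfile(fileext = ".tsv")
  write_synteny(bad, path_bad)
  expect_error(read_synteny(path_bad), "start >= end")

  pairs <- data.frame(gene_id_a = c("a1", "a2"), gene_id_b = c("b1", "b2"))
  hp <- withr::local_tempfile(fileext = ".tsv")
  write_homologs(pairs, hp)
  expect_equal(read_homologs(hp), pairs)
  dup <- data.frame(gene_id_a = c("a1", "a1"), gene_id_b = c("b1", "b2"))
  hp2 <- withr::local_tempfile(fileext = ".tsv")
  write_homologs(dup, hp2)
  expect_error(read_homologs(hp2), "1-to-1")
})
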