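# Fixtures built in code.

# A minimal gene table in internal coordinates. `starts` are gene starts on
# one chromosome; genes are `len` bp long and non-overlapping by default.
make_genes <- function(starts, len = 500, chrom = "chr1", strand = NULL,
                       gc = NA_real_, ids = NULL, introns = NULL) {
  n <- length(starts)
  ids <- ids %||% sprintf("g%03d", seq_len(n))
  df <- data.frame(
    gene_id = ids, chrom = rep_len(chrom, n), start = starts,
    end = starts + len, strand = strand %||% rep_len("+", n),
    gc_fraction = rep_len(gc, n), stringsAsFactors = FALSE
  )
  df$introns <- introns %||% rep(list(list()), n)
  df[order(df$chrom, df$start, df$gene_id), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An expression table with one value per gene replicated over tissues.
make_expr <- function(ids, values, n_tissues = 4) {
  m <- matrix(rep(values, n_tissues), ncol = n_tissues,
              dimnames = list(ids, sprintf("t%d", seq_len(n_tissues))))
  expression_table(m)
}

# A transcriptome_map object with prescribed raw and smoothed values, genes
# laid out every `spacing` bp. Used to exercise the region caller on
# hand-constructed profiles.
make_map <- function(raw, smoothed = raw, chrom = "chr1", window = 39L,
                     spacing = 10000, len = 5000) {
  n <- length(raw)
  chrom <- rep_len(chrom, n)
  stopifnot(!is.unsorted(match(chrom, unique(chrom))))  # grouped input
  idx_in_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- (idx_in_chrom - 1) * spacing
  df <- data.frame(
    chrom = chrom, gene_id = sprintf("g%04d", seq_len(n)),
    midpoint = start + len / 2, start = start, end = start + len,
    strand = "+", raw = raw, smoothed = smoothed,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("transcriptome_map", "data.frame"),
            window = as.integer(window), label = "combined",
            n_dropped_no_expression = 0L, excluded_chromosomes = character(0))
}

# Gene/region/homolog fixture reproducing a two-genome RIDGE overlap layout:
# `n_in_a` pairs have their A gene in the single A RIDGE, `n_both` of those
# also have the B partner in the single B RIDGE, out of `n_pairs` pairs.
make_overlap_fixture <- function(n_pairs, n_in_a, n_both) {
  stopifnot(n_in_a <= n_pairs, n_both <= n_in_a)
  spacing <- 1000
  ridge_a_end <- n_in_a * spacing
  a_starts <- (seq_len(n_pairs) - 1) * spacing   # first n_in_a inside RIDGE
  genes_a <- make_genes(a_starts, len = 100, chrom = "chrA",
                        ids = sprintf("a%05d", seq_len(n_pairs)))
  regions_a <- data.frame(chrom = "chrA", start = 0, end = ridge_a_end,
                          kind = "RIDGE", stringsAsFactors = FALSE)
  # B layout: pair i in B RIDGE iff i <= n_both
  ridge_b_end <- n_both * spacing
  b_starts <- (seq_len(n_pairs) - 1) * spacing
  genes_b <- make_genes(b_starts, len = 100, chrom = "chrB",
                        ids = sprintf("b%05d", seq_len(n_pairs)))
  regions_b <- data.frame(chrom = "chrB", start = 0, end = ridge_b_end,
                          kind = "RIDGE", stringsAsFactors = FALSE)
  pairs <- data.frame(gene_id_a = sprintf("a%05d", seq_len(n_pairs)),
                      gene_id_b = sprintf("b%05d", seq_len(n_pairs)),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, genes_a = genes_a, genes_b = genes_b,
       regions_a = regions_a, regions_b = regions_b)
}
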