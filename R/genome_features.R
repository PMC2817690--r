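# Per-gene feature tracks (gene density, GC, gene length, average intron
# length, minimal-intron density) aligned to the transcriptome map's gene
# ordering, and their statistical relation to the map and to called regions.

new_feature_track <- function(df, feature_name, window) {
  structure(df, class = c("feature_track", "data.frame"),
            feature_name = feature_name, window = as.integer(window))
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("feature_track [%s]: %d genes, running-median window %d\n",
              attr(x, "feature_name"), nrow(x), attr(x, "window")))
  invisible(x)
}

# Genes ordered exactly as build_map orders them, restricted to the
# chromosomes of `map` when one is supplied, so tracks align 1:1 with it.
ordered_track_genes <- function(genes, map = NULL) {
  g <- genes
  if (!is.null(map)) {
    g <- g[g$chrom %in% unique(map$chrom) & g$gene_id %in% map$gene_id, , drop = FALSE]
  }
  g <- g[gene_order(g), , drop = FALSE]
  rownames(g) <- NULL
  g
}

smooth_by_chrom <- function(chrom, values, window) {
  out <- rep(NA_real_, length(values))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- running_median(values[sel], window)
  }
  out
}

# Per-gene windowed count helper: for each gene, sum `weights` over the genes
# whose midpoints fall in the window_bp interval centred on its midpoint,
# clipped at the chromosome's analyzed ends, rescaled to the nominal width.
windowed_rate <- function(g, weights, window_bp) {
  out <- rep(NA_real_, nrow(g))
  half <- window_bp / 2
  for (ch in unique(g$chrom)) {
    sel <- which(g$chrom == ch)
    mids <- gene_midpoint(g[sel, , drop = FALSE])
    w <- weights[sel]
    cw <- cumsum(w)
    cs <- min(g$start[sel]); ce <- max(g$end[sel])
    lo <- pmax(mids - half, cs)
    hi <- pmin(mids + half, ce)
    # counts of midpoints in [lo, hi] via cumulative sums over sorted mids
    i_lo <- findInterval(lo - 0.5, mids)        # midpoints < lo
    i_hi <- findInterval(hi, mids)              # midpoints <= hi
    tot <- ifelse(i_lo > 0L, cw[pmax(i_lo, 1L)], 0)
    cnt <- cw[pmax(i_hi, 1L)] - tot
    cnt[i_hi == 0L] <- 0
    out[sel] <- cnt * window_bp / (hi - lo)
  }
  out
}

#' Gene-density track (genes per 100 kb)
#'
#' For each gene, the number of gene midpoints inside a `window_bp` interval
#' centred on the gene's midpoint. The window is clipped at the chromosome's
#' analyzed ends and the count rescaled to the nominal width, so edge genes
#' are not artificially sparse. The raw densities are then running-median
#' smoothed in gene order.
#'
#' @param genes gene table.
#' @param window_bp centring window in base pairs (default 100 kb).
#' @param window odd smoothing window in genes (default 39).
#' @param map optional `transcriptome_map` to align to (restricts the track
#'   to the map's chromosomes and genes).
#' @return a `feature_track` data frame with columns `chrom`, `gene_id`,
#'   `midpoint`, `raw`, `smoothed`.
#' @export
gene_density <- function(genes, window_bp = 1e5, window = 39L, map = NULL) {
  if (window_bp <= 0) stop_fmt("gene_density: window_bp must be positive")
  g <- ordered_track_genes(genes, map)
  raw <- windowed_rate(g, rep(1, nrow(g)), window_bp)
  df <- data.frame(chrom = g$chrom, gene_id = g$gene_id,
                   midpoint = gene_midpoint(g), raw = raw,
                   smoothed = smooth_by_chrom(g$chrom, raw, window),
                   stringsAsFactors = FALSE)
  new_feature_track(df, "gene_density", window)
}

#' Average intron length per gene
#'
#' Two-level average: the mean intron length within each transcript, then the
#' mean over the gene's transcripts. Genes without introns get `NA` and are
#' excluded from intron-based rank tests (a zero would conflate absence with
#' shortness).
#'
#' @param genes gene table.
#' @return numeric vector, one value per gene (`NA` for intronless genes).
#' @export
avg_intron_length <- function(genes) {
  vapply(genes$introns, function(trs) {
    per_tr <- vapply(trs, function(v) if (length(v) == 0L) NA_real_ else mean(v),
                     numeric(1))
    per_tr <- per_tr[!is.na(per_tr)]
    if (length(per_tr) == 0L) NA_real_ else mean(per_tr)
  }, numeric(1))
}

#' Minimal-intron density track (minimal introns per 500 kb)
#'
#' A minimal intron is an intron of `min_bp` to `max_bp` base pairs
#' (inclusive; default 50-150 bp). For each gene, the qualifying introns of
#' all genes whose midpoints fall in a `window_bp` interval centred on the
#' gene are counted, rescaled per 500 kb (with end clipping as in
#' [gene_density()]), and running-median smoothed.
#'
#' @inheritParams gene_density
#' @param min_bp,max_bp inclusive minimal-intron length bounds.
#' @param window_bp centring window (default 500 kb).
#' @export
minimal_intron_density <- function(genes, min_bp = 50, max_bp = 150,
                                   window_bp = 5e5, window = 39L, map = NULL) {
  g <- ordered_track_genes(genes, map)
  counts <- vapply(g$introns, function(trs) {
    lens <- unlist(trs)
    sum(lens >= min_bp & lens <= max_bp)
  }, numeric(1))
  raw <- windowed_rate(g, counts, window_bp)
  df <- data.frame(chrom = g$chrom, gene_id = g$gene_id,
                   midpoint = gene_midpoint(g), raw = raw,
                   smoothed = smooth_by_chrom(g$chrom, raw, window),
                   stringsAsFactors = FALSE)
  new_feature_track(df, "minimal_intron_density", window)
}

#' Per-gene feature track for an annotation-derived feature
#'
#' Builds the gene-ordered raw and smoothed track for one of the supported
#' features. `gene_density` and `minimal_intron_density` are positional
#' (windowed counts); `gc_fraction`, `gene_length` and `avg_intron_length`
#' are direct per-gene values.
#'
#' @param genes gene table.
#' @param feature_name one of `"gene_density"`, `"gc_fraction"`,
#'   `"gene_length"`, `"avg_intron_length"`, `"minimal_intron_density"`.
#' @param window odd smoothing window in genes (default 39).
#' @param map optional map to align to.
#' @return a `feature_track`.
#' @export
feature_track <- function(genes,
                          feature_name = c("gene_density", "gc_fraction",
                                           "gene_length", "avg_intron_length",
                                           "minimal_intron_density"),
                          window = 39L, map = NULL) {
  feature_name <- match.arg(feature_name)
  if (feature_name == "gene_density") {
    return(gene_density(genes, window = window, map = map))
  }
  if (feature_name == "minimal_intron_density") {
    return(minimal_intron_density(genes, window = window, map = map))
  }
  g <- ordered_track_genes(genes, map)
  raw <- feature_values(g, feature_name)
  df <- data.frame(chrom = g$chrom, gene_id = g$gene_id,
                   midpoint = gene_midpoint(g), raw = raw,
                   smoothed = smooth_by_chrom(g$chrom, raw, window),
                   stringsAsFactors = FALSE)
  new_feature_track(df, feature_name, window)
}

# Direct per-gene values for the non-positional features.
feature_values <- function(g, feature_name) {
  switch(feature_name,
    gc_fraction = g$gc_fraction,
    gene_length = g$end - g$start,
    avg_intron_length = avg_intron_length(g),
    stop_fmt("unknown per-gene feature '%s'", feature_name)
  )
}

#' Correlate a transcriptome map with a feature track
#'
#' Spearman rank correlation (default) between the smoothed map values and
#' the smoothed track values over all aligned genes. Running medians are far
#' from normal, so ranks are the appropriate scale; the p-value uses the
#' large-sample t approximation, with an exact permutation p available for
#' n <= 1000. Pearson is exposed for the chromosome-level summaries where a
#' linear correlation is conventional.
#'
#' @param map a `transcriptome_map`.
#' @param track a `feature_track` aligned to the map.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param exact_perm use a permutation p-value instead of the t
#'   approximation (Spearman only; requires n <= 1000).
#' @param n_perm permutations for `exact_perm` (default 10000).
#' @param seed seed for `exact_perm`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
map_feature_correlation <- function(map, track, method = c("spearman", "pearson"),
                                    exact_perm = FALSE, n_perm = 10000L,
                                    seed = 1L) {
  method <- match.arg(method)
  if (nrow(map) != nrow(track)) {
    stop_fmt("map (%d genes) and track (%d genes) are not aligned",
             nrow(map), nrow(track))
  }
  if (!all(map$gene_id == track$gene_id)) {
    stop_fmt("map and track gene orderings differ")
  }
  keep <- !is.na(map$smoothed) & !is.na(track$smoothed)
  x <- map$smoothed[keep]; y <- track$smoothed[keep]
  n <- length(x)
  if (n < 3L) stop_fmt("map_feature_correlation: fewer than 3 aligned genes")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  if (exact_perm) {
    if (method != "spearman") stop_fmt("exact_perm is available for Spearman only")
    if (n > 1000L) stop_fmt("exact_perm supported for n <= 1000, got %d", n)
    obs <- abs(stats::cor(x, y, method = "spearman"))
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(x, sample(y), method = "spearman")) >= obs
      }, logical(1)))
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Compare a feature between RIDGE, anti-RIDGE and genome-wide genes
#'
#' Assigns each gene to RIDGEs or anti-RIDGEs by midpoint membership and runs
#' two-sided Wilcoxon rank-sum tests: RIDGE vs anti-RIDGE (the headline
#' contrast), plus RIDGE vs genome and anti-RIDGE vs genome, together with
#' the three group medians. For intron-based features, intronless genes are
#' excluded rather than scored zero.
#'
#' @param genes gene table.
#' @param regions a `region_set`.
#' @param feature_name as in [feature_track()].
#' @return list with `feature`, `n` (per group), `medians` (per group) and
#'   `tests` (each with `statistic`, `p_value`).
#' @export
compare_region_features <- function(genes, regions,
                                    feature_name = c("gene_density",
                                                     "gc_fraction",
                                                     "gene_length",
                                                     "avg_intron_length",
                                                     "minimal_intron_density")) {
  feature_name <- match.arg(feature_name)
  g <- ordered_track_genes(genes)
  vals <- if (feature_name %in% c("gene_density", "minimal_intron_density")) {
    feature_track(g, feature_name)$raw
  } else {
    feature_values(g, feature_name)
  }
  mids <- gene_midpoint(g)
  in_ridge <- points_in_intervals(g$chrom, mids,
                                  regions[regions$kind == "RIDGE", , drop = FALSE])
  in_anti <- points_in_intervals(g$chrom, mids,
                                 regions[regions$kind == "antiRIDGE", , drop = FALSE])
  groups <- list(RIDGE = vals[in_ridge & !is.na(vals)],
                 antiRIDGE = vals[in_anti & !is.na(vals)],
                 genome = vals[!is.na(vals)])
  for (nm in names(groups)) {
    if (length(groups[[nm]]) < 2L) {
      stop_fmt("compare_region_features: group '%s' has fewer than 2 genes with feature '%s'",
               nm, feature_name)
    }
  }
  wt <- function(a, b) {
    t <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                             exact = FALSE, correct = FALSE))
    list(statistic = unname(t$statistic), p_value = t$p.value)
  }
  list(
    feature = feature_name,
    n = vapply(groups, length, integer(1)),
    medians = vapply(groups, stats::median, numeric(1)),
    tests = list(
      ridge_vs_antiridge = wt(groups$RIDGE, groups$antiRIDGE),
      ridge_vs_genome = wt(groups$RIDGE, groups$genome),
      antiridge_vs_genome = wt(groups$antiRIDGE, groups$genome)
    )
  )
}
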