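# Permutation null for the number of called regions: shuffle the assignment
# of per-gene expression values to gene positions genome-wide (positions
# fixed, values exchanged across all chromosomes), rebuild the smoothed map,
# and recount regions at the fixed thresholds.

#' Permutation test of the region count
#'
#' For each replicate the per-gene summary values are permuted across all
#' gene positions in the genome, the per-chromosome running medians are
#' recomputed, and regions of the requested kind are counted at the fixed
#' (uncalibrated) thresholds of `config`. The genomic median is invariant
#' under permutation (same multiset of values), so the thresholds are
#' constant across replicates. Re-calibrating thresholds per replicate would
#' pin coverage at the target and destroy the test, so calibration is
#' deliberately not applied here; if `config$target_coverage` is set it is
#' ignored with a message.
#'
#' The p-value is the fraction of null counts strictly greater than the
#' observed count; `conservative = TRUE` uses `(k + 1) / (n_perm + 1)`
#' instead.
#'
#' @param genes gene table.
#' @param expr an [expression_table()].
#' @param config a [caller_config()] with fixed multipliers.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; same seed gives bit-identical null counts.
#' @param kind region kind to count (default `"RIDGE"`).
#' @param conservative add-one pseudocount in the p-value (default FALSE).
#' @return a `permutation_result` list: `observed_count`, `null_counts`,
#'   `p_value`, `n_perm`, `seed`, `kind`.
#' @export
permute_and_count <- function(genes, expr, config = caller_config(),
                              n_perm, seed, kind = c("RIDGE", "antiRIDGE"),
                              conservative = FALSE) {
  kind <- match.arg(kind)
  if (n_perm < 1L) stop_fmt("permute_and_count: n_perm must be >= 1")
  if (!is.null(config$target_coverage)) {
    message("permute_and_count: ignoring target_coverage; permutation uses fixed thresholds")
  }
  map <- suppressWarnings(build_map(genes, expr, window = config$window))
  gm <- genomic_median(map)
  mult <- if (kind == "RIDGE") config$ridge_multiplier else config$antiridge_multiplier
  threshold <- mult * gm
  direction <- if (kind == "RIDGE") +1 else -1

  observed <- count_runs_fast(split(map$raw, map$chrom), config$window,
                              threshold, direction, config$min_run)

  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  values <- map$raw
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(values)
      count_runs_fast(lapply(chrom_idx, function(ix) perm[ix]),
                      config$window, threshold, direction, config$min_run)
    }, integer(1))
  })

  k <- sum(null_counts > observed)
  p <- if (conservative) (k + 1) / (n_perm + 1) else k / n_perm
  structure(list(observed_count = observed, null_counts = null_counts,
                 p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), kind = kind,
                 conservative = conservative),
            class = "permutation_result")
}

# Count qualifying runs across a list of per-chromosome raw-value vectors.
count_runs_fast <- function(values_by_chrom, window, threshold, direction,
                            min_run) {
  total <- 0L
  for (v in values_by_chrom) {
    sm <- running_median(v, window)
    qual <- if (direction > 0) sm > threshold else sm < threshold
    r <- rle(qual)
    total <- total + sum(r$values & r$lengths >= min_run)
  }
  total
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed %d %s(s); p = %.4g (%d permutations, seed %d)\n",
              x$observed_count, x$kind, x$p_value, x$n_perm, x$seed))
  invisible(x)
}
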