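# RIDGE / anti-RIDGE calling: maximal runs of consecutive running-median
# values strictly above (below) a multiple of the genomic median, of at least
# a minimum run length, become regions. Thresholds can optionally be
# calibrated so each region kind covers a target fraction of the genome.

#' Caller configuration
#'
#' @param window odd running-median window in genes (default 39).
#' @param min_run minimum number of consecutive qualifying running medians
#'   (default 10).
#' @param ridge_multiplier RIDGE threshold as a multiple of the genomic
#'   median (default 1.19); values must be strictly greater to qualify.
#' @param antiridge_multiplier anti-RIDGE threshold multiple (default 0.78);
#'   values must be strictly smaller to qualify.
#' @param target_coverage optional genome-coverage fraction; when set,
#'   [call_regions()] calibrates both multipliers with
#'   [calibrate_multiplier()] before calling.
#' @return a `caller_config` list.
#' @export
caller_config <- function(window = 39L, min_run = 10L,
                          ridge_multiplier = 1.19,
                          antiridge_multiplier = 0.78,
                          target_coverage = NULL) {
  if (!is_odd(window) || window < 3L) stop_fmt("window must be odd and >= 3")
  if (min_run < 1L) stop_fmt("min_run must be >= 1")
  if (!(antiridge_multiplier > 0 && antiridge_multiplier < 1)) {
    stop_fmt("antiridge_multiplier must lie in (0, 1)")
  }
  if (ridge_multiplier <= 1) stop_fmt("ridge_multiplier must be > 1")
  if (!is.null(target_coverage) &&
      !(target_coverage > 0 && target_coverage < 1)) {
    stop_fmt("target_coverage must lie in (0, 1)")
  }
  structure(list(window = as.integer(window), min_run = as.integer(min_run),
                 ridge_multiplier = ridge_multiplier,
                 antiridge_multiplier = antiridge_multiplier,
                 target_coverage = target_coverage),
            class = "caller_config")
}

#' Genomic median expression
#'
#' The median of the per-gene raw summary values over all genes retained in
#' the map (not of the smoothed values); the reference level that region
#' thresholds are multiples of.
#'
#' @param map a `transcriptome_map`.
#' @return a single log2 value.
#' @export
genomic_median <- function(map) {
  if (nrow(map) == 0L) stop_fmt("genomic_median: empty map")
  stats::median(map$raw)
}

# Maximal qualifying runs of one kind on one already-ordered map.
# direction +1: smoothed strictly greater than threshold; -1: strictly less.
call_runs_one_kind <- function(map, threshold, direction, min_run, kind) {
  res <- list()
  for (ch in unique(map$chrom)) {
    x <- map[map$chrom == ch, , drop = FALSE]
    qual <- if (direction > 0) x$smoothed > threshold else x$smoothed < threshold
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_run)
    for (h in hit) {
      members <- starts[h]:ends[h]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        start = min(x$start[members]),
        end = max(x$end[members]),
        kind = kind,
        n_genes = length(members),
        mean_smoothed = mean(x$smoothed[members]),
        run_length = length(members),
        gene_ids = I(list(x$gene_id[members])),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0),
                      n_genes = integer(0), mean_smoothed = numeric(0),
                      run_length = integer(0),
                      gene_ids = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Call RIDGEs and anti-RIDGEs on a smoothed map
#'
#' A RIDGE is a maximal run of at least `min_run` consecutive genes whose
#' running-median value is strictly greater than
#' `ridge_multiplier x genomic median`; an anti-RIDGE a run strictly below
#' `antiridge_multiplier x genomic median`. Runs never cross chromosome
#' boundaries; a region's span is `[start of first member gene, end of last
#' member gene)`, so every member gene lies inside it. Values exactly at a
#' threshold qualify for neither kind.
#'
#' When `config$target_coverage` is set, both multipliers are first
#' calibrated so each kind's coverage is as close as possible to the target.
#'
#' @param map a `transcriptome_map` built with `config$window`.
#' @param config a [caller_config()].
#' @return a `region_set` data frame with columns `chrom`, `start`, `end`,
#'   `kind`, `n_genes`, `mean_smoothed`, `run_length` and list column
#'   `gene_ids`; attributes record the genomic median, the thresholds and any
#'   calibration result.
#' @export
call_regions <- function(map, config = caller_config()) {
  if (nrow(map) == 0L) stop_fmt("call_regions: empty map")
  if (any(is.na(map$smoothed))) stop_fmt("call_regions: map is not smoothed")
  if (!is.null(attr(map, "window")) && attr(map, "window") != config$window) {
    stop_fmt("call_regions: map was smoothed with window %d but config says %d",
             attr(map, "window"), config$window)
  }
  calibration <- NULL
  ridge_mult <- config$ridge_multiplier
  anti_mult <- config$antiridge_multiplier
  if (!is.null(config$target_coverage)) {
    cal_r <- calibrate_multiplier(map, "RIDGE", config$target_coverage, config)
    cal_a <- calibrate_multiplier(map, "antiRIDGE", config$target_coverage, config)
    ridge_mult <- cal_r$multiplier
    anti_mult <- cal_a$multiplier
    calibration <- list(RIDGE = cal_r, antiRIDGE = cal_a)
  }
  gm <- genomic_median(map)
  ridges <- call_runs_one_kind(map, ridge_mult * gm, +1, config$min_run, "RIDGE")
  antis <- call_runs_one_kind(map, anti_mult * gm, -1, config$min_run, "antiRIDGE")
  out <- rbind(ridges, antis)
  rownames(out) <- NULL
  structure(out, class = c("region_set", "data.frame"),
            genomic_median = gm,
            ridge_threshold = ridge_mult * gm,
            antiridge_threshold = anti_mult * gm,
            ridge_multiplier = ridge_mult,
            antiridge_multiplier = anti_mult,
            config = config, calibration = calibration,
            genome_length = analyzed_genome_length(map))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d RIDGE(s), %d anti-RIDGE(s); genomic median %.4g\n",
              sum(x$kind == "RIDGE"), sum(x$kind == "antiRIDGE"),
              attr(x, "genomic_median")))
  invisible(x)
}

#' Genome-coverage fraction of a set of same-kind regions
#'
#' Union length of the region spans over the analyzed genome length. The
#' member-gene runs of distinct same-kind regions are disjoint by
#' construction, but because a region's span covers its member genes' full
#' extents, the spans of two nearby regions can abut or overlap slightly when
#' a boundary gene is long; the union makes coverage well defined in that
#' case and reduces to the plain sum for disjoint regions.
#'
#' @param regions a `region_set` (or data frame) of a single kind.
#' @param genome_length analyzed genome length in base pairs (sum over
#'   chromosomes of first-gene start to last-gene end;
#'   see [analyzed_genome_length()]).
#' @return fraction in `[0, 1]` (can exceed 1 only if `genome_length` is
#'   inconsistent with the regions).
#' @export
coverage <- function(regions, genome_length) {
  if (length(unique(regions$kind)) > 1L) {
    stop_fmt("coverage: regions must be of a single kind; filter by kind first")
  }
  if (nrow(regions) == 0L) return(0)
  interval_union_length(regions[, c("chrom", "start", "end")]) / genome_length
}

#' Calibrate a threshold multiplier to a target genome coverage
#'
#' Bisects the multiplier so that the coverage of the called regions of the
#' given kind is as close as possible to `target_coverage`. Coverage is a
#' step function of the multiplier (non-increasing for RIDGEs,
#' non-decreasing for anti-RIDGEs), so the exact target may be unattainable;
#' the multiplier with coverage nearest the target among those visited is
#' returned, with `attained = FALSE` flagging a miss larger than `tol`.
#'
#' @param map a smoothed `transcriptome_map`.
#' @param kind `"RIDGE"` or `"antiRIDGE"`.
#' @param target_coverage fraction in (0, 1).
#' @param config a [caller_config()]; supplies `min_run`.
#' @param bounds search interval for the multiplier; defaults to `[1, 3]`
#'   for RIDGEs and `[0.1, 1]` for anti-RIDGEs, which brackets any plausible
#'   log2-scale map.
#' @param iterations bisection steps (default 60).
#' @param tol coverage miss above which the result is flagged unattained
#'   (default 0.01).
#' @return list with `multiplier`, `achieved_coverage`, `target`, `attained`.
#' @export
calibrate_multiplier <- function(map, kind = c("RIDGE", "antiRIDGE"),
                                 target_coverage, config = caller_config(),
                                 bounds = NULL, iterations = 60L, tol = 0.01) {
  kind <- match.arg(kind)
  if (!(target_coverage > 0 && target_coverage < 1)) {
    stop_fmt("target_coverage must lie in (0, 1)")
  }
  gm <- genomic_median(map)
  gl <- analyzed_genome_length(map)
  direction <- if (kind == "RIDGE") +1 else -1
  bounds <- bounds %||% if (kind == "RIDGE") c(1.0, 3.0) else c(0.1, 1.0)

  cov_at <- function(mult) {
    regs <- call_runs_one_kind(map, mult * gm, direction, config$min_run, kind)
    coverage(regs, gl)
  }

  best_mult <- NA_real_
  best_cov <- NA_real_
  best_miss <- Inf
  consider <- function(mult) {
    cv <- cov_at(mult)
    miss <- abs(cv - target_coverage)
    if (miss < best_miss) {
      best_miss <<- miss; best_mult <<- mult; best_cov <<- cv
    }
    cv
  }
  lo <- bounds[1L]; hi <- bounds[2L]
  consider(lo); consider(hi)
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    cv <- consider(mid)
    # coverage decreases as the RIDGE threshold rises and as the anti-RIDGE
    # threshold falls; move the bound that keeps the target bracketed
    if (kind == "RIDGE") {
      if (cv > target_coverage) lo <- mid else hi <- mid
    } else {
      if (cv > target_coverage) hi <- mid else lo <- mid
    }
  }
  attained <- best_miss <= tol
  if (!attained) {
    warn_fmt("calibrate_multiplier(%s): nearest achievable coverage %.4f misses target %.4f",
             kind, best_cov, target_coverage)
  }
  list(multiplier = best_mult, achieved_coverage = best_cov,
       target = target_coverage, attained = attained)
}
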