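# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates `expr`, and restores the
#' state on exit, so seeded package functions never perturb a user's stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a named sub-stream seed from a master seed; keeps independent
# components (positions, expression, synteny, ...) on distinct streams so
# changing the draw count of one does not perturb the others.
mix_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
  as.integer(max(1, s))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_odd <- function(x) x %% 2L == 1L

# Sort key used everywhere genes are ordered along a chromosome:
# midpoint, then start, then gene_id (deterministic tie-break).
gene_order <- function(df) {
  order(df$chrom, gene_midpoint(df), df$start, df$gene_id, method = "radix")
}

#' Gene midpoints in internal (0-based half-open) coordinates
#'
#' Midpoint of a gene is `floor((start + end) / 2)`; an integral midpoint
#' makes the along-chromosome gene ordering deterministic.
#'
#' @param genes a gene table as returned by [read_gene_table()].
#' @return numeric vector of midpoints, one per gene.
#' @export
gene_midpoint <- function(genes) {
  floor((genes$start + genes$end) / 2)
}

# --- interval arithmetic on plain (chrom, start, end) frames -----------------
# All intervals are 0-based half-open.

# Total length of the union of intervals (may overlap).
interval_union_length <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  total <- 0
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    cur_s <- x$start[1]; cur_e <- x$end[1]
    if (nrow(x) > 1L) {
      for (i in 2:nrow(x)) {
        if (x$start[i] <= cur_e) {
          cur_e <- max(cur_e, x$end[i])
        } else {
          total <- total + (cur_e - cur_s)
          cur_s <- x$start[i]; cur_e <- x$end[i]
        }
      }
    }
    total <- total + (cur_e - cur_s)
  }
  total
}

# Length of the intersection of two interval sets.
interval_intersection_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    xa <- a[a$chrom == ch, , drop = FALSE]
    xb <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(xa))) {
      ov <- pmin(xa$end[i], xb$end) - pmax(xa$start[i], xb$start)
      total <- total + sum(ov[ov > 0])
    }
  }
  total
}

#' Base-pair Jaccard index between two interval sets
#'
#' Used to score how well called regions recover planted ground-truth
#' intervals: intersection length over union length, in base pairs.
#'
#' @param a,b data frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return a single number in `[0, 1]`; 1 for identical sets.
#' @export
interval_jaccard <- function(a, b) {
  a <- as.data.frame(a)[, c("chrom", "start", "end")]
  b <- as.data.frame(b)[, c("chrom", "start", "end")]
  inter <- interval_intersection_length(a, b)
  uni <- interval_union_length(a) + interval_union_length(b) - inter
  if (uni == 0) return(if (inter == 0) 1 else 0)
  inter / uni
}

# Membership of points in an interval set: TRUE where (chrom, pos) falls in
# some half-open [start, end). Intervals of one set are assumed disjoint
# per chromosome (true for called regions of one kind).
points_in_intervals <- function(chrom, pos, iv) {
  res <- logical(length(pos))
  if (nrow(iv) == 0L) return(res)
  for (ch in unique(iv$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    x <- iv[iv$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    idx <- findInterval(pos[sel], x$start)
    hit <- idx >= 1L & pos[sel] < x$end[pmax(idx, 1L)]
    res[sel] <- hit
  }
  res
}
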