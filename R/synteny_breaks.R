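# Evolutionary breakpoints from synteny blocks: every block end is a
# breakpoint, with its orthologous position in the other genome determined by
# the block's orientation. Enrichment of breakpoints in called regions is a
# 1-df chi-square against the fraction of the genome the regions cover.

#' Derive breakpoints from synteny blocks
#'
#' Each block contributes exactly two breakpoints, its left and right ends on
#' genome A. For a `+` block the left end of A pairs with the left end of B;
#' for a `-` block the pairing is flipped (left end of A with right end of B).
#'
#' @param blocks validated block table ([read_synteny()]).
#' @return data frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `source_block`, `which_end`; exactly `2 * nrow(blocks)` rows.
#' @export
blocks_to_breakpoints <- function(blocks) {
  flip <- blocks$orientation == "-"
  left <- data.frame(
    chrom_a = blocks$chrom_a, pos_a = blocks$start_a,
    chrom_b = blocks$chrom_b,
    pos_b = ifelse(flip, blocks$end_b, blocks$start_b),
    source_block = blocks$block_id, which_end = "left",
    stringsAsFactors = FALSE
  )
  right <- data.frame(
    chrom_a = blocks$chrom_a, pos_a = blocks$end_a,
    chrom_b = blocks$chrom_b,
    pos_b = ifelse(flip, blocks$start_b, blocks$end_b),
    source_block = blocks$block_id, which_end = "right",
    stringsAsFactors = FALSE
  )
  out <- rbind(left, right)
  out <- out[order(out$source_block, out$which_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Breakpoint enrichment in a region set
#'
#' One-sample chi-square goodness of fit (1 df, no continuity correction)
#' comparing the observed split of breakpoints inside versus outside the
#' regions with the split expected if breakpoints fell uniformly, i.e.
#' proportionally to the fraction of the genome the regions cover.
#'
#' @param breakpoints breakpoint table ([blocks_to_breakpoints()]); positions
#'   on genome A are tested.
#' @param regions regions of a single kind (data frame with `chrom`, `start`,
#'   `end` on genome A).
#' @param genome_length analyzed genome length consistent with the region
#'   coordinates.
#' @param region_fraction optionally override the coverage fraction (e.g.
#'   when regions and breakpoints come from published counts rather than a
#'   map); defaults to total region length / `genome_length`.
#' @return an `enrichment_report` list: `n_total`, `n_in_regions`,
#'   `region_fraction`, `expected`, `chi_square`, `p_value`, `direction`.
#' @export
breakpoint_enrichment <- function(breakpoints, regions, genome_length,
                                  region_fraction = NULL) {
  f <- region_fraction %||%
    (sum(regions$end - regions$start) / genome_length)
  if (f <= 0 || f >= 1) {
    stop_fmt("breakpoint_enrichment: region fraction %.4g is degenerate", f)
  }
  n <- nrow(breakpoints)
  n_in <- sum(points_in_intervals(breakpoints$chrom_a, breakpoints$pos_a,
                                  regions[, c("chrom", "start", "end")]))
  enrichment_from_counts(n_in, n, f)
}

# Core chi-square computation, also used directly when only published counts
# are available.
enrichment_from_counts <- function(n_in, n_total, region_fraction) {
  expected <- n_total * region_fraction
  test <- suppressWarnings(stats::chisq.test(
    c(n_in, n_total - n_in),
    p = c(region_fraction, 1 - region_fraction), correct = FALSE
  ))
  structure(list(
    n_total = n_total, n_in_regions = n_in,
    region_fraction = region_fraction, expected = expected,
    chi_square = unname(test$statistic), p_value = test$p.value,
    direction = if (n_in >= expected) "enriched" else "depleted"
  ), class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment_report: %d of %d breakpoints in regions (%.1f%% of genome); expected %.1f; chi-square %.2f, p = %.3g (%s)\n",
              x$n_in_regions, x$n_total, 100 * x$region_fraction,
              x$expected, x$chi_square, x$p_value, x$direction))
  invisible(x)
}

# Label each point by the kind of region containing it ("RIDGE",
# "antiRIDGE", or "none").
region_kind_at <- function(chrom, pos, regions) {
  lab <- rep("none", length(pos))
  for (k in c("RIDGE", "antiRIDGE")) {
    iv <- regions[regions$kind == k, c("chrom", "start", "end"), drop = FALSE]
    lab[points_in_intervals(chrom, pos, iv)] <- k
  }
  lab
}

#' Classify breakpoints by region membership in both genomes
#'
#' Labels every breakpoint by the region kind containing its genome-A
#' position and the kind containing its orthologous genome-B position, and
#' tests whether RIDGE-to-RIDGE (and anti-RIDGE-to-anti-RIDGE) breakpoints
#' exceed the independence expectation
#' `n_total x fraction(in A kind) x fraction(in B kind)` with a 2x2
#' chi-square (1 df, no continuity correction).
#'
#' @param breakpoints breakpoint table with both genomes' positions.
#' @param regions_a,regions_b region sets for genomes A and B.
#' @return list with `table` (the labelled breakpoints), `counts`
#'   (cross-tabulation of A kind x B kind) and test reports
#'   `ridge_to_ridge`, `anti_to_anti` (each `observed`, `expected`,
#'   `chi_square`, `p_value`).
#' @export
classify_cross_species <- function(breakpoints, regions_a, regions_b) {
  if (is.null(regions_a) || is.null(regions_b)) {
    stop_fmt("classify_cross_species: region sets for both genomes are required")
  }
  kind_a <- region_kind_at(breakpoints$chrom_a, breakpoints$pos_a, regions_a)
  kind_b <- region_kind_at(breakpoints$chrom_b, breakpoints$pos_b, regions_b)
  tab <- breakpoints
  tab$kind_a <- kind_a
  tab$kind_b <- kind_b
  n <- nrow(tab)

  pair_test <- function(kind) {
    in_a <- kind_a == kind
    in_b <- kind_b == kind
    observed <- sum(in_a & in_b)
    expected <- n * mean(in_a) * mean(in_b)
    m <- table(factor(in_a, c(FALSE, TRUE)), factor(in_b, c(FALSE, TRUE)))
    test <- if (mean(in_a) %in% c(0, 1) || mean(in_b) %in% c(0, 1)) {
      list(statistic = c(X = NA_real_), p.value = NA_real_)
    } else {
      suppressWarnings(stats::chisq.test(m, correct = FALSE))
    }
    list(observed = observed, expected = expected,
         chi_square = unname(test$statistic), p_value = test$p.value)
  }

  list(table = tab,
       counts = table(kind_a, kind_b),
       ridge_to_ridge = pair_test("RIDGE"),
       anti_to_anti = pair_test("antiRIDGE"))
}

#' Homolog overlap between two genomes' RIDGEs
#'
#' Of the 1-to-1 homolog pairs whose genome-A gene lies in an A RIDGE, the
#' fraction whose genome-B partner also lies in a B RIDGE, compared by a 1-df
#' chi-square with the fraction expected if B membership were independent of
#' A membership (the fraction of all B genes in B RIDGEs).
#'
#' Gene-in-region membership uses the gene midpoint by default, consistent
#' with how genes are ordered on the map; `"any"` (any overlap) and `"full"`
#' (gene entirely inside) rules are also available.
#'
#' @param pairs homolog pair table ([read_homologs()]).
#' @param regions_a,regions_b region sets for the two genomes.
#' @param genes_a,genes_b gene tables for the two genomes.
#' @param membership `"midpoint"`, `"any"`, or `"full"`.
#' @return list with counts `n_pairs`, `n_a_in_ridge`, `n_both_in_ridge`,
#'   `percent_overlap` (of A-RIDGE pairs also in B RIDGEs, in percent),
#'   `expected_fraction`, `chi_square`, `p_value` and
#'   `degenerate` (TRUE when no pair falls in an A RIDGE).
#' @export
homolog_region_overlap <- function(pairs, regions_a, regions_b,
                                   genes_a, genes_b,
                                   membership = c("midpoint", "any", "full")) {
  membership <- match.arg(membership)
  unknown_a <- setdiff(pairs$gene_id_a, genes_a$gene_id)
  unknown_b <- setdiff(pairs$gene_id_b, genes_b$gene_id)
  if (length(unknown_a) + length(unknown_b) > 0L) {
    stop_fmt("homolog_region_overlap: unknown gene id(s): %s",
             paste(utils::head(c(unknown_a, unknown_b), 5L), collapse = ", "))
  }
  in_ridge <- function(genes, ids, regions) {
    g <- genes[match(ids, genes$gene_id), , drop = FALSE]
    iv <- regions[regions$kind == "RIDGE", c("chrom", "start", "end"), drop = FALSE]
    switch(membership,
      midpoint = points_in_intervals(g$chrom, gene_midpoint(g), iv),
      any = points_in_intervals(g$chrom, gene_midpoint(g), iv) |
            points_in_intervals(g$chrom, g$start, iv) |
            points_in_intervals(g$chrom, pmax(g$end - 1, g$start), iv),
      full = points_in_intervals(g$chrom, g$start, iv) &
             points_in_intervals(g$chrom, pmax(g$end - 1, g$start), iv)
    )
  }
  a_in <- in_ridge(genes_a, pairs$gene_id_a, regions_a)
  b_in <- in_ridge(genes_b, pairs$gene_id_b, regions_b)
  n_a <- sum(a_in)
  n_both <- sum(a_in & b_in)
  f_b <- mean(in_ridge(genes_b, genes_b$gene_id, regions_b))
  if (n_a == 0L) {
    return(list(n_pairs = nrow(pairs), n_a_in_ridge = 0L,
                n_both_in_ridge = 0L, percent_overlap = NA_real_,
                expected_fraction = f_b, chi_square = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  }
  pct <- 100 * n_both / n_a
  if (f_b <= 0 || f_b >= 1) {
    chi <- NA_real_; p <- NA_real_
  } else {
    test <- suppressWarnings(stats::chisq.test(
      c(n_both, n_a - n_both), p = c(f_b, 1 - f_b), correct = FALSE))
    chi <- unname(test$statistic); p <- test$p.value
  }
  list(n_pairs = nrow(pairs), n_a_in_ridge = n_a, n_both_in_ridge = n_both,
       percent_overlap = pct, expected_fraction = f_b,
       chi_square = chi, p_value = p, degenerate = FALSE)
}
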