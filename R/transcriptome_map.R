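# Ordering genes along chromosomes and smoothing their expression with a
# running median produces the transcriptome map that region calling and all
# track correlations operate on.

#' Running median with shrinking symmetric edge windows
#'
#' Replaces each value by the median of the `window` values centred on it.
#' Near the series ends, the largest odd window centred at the position that
#' still fits is used, so the first and last values are returned unchanged
#' and the output has the same length as the input. The interior is computed
#' by [stats::runmed()]; the edge rule replaces its end rules because the
#' shrinking symmetric window is deterministic and oracle-testable.
#'
#' @param values numeric vector, length >= 1.
#' @param window odd integer window size in genes.
#' @param edge_rule `"shrink"` (default, shrinking symmetric windows) or
#'   `"keep"` (leave the `(window-1)/2` edge values untouched, the classical
#'   end rule of [stats::runmed()]).
#' @return numeric vector of the same length as `values`.
#' @export
running_median <- function(values, window, edge_rule = c("shrink", "keep")) {
  edge_rule <- match.arg(edge_rule)
  if (length(values) == 0L) stop_fmt("running_median: empty series")
  if (length(window) != 1L || !is.finite(window) || window < 1 || !is_odd(window)) {
    stop_fmt("running_median: window must be an odd integer >= 1, got %s",
             paste(window, collapse = ","))
  }
  window <- as.integer(window)
  n <- length(values)
  if (window == 1L) return(as.numeric(values))
  k <- (window - 1L) %/% 2L
  shrink_at <- function(i) {
    ki <- min(k, i - 1L, n - i)
    stats::median(values[(i - ki):(i + ki)])
  }
  if (n >= window) {
    out <- as.numeric(stats::runmed(values, window, endrule = "keep"))
    if (edge_rule == "shrink") {
      edge <- c(seq_len(k), (n - k + 1L):n)
      out[edge] <- vapply(edge, shrink_at, numeric(1))
    }
  } else {
    # series shorter than the window: every position is an edge
    out <- if (edge_rule == "shrink") {
      vapply(seq_len(n), shrink_at, numeric(1))
    } else {
      as.numeric(values)
    }
  }
  out
}

#' Build a transcriptome map
#'
#' Orders genes along each chromosome by midpoint (ties broken by start, then
#' gene id), attaches each gene's expression value, and smooths the values per
#' chromosome with a running median counted in genes. Chromosomes carrying
#' fewer genes than `min_genes` are excluded with a warning: a window of
#' `window` genes cannot resolve regional structure there.
#'
#' @param genes gene table from [read_gene_table()].
#' @param expr an [expression_table()].
#' @param window odd running-median window in genes (default 39).
#' @param value_source `"median"` for the per-gene cross-tissue median
#'   (the combined map) or the name of a single tissue.
#' @param min_genes minimum genes per retained chromosome (default = `window`).
#' @param allow_empty keep going (returning a 0-row map) when no chromosome
#'   survives the minimum-size rule; used for per-strand maps where one strand
#'   may be empty.
#' @return a `transcriptome_map`: a data frame with columns `chrom`,
#'   `gene_id`, `midpoint`, `start`, `end`, `strand`, `raw`, `smoothed`,
#'   ordered by (chrom, midpoint), with attributes `window`, `label`,
#'   `n_dropped_no_expression` and `excluded_chromosomes`.
#' @export
build_map <- function(genes, expr, window = 39L,
                      value_source = "median", min_genes = window,
                      allow_empty = FALSE) {
  if (!is_odd(window) || window < 3L) {
    stop_fmt("build_map: window must be an odd integer >= 3, got %s", window)
  }
  if (identical(value_source, "median")) {
    vals <- expr$summary
    label <- "combined"
  } else {
    if (!value_source %in% expr$tissue_names) {
      stop_fmt("build_map: tissue '%s' not in expression table", value_source)
    }
    vals <- expr$values[, value_source]
    label <- paste0("tissue:", value_source)
  }
  names(vals) <- expr$gene_ids

  keep <- genes$gene_id %in% expr$gene_ids
  n_dropped <- sum(!keep)
  g <- genes[keep, , drop = FALSE]

  tab <- table(g$chrom)
  excluded <- names(tab)[tab < min_genes]
  if (length(excluded) > 0L) {
    warn_fmt("excluding %d chromosome(s) with fewer than %d genes: %s",
             length(excluded), min_genes, paste(excluded, collapse = ", "))
    g <- g[!g$chrom %in% excluded, , drop = FALSE]
  }
  if (nrow(g) == 0L && !allow_empty) {
    stop_fmt("build_map: no chromosome retains at least %d genes", min_genes)
  }

  g <- g[gene_order(g), , drop = FALSE]
  map <- data.frame(
    chrom = g$chrom, gene_id = g$gene_id, midpoint = gene_midpoint(g),
    start = g$start, end = g$end, strand = g$strand,
    raw = unname(vals[g$gene_id]), smoothed = rep(NA_real_, nrow(g)),
    stringsAsFactors = FALSE
  )
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    map$smoothed[sel] <- running_median(map$raw[sel], window)
  }
  rownames(map) <- NULL
  structure(map, class = c("transcriptome_map", "data.frame"),
            window = as.integer(window), label = label,
            n_dropped_no_expression = n_dropped,
            excluded_chromosomes = excluded)
}

#' @export
print.transcriptome_map <- function(x, ...) {
  cat(sprintf("transcriptome_map [%s]: %d genes on %d chromosome(s), running-median window %d\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom)), attr(x, "window")))
  invisible(x)
}

#' Build per-strand transcriptome maps
#'
#' Splits the genes by strand and builds one map per strand, by default with
#' a window of 19 genes (roughly half the combined-map window, so each strand
#' map integrates a comparable genomic span). A strand with no retained
#' chromosome yields an empty map rather than an error.
#'
#' @inheritParams build_map
#' @param window odd window per strand (default 19).
#' @return list with elements `plus` and `minus`, each a `transcriptome_map`.
#' @export
build_strand_maps <- function(genes, expr, window = 19L,
                              value_source = "median", min_genes = window) {
  maps <- lapply(c("+", "-"), function(s) {
    m <- build_map(genes[genes$strand == s, , drop = FALSE], expr,
                   window = window, value_source = value_source,
                   min_genes = min_genes, allow_empty = TRUE)
    attr(m, "label") <- paste0("strand:", s)
    m
  })
  names(maps) <- c("plus", "minus")
  maps
}

#' Per-chromosome summaries of a transcriptome map
#'
#' For each retained chromosome: gene count, analyzed length (end of the last
#' gene minus start of the first gene) and the median of the per-gene raw
#' values. The median-expression versus chromosome-length relationship is the
#' classic contrast between short, gene-dense, highly expressed chromosomes
#' and long, sparse ones.
#'
#' @param map a `transcriptome_map`.
#' @return data frame with columns `chrom`, `length`, `n_genes`,
#'   `median_expression`.
#' @export
chromosome_summaries <- function(map) {
  chroms <- unique(map$chrom)
  out <- lapply(chroms, function(ch) {
    x <- map[map$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch,
               length = max(x$end) - min(x$start),
               n_genes = nrow(x),
               median_expression = stats::median(x$raw),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Total analyzed genome length of a map
#'
#' Sum over retained chromosomes of (last gene end - first gene start); the
#' denominator used for region coverage fractions.
#'
#' @param map a `transcriptome_map`.
#' @return length in base pairs.
#' @export
analyzed_genome_length <- function(map) {
  sum(chromosome_summaries(map)$length)
}

#' Write a transcriptome map as TSV
#' @param map a `transcriptome_map`.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  hdr <- sprintf("# window=%d label=%s", attr(map, "window"), attr(map, "label"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(map), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcriptome map written by [write_map()]
#' @param path path to the TSV.
#' @return a `transcriptome_map`.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop_fmt("map file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  window <- as.integer(sub(".*window=(\\d+).*", "\\1", hdr))
  label <- sub(".*label=(\\S+).*", "\\1", hdr)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  structure(df, class = c("transcriptome_map", "data.frame"),
            window = window, label = label,
            n_dropped_no_expression = NA_integer_,
            excluded_chromosomes = character(0))
}
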