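# Readers and writers for the tables the pipeline touches, plus the
# coordinate-convention normalisation applied on the way in.
#
# Internal convention: 0-based half-open throughout. TSV and GFF-lite inputs
# are treated as 1-based inclusive (Ensembl convention) and shifted on read;
# BED is already 0-based half-open and passes through unchanged.

#' Read a gene annotation table
#'
#' Reads per-gene location, strand, GC fraction and intron structure from one
#' of three dialects and normalises coordinates to the internal 0-based
#' half-open convention. Records are returned sorted by (chrom, start).
#'
#' Dialects:
#' \describe{
#'   \item{`tsv`}{columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'     `gc_fraction`, `intron_lengths`; coordinates 1-based inclusive.
#'     `intron_lengths` holds one transcript per semicolon-separated field,
#'     comma-separated intron lengths within a transcript; empty allowed.}
#'   \item{`bed`}{BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`),
#'     0-based half-open; GC and introns unavailable.}
#'   \item{`gff-lite`}{9-column GFF with the gene id in an `ID=` attribute;
#'     coordinates 1-based inclusive.}
#' }
#'
#' @param path path to the file.
#' @param dialect one of `"tsv"`, `"bed"`, `"gff-lite"`.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (internal coordinates), `strand`, `gc_fraction` (`NA` when absent) and a
#'   list column `introns` (one numeric vector of intron lengths per
#'   transcript).
#' @export
read_gene_table <- function(path, dialect = c("tsv", "bed", "gff-lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("gene table not found: %s", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    required <- c("gene_id", "chrom", "start", "end", "strand")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop_fmt("gene table %s is missing required column(s): %s",
               path, paste(missing, collapse = ", "))
    }
    gc <- if ("gc_fraction" %in% names(df)) {
      suppressWarnings(as.numeric(df$gc_fraction))
    } else rep(NA_real_, nrow(df))
    introns <- if ("intron_lengths" %in% names(df)) {
      lapply(df$intron_lengths, parse_intron_field)
    } else rep(list(list()), nrow(df))
    out <- new_gene_table(
      gene_id = df$gene_id, chrom = df$chrom,
      start = as.numeric(df$start), end = as.numeric(df$end),
      strand = df$strand, gc_fraction = gc, introns = introns,
      one_based = TRUE, path = path
    )
  } else if (dialect == "bed") {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) < 6L) {
      stop_fmt("BED gene table %s needs 6 columns (chrom start end name score strand), found %d",
               path, ncol(df))
    }
    out <- new_gene_table(
      gene_id = df[[4L]], chrom = df[[1L]],
      start = as.numeric(df[[2L]]), end = as.numeric(df[[3L]]),
      strand = df[[6L]], gc_fraction = rep(NA_real_, nrow(df)),
      introns = rep(list(list()), nrow(df)),
      one_based = FALSE, path = path
    )
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            comment.char = "#", colClasses = "character")
    if (ncol(df) < 9L) {
      stop_fmt("GFF-lite gene table %s needs 9 columns, found %d", path, ncol(df))
    }
    ids <- sub(".*ID=([^;]+).*", "\\1", df[[9L]])
    out <- new_gene_table(
      gene_id = ids, chrom = df[[1L]],
      start = as.numeric(df[[4L]]), end = as.numeric(df[[5L]]),
      strand = df[[7L]], gc_fraction = rep(NA_real_, nrow(df)),
      introns = rep(list(list()), nrow(df)),
      one_based = TRUE, path = path
    )
  }
  out
}

# Shared construction/validation path for all dialects. Validation runs on the
# raw external coordinates (start < end strictly), then the 1-based inclusive
# dialects are shifted to 0-based half-open.
new_gene_table <- function(gene_id, chrom, start, end, strand, gc_fraction,
                           introns, one_based, path = "<memory>") {
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0L) {
    stop_fmt("%s: non-numeric coordinates at record %d", path, bad[1L])
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop_fmt("%s: start >= end at record %d (gene %s)",
             path, bad[1L], gene_id[bad[1L]])
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop_fmt("%s: invalid strand '%s' at record %d", path, strand[bad[1L]], bad[1L])
  }
  ok_gc <- is.na(gc_fraction) | (gc_fraction >= 0 & gc_fraction <= 1)
  if (!all(ok_gc)) {
    stop_fmt("%s: gc_fraction outside [0,1] at record %d", path, which(!ok_gc)[1L])
  }
  for (i in seq_along(introns)) {
    lens <- unlist(introns[[i]])
    if (length(lens) > 0L && any(!is.finite(lens) | lens <= 0)) {
      stop_fmt("%s: non-positive intron length at record %d (gene %s)",
               path, i, gene_id[i])
    }
  }
  if (one_based) start <- start - 1
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                   strand = strand, gc_fraction = gc_fraction,
                   stringsAsFactors = FALSE)
  df$introns <- introns
  df <- df[order(df$chrom, df$start, df$gene_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# "100,200;300" -> list(c(100, 200), 300); "" -> list()
parse_intron_field <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1L]], function(tr) {
    if (!nzchar(tr)) return(numeric(0))
    as.numeric(strsplit(tr, ",", fixed = TRUE)[[1L]])
  })
}

format_intron_field <- function(introns) {
  vapply(introns, function(trs) {
    paste(vapply(trs, function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                                        collapse = ","),
                 character(1)), collapse = ";")
  }, character(1))
}

#' Write a gene table to the package's TSV dialect
#'
#' Inverse of `read_gene_table(dialect = "tsv")`: internal 0-based half-open
#' coordinates are converted back to 1-based inclusive on the way out, so a
#' write/read round trip is the identity.
#'
#' @param genes a gene table.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = format(genes$start + 1, scientific = FALSE, trim = TRUE),
    end = format(genes$end, scientific = FALSE, trim = TRUE),
    strand = genes$strand,
    gc_fraction = genes$gc_fraction,
    intron_lengths = format_intron_field(genes$introns),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- expression --------------------------------------------------------------

#' Construct an expression table
#'
#' Bundles a genes-by-tissues matrix of log2 expression values with the
#' per-gene cross-tissue median used as each gene's summary expression.
#'
#' @param values numeric matrix, rows = genes (rownames are gene ids),
#'   columns = tissues (colnames are tissue names).
#' @return an object of class `expression_table` with elements `gene_ids`,
#'   `tissue_names`, `values` and `summary` (the per-gene median).
#' @export
expression_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_fmt("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fmt("expression matrix needs gene ids as rownames and tissue names as colnames")
  }
  dup <- duplicated(rownames(values))
  if (any(dup)) {
    stop_fmt("duplicate gene id in expression table: %s", rownames(values)[which(dup)[1L]])
  }
  if (any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_fmt("non-finite expression value at gene %s, tissue %s",
             rownames(values)[idx[1L]], colnames(values)[idx[2L]])
  }
  structure(
    list(gene_ids = rownames(values),
         tissue_names = colnames(values),
         values = values,
         summary = apply(values, 1L, stats::median)),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d tissues (log2), summary = cross-tissue median\n",
              length(x$gene_ids), length(x$tissue_names)))
  invisible(x)
}

#' Read a gene-by-tissue expression TSV
#'
#' Expects a header row with `gene_id` followed by one column per tissue and
#' one row per gene; computes the cross-tissue median summary per gene.
#'
#' @param path path to the TSV.
#' @return an [expression_table()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_fmt("expression table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop_fmt("%s: need gene_id plus at least one tissue column", path)
  ids <- df[[1L]]
  dup <- duplicated(ids)
  if (any(dup)) stop_fmt("%s: duplicate gene id '%s'", path, ids[which(dup)[1L]])
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1L]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) | is.na(df[[j]]))
    if (length(bad) > 0L) {
      stop_fmt("%s: non-numeric value at row %d, column '%s'",
               path, bad[1L], names(df)[j])
    }
    m[, j - 1L] <- v
  }
  expression_table(m)
}

#' Write an expression table as TSV
#' @param expr an [expression_table()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level expression to gene level
#'
#' Averages (arithmetic mean) the probes mapping to each gene, per tissue.
#' Probes with no mapping, or mapping to more than one gene, are dropped and
#' counted in the report; exact duplicate rows in the probe map are treated
#' as an annotation error.
#'
#' @param probe_values numeric matrix, probes x tissues, rownames = probe ids.
#' @param probe_map data frame with columns `probe_id`, `gene_id`.
#' @return a list with `table` (an [expression_table()]) and `report`
#'   (counts of dropped probes and the mean within-gene between-probe
#'   variance, a flag for annotation quality).
#' @export
collapse_probes <- function(probe_values, probe_map) {
  if (!is.matrix(probe_values) || is.null(rownames(probe_values))) {
    stop_fmt("probe_values must be a matrix with probe ids as rownames")
  }
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop_fmt("probe_map needs columns probe_id and gene_id")
  }
  dup_row <- duplicated(probe_map[, c("probe_id", "gene_id")])
  if (any(dup_row)) {
    stop_fmt("duplicate probe-to-gene row for probe '%s': annotation error",
             probe_map$probe_id[which(dup_row)[1L]])
  }
  multi <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  map <- probe_map[!probe_map$probe_id %in% multi, , drop = FALSE]
  probes <- rownames(probe_values)
  n_multi <- sum(probes %in% multi)
  mapped <- probes[probes %in% map$probe_id]
  n_unmapped <- length(probes) - length(mapped) - n_multi
  if (length(mapped) == 0L) {
    stop_fmt("no probe in the expression matrix maps uniquely to a gene")
  }
  gene_of <- map$gene_id[match(mapped, map$probe_id)]
  vals <- probe_values[mapped, , drop = FALSE]
  genes <- sort(unique(gene_of))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(vals),
                dimnames = list(genes, colnames(vals)))
  within_var <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    rows <- vals[gene_of == genes[i], , drop = FALSE]
    out[i, ] <- colMeans(rows)
    if (nrow(rows) > 1L) within_var[i] <- mean(apply(rows, 2L, stats::var))
  }
  list(
    table = expression_table(out),
    report = list(
      n_probes = length(probes),
      n_probes_used = length(mapped),
      n_dropped_unmapped = n_unmapped,
      n_dropped_multi_gene = n_multi,
      n_genes = length(genes),
      mean_within_gene_variance = if (all(is.na(within_var))) NA_real_
                                  else mean(within_var, na.rm = TRUE)
    )
  )
}

# --- regions (BED6) ----------------------------------------------------------

#' Write called regions as BED6
#'
#' One line per region: chrom, start, end (0-based half-open), name
#' (`RIDGE` or `antiRIDGE`), score = mean smoothed value, strand `.`.
#'
#' @param regions a region set from [call_regions()] (or any data frame with
#'   columns `chrom`, `start`, `end`, `kind`, `mean_smoothed`).
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t.",
                   regions$chrom,
                   format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   regions$kind,
                   format(regions$mean_smoothed, digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 region file written by [write_regions()]
#' @param path path to the BED file.
#' @return data frame with columns `chrom`, `start`, `end`, `kind`,
#'   `mean_smoothed`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_fmt("region file not found: %s", path)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0),
                      mean_smoothed = numeric(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) == 0L) return(empty)
  data.frame(chrom = df[[1L]], start = as.numeric(df[[2L]]),
             end = as.numeric(df[[3L]]), kind = df[[4L]],
             mean_smoothed = as.numeric(df[[5L]]), stringsAsFactors = FALSE)
}

# --- synteny blocks and homolog pairs ---------------------------------------

#' Read a synteny block table
#'
#' TSV columns: `block_id`, `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#' `start_b`, `end_b`, `orientation`. Coordinates are 1-based inclusive on
#' both genomes and converted to the internal convention.
#'
#' @param path path to the TSV.
#' @return data frame of validated blocks in internal coordinates.
#' @export
read_synteny <- function(path) {
  if (!file.exists(path)) stop_fmt("synteny table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  required <- c("block_id", "chrom_a", "start_a", "end_a",
                "chrom_b", "start_b", "end_b", "orientation")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_fmt("synteny table %s is missing column(s): %s",
             path, paste(missing, collapse = ", "))
  }
  out <- data.frame(
    block_id = df$block_id,
    chrom_a = df$chrom_a, start_a = as.numeric(df$start_a) - 1,
    end_a = as.numeric(df$end_a),
    chrom_b = df$chrom_b, start_b = as.numeric(df$start_b) - 1,
    end_b = as.numeric(df$end_b),
    orientation = df$orientation, stringsAsFactors = FALSE
  )
  validate_synteny(out, path)
}

validate_synteny <- function(blocks, path = "<memory>") {
  bad <- which(blocks$start_a >= blocks$end_a | blocks$start_b >= blocks$end_b)
  if (length(bad) > 0L) {
    stop_fmt("%s: block %s has start >= end", path, blocks$block_id[bad[1L]])
  }
  bad <- which(!blocks$orientation %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop_fmt("%s: block %s has invalid orientation '%s'",
             path, blocks$block_id[bad[1L]], blocks$orientation[bad[1L]])
  }
  blocks
}

#' Write a synteny block table (inverse of [read_synteny()])
#' @param blocks validated block data frame.
#' @param path output path.
#' @export
write_synteny <- function(blocks, path) {
  out <- blocks
  out$start_a <- format(out$start_a + 1, scientific = FALSE, trim = TRUE)
  out$end_a <- format(out$end_a, scientific = FALSE, trim = TRUE)
  out$start_b <- format(out$start_b + 1, scientific = FALSE, trim = TRUE)
  out$end_b <- format(out$end_b, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 1-to-1 homolog pair table
#'
#' TSV with columns `gene_id_a`, `gene_id_b`; each id may appear in at most
#' one pair.
#'
#' @param path path to the TSV.
#' @return data frame of pairs.
#' @export
read_homologs <- function(path) {
  if (!file.exists(path)) stop_fmt("homolog table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("gene_id_a", "gene_id_b") %in% names(df))) {
    stop_fmt("homolog table %s needs columns gene_id_a and gene_id_b", path)
  }
  if (anyDuplicated(df$gene_id_a) || anyDuplicated(df$gene_id_b)) {
    stop_fmt("%s: homolog pairs must be 1-to-1 (duplicated gene id found)", path)
  }
  df[, c("gene_id_a", "gene_id_b")]
}

#' Write a homolog pair table
#' @param pairs data frame with columns `gene_id_a`, `gene_id_b`.
#' @param path output path.
#' @export
write_homologs <- function(pairs, path) {
  utils::write.table(pairs[, c("gene_id_a", "gene_id_b")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
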