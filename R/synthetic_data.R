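# Synthetic genomes with planted expression domains. The generator emulates
# the statistical structure the analysis assumes -- spatially clustered
# high/low expression covering ~10% of the genome each, annotation features
# coupled to the expression regime, and synteny breakpoints biased into the
# high-expression blocks -- with fully known ground truth, so every stage of
# the pipeline can be scored against planted truth.

#' Simulation configuration
#'
#' Defaults describe a compact genome (~5,000 genes on 10 chromosomes, 8
#' tissues) that preserves the structure of a real bird-genome study at a
#' size convenient for testing; `paper_scale = TRUE` switches to ~11,400
#' genes on 27 chromosomes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_range min/max chromosome length in bp; lengths are
#'   drawn log-uniformly so the genome mixes long and short chromosomes.
#' @param genes_per_mb background gene density.
#' @param n_tissues number of tissues (default 8).
#' @param baseline background log2 expression level (default 7, the middle of
#'   a typical log2 microarray intensity range).
#' @param planted_high_fraction,planted_low_fraction genome fraction covered
#'   by planted high/low blocks (default 0.10 each).
#' @param high_effect,low_effect log2 shift inside high/low blocks
#'   (defaults +0.8 / -0.8).
#' @param noise_sd per-gene noise sd in log2 units (default 0.5).
#' @param tissue_sd per-gene-per-tissue noise sd (default 0.3).
#' @param feature_coupling list of regime effects on annotation features in
#'   high blocks (inverted in low blocks): `gc_shift` added to mean GC,
#'   `length_factor` multiplying gene length, `intron_factor` multiplying
#'   intron length, `density_factor` multiplying gene density.
#' @param block_target_genes expected genes per planted high block; sets the
#'   planted block length (default 60, comfortably above the caller's
#'   minimum run).
#' @param min_gap_genes minimum gap between planted blocks, in expected
#'   genes (default 39, one smoothing window, keeping planted blocks
#'   unambiguous for recovery scoring).
#' @param n_breaks number of synteny cut points across the genome
#'   (default 200).
#' @param breakpoint_ridge_bias relative cut rate inside high blocks
#'   (default 3).
#' @param block_trim_frac each synteny block is trimmed at both ends by a
#'   uniform fraction up to this of the segment length, so adjacent block
#'   ends do not coincide (default 0.25).
#' @param seed master seed; each component (positions, expression, synteny)
#'   draws from its own derived stream.
#' @param paper_scale preset emitting ~11,400 genes on 27 chromosomes.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_chromosomes = 10L,
                              chrom_length_range = c(3e7, 1.5e8),
                              genes_per_mb = 6.5,
                              n_tissues = 8L,
                              baseline = 7.0,
                              planted_high_fraction = 0.10,
                              planted_low_fraction = 0.10,
                              high_effect = 0.8,
                              low_effect = -0.8,
                              noise_sd = 0.5,
                              tissue_sd = 0.3,
                              feature_coupling = list(gc_shift = 0.05,
                                                      length_factor = 0.6,
                                                      intron_factor = 0.6,
                                                      density_factor = 1.5),
                              block_target_genes = 60L,
                              min_gap_genes = 39L,
                              n_breaks = 200L,
                              breakpoint_ridge_bias = 3.0,
                              block_trim_frac = 0.25,
                              seed = 1L,
                              paper_scale = FALSE) {
  if (paper_scale) {
    n_chromosomes <- 27L
    chrom_length_range <- c(5e6, 2e8)
    genes_per_mb <- 11
  }
  stopifnot(planted_high_fraction > 0, planted_high_fraction < 1,
            planted_low_fraction > 0, planted_low_fraction < 1,
            planted_high_fraction + planted_low_fraction < 1,
            noise_sd >= 0, tissue_sd >= 0, n_chromosomes >= 1,
            genes_per_mb > 0)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_range = chrom_length_range,
    genes_per_mb = genes_per_mb, n_tissues = as.integer(n_tissues),
    baseline = baseline,
    planted_high_fraction = planted_high_fraction,
    planted_low_fraction = planted_low_fraction,
    high_effect = high_effect, low_effect = low_effect,
    noise_sd = noise_sd, tissue_sd = tissue_sd,
    feature_coupling = feature_coupling,
    block_target_genes = as.integer(block_target_genes),
    min_gap_genes = as.integer(min_gap_genes),
    n_breaks = as.integer(n_breaks),
    breakpoint_ridge_bias = breakpoint_ridge_bias,
    block_trim_frac = block_trim_frac,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# regime multiplier helpers: high blocks apply the coupling factor, low
# blocks its reciprocal, background none.
regime_factor <- function(regime, factor) {
  ifelse(regime == "high", factor, ifelse(regime == "low", 1 / factor, 1))
}

# Rejection-sample non-overlapping block placements on [0, L] with a minimum
# gap; returns a data frame of (start, end) or fewer rows than asked when the
# chromosome is too crowded.
place_blocks <- function(L, lengths, gap_bp, max_tries = 2000L) {
  placed <- data.frame(start = numeric(0), end = numeric(0))
  for (len in lengths) {
    if (len >= L) next
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- stats::runif(1, 0, L - len)
      e <- s + len
      if (nrow(placed) == 0L ||
          all(s >= placed$end + gap_bp | e <= placed$start - gap_bp)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        ok <- TRUE
        break
      }
    }
  }
  placed[order(placed$start), , drop = FALSE]
}

#' Simulate a genome with planted expression domains
#'
#' Chromosome lengths are log-uniform over `chrom_length_range`. Planted
#' high and low blocks are sized to carry `block_target_genes` expected
#' genes, allocated per chromosome in proportion to length so each regime
#' covers its target genome fraction, and placed by rejection sampling with
#' a minimum gap of one smoothing window of expected genes. Gene positions
#' follow a piecewise-constant Poisson process whose rate is multiplied by
#' the density coupling inside high blocks (and divided inside low blocks);
#' gene and intron lengths are log-normal with regime-dependent medians, and
#' GC is beta-distributed with a regime shift of the mean.
#'
#' @param config a [simulation_config()].
#' @return list with `genes` (a gene table), `truth` (planted `intervals`
#'   with regimes, the per-gene `gene_regime` labels, and `chrom_lengths`)
#'   -- everything needed to score recovery.
#' @export
simulate_genome <- function(config = simulation_config()) {
  fc <- config$feature_coupling
  with_seed(mix_seed(config$seed, 1L), {
    lens <- exp(stats::runif(config$n_chromosomes,
                             log(config$chrom_length_range[1L]),
                             log(config$chrom_length_range[2L])))
    if (all(lens * config$genes_per_mb / 1e6 < 39)) {
      stop_fmt("simulate_genome: expected gene count below one smoothing window on every chromosome")
    }
    chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    gap_bp <- config$min_gap_genes / config$genes_per_mb * 1e6

    hi_len_unit <- config$block_target_genes /
      (config$genes_per_mb * fc$density_factor) * 1e6
    lo_len_unit <- config$block_target_genes * fc$density_factor /
      config$genes_per_mb * 1e6

    intervals <- list()
    rows <- list()
    for (i in seq_along(chroms)) {
      L <- lens[i]
      n_hi <- max(1L, round(L * config$planted_high_fraction / hi_len_unit))
      n_lo <- max(1L, round(L * config$planted_low_fraction / lo_len_unit))
      hi_lens <- rep(L * config$planted_high_fraction / n_hi, n_hi)
      lo_lens <- rep(L * config$planted_low_fraction / n_lo, n_lo)
      # place the larger (low) blocks first: easier packing
      all_lens <- c(lo_lens, hi_lens)
      all_kind <- c(rep("low", n_lo), rep("high", n_hi))
      ord <- order(-all_lens)
      placed <- place_blocks(L, all_lens[ord], gap_bp)
      kinds <- all_kind[ord][seq_len(nrow(placed))]
      # place_blocks may drop blocks on crowded chromosomes; re-sort spatially
      ord2 <- order(placed$start)
      iv <- data.frame(chrom = chroms[i],
                       start = round(placed$start[ord2]),
                       end = round(placed$end[ord2]),
                       regime = kinds[ord2], stringsAsFactors = FALSE)
      intervals[[i]] <- iv

      # piecewise segments: background between planted blocks
      bounds <- c(0, as.vector(rbind(iv$start, iv$end)), L)
      seg_regime <- c(rbind(rep("bg", nrow(iv) + 1L),
                            c(iv$regime, "bg")))[seq_len(2L * nrow(iv) + 1L)]
      for (s in seq_len(length(bounds) - 1L)) {
        s0 <- bounds[s]; s1 <- bounds[s + 1L]
        if (s1 <= s0) next
        regime <- seg_regime[s]
        rate <- config$genes_per_mb / 1e6 *
          regime_factor(regime, fc$density_factor)
        n <- stats::rpois(1L, (s1 - s0) * rate)
        if (n == 0L) next
        start <- round(sort(stats::runif(n, s0, s1)))
        glen <- round(stats::rlnorm(n,
          meanlog = log(2e4 * regime_factor(regime, fc$length_factor)),
          sdlog = 0.8)) + 200
        gc_mean <- 0.42 +
          ifelse(regime == "high", fc$gc_shift,
                 ifelse(regime == "low", -fc$gc_shift, 0))
        conc <- 60
        gc <- stats::rbeta(n, gc_mean * conc, (1 - gc_mean) * conc)
        intron_med <- 1000 * regime_factor(regime, fc$intron_factor)
        introns <- lapply(seq_len(n), function(j) {
          if (stats::runif(1) < 0.10) return(list())  # intronless gene
          n_tr <- 1L + stats::rbinom(1L, 1L, 0.4)
          lapply(seq_len(n_tr), function(t) {
            k <- 1L + stats::rpois(1L, 6)
            pmax(20, round(stats::rlnorm(k, log(intron_med), 1.3)))
          })
        })
        rows[[length(rows) + 1L]] <- list(
          chrom = rep(chroms[i], n), start = start, end = start + glen,
          strand = sample(c("+", "-"), n, replace = TRUE),
          gc = gc, introns = introns
        )
      }
    }
    intervals <- do.call(rbind, intervals)
    genes <- new_gene_table(
      gene_id = sprintf("tmp%06d", seq_along(unlist(lapply(rows, `[[`, "start")))),
      chrom = unlist(lapply(rows, `[[`, "chrom")),
      start = unlist(lapply(rows, `[[`, "start")),
      end = unlist(lapply(rows, `[[`, "end")),
      strand = unlist(lapply(rows, `[[`, "strand")),
      gc_fraction = round(unlist(lapply(rows, `[[`, "gc")), 4),
      introns = do.call(c, lapply(rows, `[[`, "introns")),
      one_based = FALSE
    )
    # stable ids in genomic order
    genes$gene_id <- sprintf("gA%05d", seq_len(nrow(genes)))
    regime <- rep("bg", nrow(genes))
    mids <- gene_midpoint(genes)
    for (r in c("high", "low")) {
      iv <- intervals[intervals$regime == r, , drop = FALSE]
      names(iv)[names(iv) == "regime"] <- "kind"
      regime[points_in_intervals(genes$chrom, mids, iv)] <- r
    }
    list(genes = genes,
         truth = list(intervals = intervals,
                      gene_regime = stats::setNames(regime, genes$gene_id),
                      chrom_lengths = stats::setNames(round(lens), chroms)))
  })
}

#' Simulate log2 expression over tissues
#'
#' `value(g, t) = baseline + regime shift + per-gene noise + per-tissue
#' noise`; the per-gene noise is shared across tissues, so tissue maps stay
#' highly correlated with the combined map, as observed in real tissue
#' panels.
#'
#' @param genes gene table from [simulate_genome()].
#' @param truth matching ground truth.
#' @param config the [simulation_config()].
#' @return an [expression_table()].
#' @export
simulate_expression <- function(genes, truth, config = simulation_config()) {
  with_seed(mix_seed(config$seed, 2L), {
    n <- nrow(genes)
    regime <- truth$gene_regime[genes$gene_id]
    shift <- ifelse(regime == "high", config$high_effect,
                    ifelse(regime == "low", config$low_effect, 0))
    gene_eff <- stats::rnorm(n, 0, config$noise_sd)
    tissue_eff <- matrix(stats::rnorm(n * config$n_tissues, 0, config$tissue_sd),
                         nrow = n)
    vals <- config$baseline + shift + gene_eff + tissue_eff
    tissues <- c("brain", "bursa", "heart", "kidney", "liver", "lung",
                 "muscle", "spleen", "thymus", "ovary", "testis", "skin")
    tissue_names <- if (config$n_tissues <= length(tissues)) {
      tissues[seq_len(config$n_tissues)]
    } else sprintf("tissue_%02d", seq_len(config$n_tissues))
    dimnames(vals) <- list(genes$gene_id, tissue_names)
    expression_table(round(vals, 6))
  })
}

#' Simulate a rearranged second genome with synteny blocks
#'
#' Genome B is genome A cut at `n_breaks` points placed with rate
#' `breakpoint_ridge_bias` times higher inside planted high blocks, with the
#' resulting segments shuffled across renamed chromosomes (random
#' orientation flips). Every A gene maps to exactly one B copy (the homolog
#' pairs); recorded synteny blocks are the segments trimmed at both ends by
#' a random fraction, mimicking blocks that do not abut, so the two
#' breakpoints flanking a cut fall at distinct positions.
#'
#' @param genes_a genome-A gene table.
#' @param truth_a genome-A ground truth.
#' @param config the [simulation_config()].
#' @return list with `blocks` (synteny table), `genes_b` (gene table),
#'   `truth_b` (planted intervals mapped to B coordinates), `homologs`
#'   (1-to-1 pair table), and `cuts` (the planted cut positions on A).
#' @export
simulate_synteny <- function(genes_a, truth_a, config = simulation_config()) {
  with_seed(mix_seed(config$seed, 3L), {
    chroms <- names(truth_a$chrom_lengths)
    lens <- as.numeric(truth_a$chrom_lengths)
    hi <- truth_a$intervals[truth_a$intervals$regime == "high", , drop = FALSE]
    names(hi)[names(hi) == "regime"] <- "kind"
    bias <- config$breakpoint_ridge_bias

    # biased cut placement by rejection sampling
    cuts <- data.frame(chrom = character(0), pos = numeric(0))
    accept_max <- max(bias, 1)
    while (nrow(cuts) < config$n_breaks) {
      m <- 4L * (config$n_breaks - nrow(cuts))
      ch <- sample(chroms, m, replace = TRUE, prob = lens)
      pos <- stats::runif(m, 0, lens[match(ch, chroms)])
      w <- ifelse(points_in_intervals(ch, pos, hi), bias, 1) / accept_max
      keep <- stats::runif(m) < w
      cuts <- rbind(cuts, data.frame(chrom = ch[keep], pos = round(pos[keep])))
    }
    cuts <- cuts[seq_len(config$n_breaks), , drop = FALSE]

    # segments per chromosome
    segs <- list()
    for (i in seq_along(chroms)) {
      b <- sort(unique(c(0, cuts$pos[cuts$chrom == chroms[i]], lens[i])))
      for (s in seq_len(length(b) - 1L)) {
        if (b[s + 1L] > b[s]) {
          segs[[length(segs) + 1L]] <- list(chrom_a = chroms[i],
                                            a0 = b[s], a1 = b[s + 1L])
        }
      }
    }
    if (length(segs) < 2L) stop_fmt("simulate_synteny: fewer than 2 segments")

    # shuffle segments into B chromosomes with spacers
    perm <- sample(length(segs))
    n_chr_b <- length(chroms)
    chrom_b_names <- sprintf("chrB%02d", seq_len(n_chr_b))
    assign_chr <- rep(seq_len(n_chr_b), length.out = length(segs))
    offset <- stats::setNames(rep(0, n_chr_b), chrom_b_names)
    gap <- 1e6
    for (j in seq_along(perm)) {
      s <- segs[[perm[j]]]
      cb <- chrom_b_names[assign_chr[j]]
      seg_len <- s$a1 - s$a0
      segs[[perm[j]]]$chrom_b <- cb
      segs[[perm[j]]]$b0 <- offset[cb]
      segs[[perm[j]]]$b1 <- offset[cb] + seg_len
      segs[[perm[j]]]$orientation <- sample(c("+", "-"), 1L)
      offset[cb] <- offset[cb] + seg_len + gap
    }

    seg_df <- do.call(rbind, lapply(segs, function(s) {
      data.frame(chrom_a = s$chrom_a, a0 = s$a0, a1 = s$a1,
                 chrom_b = s$chrom_b, b0 = s$b0, b1 = s$b1,
                 orientation = s$orientation, stringsAsFactors = FALSE)
    }))

    map_point <- function(chrom, pos) {
      idx <- rep(NA_integer_, length(pos))
      for (s in seq_len(nrow(seg_df))) {
        sel <- chrom == seg_df$chrom_a[s] & pos >= seg_df$a0[s] &
          pos < seg_df$a1[s]
        idx[sel & is.na(idx)] <- s
      }
      # positions at/after the last segment end (possible for genes running
      # past the simulated chromosome length) fall into the final segment
      for (s in seq_len(nrow(seg_df))) {
        sel <- is.na(idx) & chrom == seg_df$chrom_a[s] & pos >= seg_df$a1[s]
        last <- tapply(seq_len(nrow(seg_df)), seg_df$chrom_a, max)
        sel <- sel & s == last[chrom]
        idx[sel] <- s
      }
      fwd <- seg_df$orientation[idx] == "+"
      data.frame(
        seg = idx,
        chrom = seg_df$chrom_b[idx],
        pos = ifelse(fwd, seg_df$b0[idx] + (pos - seg_df$a0[idx]),
                     seg_df$b0[idx] + (seg_df$a1[idx] - pos))
      )
    }

    # homolog copies of every A gene
    mids <- gene_midpoint(genes_a)
    mp <- map_point(genes_a$chrom, pmin(mids, lens[match(genes_a$chrom, chroms)] - 1))
    glen <- genes_a$end - genes_a$start
    start_b <- pmax(0, round(mp$pos - glen / 2))
    flip <- seg_df$orientation[mp$seg] == "-"
    strand_b <- ifelse(flip,
                       ifelse(genes_a$strand == "+", "-", "+"),
                       genes_a$strand)
    ids_b <- sub("^gA", "gB", genes_a$gene_id)
    genes_b <- new_gene_table(
      gene_id = ids_b, chrom = mp$chrom, start = start_b,
      end = start_b + glen, strand = strand_b,
      gc_fraction = genes_a$gc_fraction, introns = genes_a$introns,
      one_based = FALSE
    )
    homologs <- data.frame(gene_id_a = genes_a$gene_id, gene_id_b = ids_b,
                           stringsAsFactors = FALSE)

    # planted intervals carried to B coordinates (split at cuts)
    tb <- list()
    iv <- truth_a$intervals
    for (r in seq_len(nrow(iv))) {
      for (s in seq_len(nrow(seg_df))) {
        if (seg_df$chrom_a[s] != iv$chrom[r]) next
        s0 <- max(iv$start[r], seg_df$a0[s])
        s1 <- min(iv$end[r], seg_df$a1[s])
        if (s1 <= s0) next
        if (seg_df$orientation[s] == "+") {
          b_lo <- seg_df$b0[s] + (s0 - seg_df$a0[s])
          b_hi <- seg_df$b0[s] + (s1 - seg_df$a0[s])
        } else {
          b_lo <- seg_df$b0[s] + (seg_df$a1[s] - s1)
          b_hi <- seg_df$b0[s] + (seg_df$a1[s] - s0)
        }
        tb[[length(tb) + 1L]] <- data.frame(
          chrom = seg_df$chrom_b[s], start = b_lo, end = b_hi,
          regime = iv$regime[r], stringsAsFactors = FALSE)
      }
    }
    truth_b <- list(intervals = do.call(rbind, tb))

    # recorded blocks: segments trimmed at both ends
    t1 <- stats::runif(nrow(seg_df), 0, config$block_trim_frac)
    t2 <- stats::runif(nrow(seg_df), 0, config$block_trim_frac)
    seg_len <- seg_df$a1 - seg_df$a0
    a_lo <- round(seg_df$a0 + t1 * seg_len)
    a_hi <- round(seg_df$a1 - t2 * seg_len)
    keep <- a_hi > a_lo + 1
    fwd <- seg_df$orientation == "+"
    b_lo <- ifelse(fwd, seg_df$b0 + (a_lo - seg_df$a0),
                   seg_df$b0 + (seg_df$a1 - a_hi))
    b_hi <- ifelse(fwd, seg_df$b0 + (a_hi - seg_df$a0),
                   seg_df$b0 + (seg_df$a1 - a_lo))
    blocks <- data.frame(
      block_id = sprintf("blk%04d", seq_len(nrow(seg_df))),
      chrom_a = seg_df$chrom_a, start_a = a_lo, end_a = a_hi,
      chrom_b = seg_df$chrom_b, start_b = b_lo, end_b = b_hi,
      orientation = seg_df$orientation, stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
    rownames(blocks) <- NULL
    validate_synteny(blocks)

    list(blocks = blocks, genes_b = genes_b, truth_b = truth_b,
         homologs = homologs, cuts = cuts)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genome()], [simulate_expression()]
#' and optionally [simulate_synteny()] off one configuration.
#'
#' @param config a [simulation_config()].
#' @param synteny also simulate the rearranged second genome (default TRUE).
#' @return list with `genes`, `truth`, `expr`, and (when `synteny`)
#'   `blocks`, `genes_b`, `truth_b`, `homologs`.
#' @export
simulate_dataset <- function(config = simulation_config(), synteny = TRUE) {
  gen <- simulate_genome(config)
  expr <- simulate_expression(gen$genes, gen$truth, config)
  out <- list(genes = gen$genes, truth = gen$truth, expr = expr,
              config = config)
  if (synteny) {
    syn <- simulate_synteny(gen$genes, gen$truth, config)
    out <- c(out, syn)
  }
  out
}

#' Planted truth intervals as a region-like frame
#'
#' Converts the generator's ground-truth intervals into the `chrom`, `start`,
#' `end`, `kind` layout used by region sets (`high` becomes `RIDGE`, `low`
#' becomes `antiRIDGE`), for direct use in recovery scoring and the
#' cross-species classifiers.
#'
#' @param truth a ground-truth list from [simulate_genome()] (or `truth_b`).
#' @return data frame with columns `chrom`, `start`, `end`, `kind`.
#' @export
truth_regions <- function(truth) {
  iv <- truth$intervals
  data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
             kind = ifelse(iv$regime == "high", "RIDGE", "antiRIDGE"),
             stringsAsFactors = FALSE)
}
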