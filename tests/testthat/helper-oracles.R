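# Independent oracles: deliberately naive implementations used only to
# check the package's optimised paths.

# Sliding median with shrinking symmetric edge windows, by direct
# per-position sort-and-middle.
brute_running_median <- function(values, window) {
  n <- length(values)
  k <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    ki <- min(k, i - 1, n - i)
    sort(values[(i - ki):(i + ki)])[ki + 1]
  }, numeric(1))
}

# Mann-Whitney W by brute-force pair enumeration (ties count 1/2).
brute_rank_sum_W <- function(x, y) {
  w <- 0
  for (xi in x) for (yj in y) {
    w <- w + (xi > yj) + 0.5 * (xi == yj)
  }
  w
}

# Textbook goodness-of-fit chi-square: sum((O - E)^2 / E) over the two cells.
chisq_formula <- function(n_in, n_total, fraction) {
  e_in <- n_total * fraction
  e_out <- n_total * (1 - fraction)
  (n_in - e_in)^2 / e_in + ((n_total - n_in) - e_out)^2 / e_out
}
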