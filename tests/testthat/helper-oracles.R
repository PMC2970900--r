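# Independent oracles and shared fixture builders.

# Posterior moments by trapezoidal numerical integration of the
# (unnormalized) product of per-shift Gaussian likelihoods under a flat
# prior: p(c) propto exp(-0.5 * sum_i k_i (r_i - c)^2). Independent of the
# closed form it checks.
numeric_posterior <- function(residuals, precisions, n_grid = 20001L,
                              width_sigma = 10) {
  # center/scale the grid from the data themselves, not the closed form
  K <- sum(precisions)
  center <- sum(precisions * residuals) / K   # used only to place the grid
  sd0 <- 1 / sqrt(K)
  grid <- seq(center - width_sigma * sd0, center + width_sigma * sd0,
              length.out = n_grid)
  logp <- vapply(grid, function(c0)
    -0.5 * sum(precisions * (residuals - c0)^2), numeric(1))
  p <- exp(logp - max(logp))
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * diff(grid[1:2])
  Z <- trap(p)
  m <- trap(grid * p) / Z
  v <- trap((grid - m)^2 * p) / Z
  list(mean = m, sd = sqrt(v))
}

# Exhaustive global-alignment optimum by plain recursion (Delannoy-path
# enumeration, no memoization): independent of the DP implementation.
exhaustive_nw_score <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      sc <- if (s1[i] == s2[j] && s1[i] != "-") match else mismatch
      best <- max(best, rec(i - 1, j - 1) + sc)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(s1), length(s2))
}

# small direct-mode reference database for unit tests: one class per group
tiny_refdb <- function() {
  layout <- data.frame(
    atom_name = c("H", "N", "CA", "CD1", "C"),
    residue_type = c("ALA", "ALA", "ALA", "PHE", "ALA"),
    ss_state = "coil", bin_index = 0L, bin_low = 0, bin_high = Inf,
    mean_ppm = c(8.3, 119, 56, 131.5, 177.5),
    sd_ppm = c(0.6, 4, 2.2, 1.4, 1.3), count = 200L,
    stringsAsFactors = FALSE)
  make_refdb(layout, mode = "direct")
}

# classified data.frame built directly (bypasses IO) for posterior tests:
# one row per shift with explicit class mean/precision and group
make_classified <- function(group, value, class_mean, precision, n = NULL) {
  n <- n %||% max(length(group), length(value), length(class_mean),
                  length(precision))
  data.frame(chain_id = "A", seq_pos = seq_len(n),
             residue_type = "ALA", atom_name = "CA",
             value_ppm = rep_len(value, n),
             atom_type = "CA", ss_state = "coil", bin_index = 0L,
             class_mean_ppm = rep_len(class_mean, n),
             class_precision = rep_len(precision, n),
             group = rep_len(group, n), stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- shiftref:::`%||%`
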