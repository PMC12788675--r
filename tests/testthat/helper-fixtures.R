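# Shared fixtures: small hand-built datasets and independent oracles.

# dataset with per-kind constant cross sections above threshold
const_dataset <- function(ion = rep(0, 5), exc = rep(0, 5), el = 1,
                          grid = 10^seq(log10(8), 6, length.out = 25),
                          channels = water_channels(), name = "const") {
  thr <- channels$transition_energy[!is.na(channels$transition_energy)]
  grid <- sort(unique(c(grid, thr[thr > grid[1] & thr < grid[length(grid)]])))
  S <- matrix(0, length(grid), 11, dimnames = list(NULL, channels$channel))
  for (i in 1:5) S[grid > channels$transition_energy[i], i] <- ion[i]
  for (i in 1:5) S[grid > channels$transition_energy[5 + i], 5 + i] <- exc[i]
  S[, 11] <- el
  xs_dataset(grid, S, channels = channels, name = name, provenance = "synthetic")
}

# random strictly positive dataset on a shared grid (ionization thresholded)
random_dataset <- function(seed, grid = 10^seq(log10(8), 6, length.out = 20),
                           channels = water_channels(), name = NULL) {
  set.seed(seed)
  S <- matrix(exp(stats::rnorm(length(grid) * 11, sd = 0.5)),
              length(grid), 11, dimnames = list(NULL, channels$channel))
  for (i in 1:5) S[grid <= channels$transition_energy[i], i] <- 0
  xs_dataset(grid, S, channels = channels,
             name = name %||% paste0("rand", seed), provenance = "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent earth-mover oracle via the quantile-function coupling:
# W1 = integral over u in (0,1) of |Q_x(u) - Q_y(u)| du, evaluated exactly
# on the merged breakpoints of the two step-wise quantile functions.
oracle_w1 <- function(x, y) {
  x <- if (inherits(x, "icsd")) x$p else x
  y <- if (inherits(y, "icsd")) y$p else y
  m <- max(length(x), length(y))
  x <- c(x, rep(0, m - length(x)))
  y <- c(y, rep(0, m - length(y)))
  cx <- cumsum(x); cy <- cumsum(y)
  lv <- sort(unique(c(0, cx, cy, 1)))
  lv <- lv[lv <= 1 + 1e-15]
  tot <- 0
  for (i in seq_len(length(lv) - 1)) {
    u <- (lv[i] + lv[i + 1]) / 2
    qx <- which(cx >= u - 1e-15)[1] - 1
    qy <- which(cy >= u - 1e-15)[1] - 1
    tot <- tot + abs(qx - qy) * (lv[i + 1] - lv[i])
  }
  tot
}

# random normalized histogram over nu = 0..(k-1)
random_hist <- function(k, concentration = 1) {
  w <- stats::rgamma(k, concentration)
  w / sum(w)
}

# tolerance for comparing a recomputed summary statistic with a printed
# cell: half a unit in the cell's last digit plus half a unit in the last
# digit of the printed inputs it was derived from
printed_tol <- function(cell_str, input_strs = NULL) {
  dp <- function(s) nchar(sub("^[^.]*\\.?", "", s))
  tol <- 0.5 * 10^(-dp(cell_str))
  if (!is.null(input_strs)) tol <- tol + 0.5 * 10^(-min(vapply(input_strs, dp, 1L)))
  tol
}
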