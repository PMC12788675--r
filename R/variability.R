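# Inter-dataset variability machinery: the discrete Wasserstein-1
# (earth-mover) distance between cluster-size histograms, mean
# distributions, per-family variability records, and GUM-style dispersion
# summaries (MV, SD, RSD with uncertainties).

.as_prob <- function(x, what = "distribution") {
  p <- if (inherits(x, "icsd")) x$p else as.numeric(x)
  if (any(p < -1e-15)) stop(sprintf("%s has negative probabilities", what))
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("%s is not normalized (sums to %.12g)", what, sum(p)))
  p
}

.pad_common <- function(plist) {
  m <- max(vapply(plist, length, integer(1)))
  lapply(plist, function(p) c(p, rep(0, m - length(p))))
}

#' Wasserstein-1 (earth-mover) distance between discrete histograms
#'
#' For two normalized histograms on the same integer bins,
#' `W1 = sum_i |delta_i|` with `delta_0 = 0`,
#' `delta_{i+1} = delta_i + x_i - y_i` (the running difference of the
#' cumulative distributions).  The shorter histogram is zero-padded.  Two
#' identical shapes offset by `k` bins have `W1 = k`.
#'
#' @param x,y `icsd` objects or normalized probability vectors over
#'   nu = 0, 1, 2, ...
#' @return `W1` in bin units (here: ionizations).
#' @export
wasserstein1 <- function(x, y) {
  p <- .pad_common(list(.as_prob(x, "x"), .as_prob(y, "y")))
  px <- p[[1]]; py <- p[[2]]
  delta <- 0
  w1 <- 0
  for (i in seq_along(px)) {
    delta <- delta + px[i] - py[i]
    w1 <- w1 + abs(delta)
  }
  w1
}

#' First-order uncertainty of a Wasserstein-1 distance
#'
#' Propagates per-bin binomial count uncertainties through
#' `W1 = sum_i |delta_i|`, treating the two distributions as statistically
#' independent.  When one argument is the mean of a family containing the
#' other, independence fails and this is an overestimate; it is reported as
#' such, matching how such uncertainties are usually quoted.
#'
#' @param x,y `icsd` objects (history counts are needed for the bin
#'   uncertainties).
#' @return standard uncertainty of `W1`.
#' @export
u_wasserstein1 <- function(x, y) {
  stopifnot(inherits(x, "icsd"), inherits(y, "icsd"))
  p <- .pad_common(list(x$p, y$p))
  px <- p[[1]]; py <- p[[2]]
  delta <- cumsum(px - py)
  s <- sign(round(delta, 15))
  # d W1 / d x_j = sum_{i >= j} sign(delta_i); same magnitude for y_j
  coef <- rev(cumsum(rev(s)))
  ux <- u_binomial(px, x$n)
  uy <- u_binomial(py, y$n)
  sqrt(sum(coef^2 * (ux^2 + uy^2)))
}

#' Per-bin mean of a family of distributions
#'
#' Zero-pads all members to the longest support and takes the arithmetic
#' mean bin by bin (the "mean ICSD" used as the reference distribution when
#' quantifying family variability).
#'
#' @param icsds list (>= 2) of `icsd` objects or probability vectors.
#' @return normalized probability vector.
#' @export
mean_distribution <- function(icsds) {
  stopifnot(is.list(icsds), length(icsds) >= 2)
  p <- .pad_common(lapply(icsds, .as_prob))
  m <- Reduce(`+`, p) / length(p)
  m / sum(m)
}

#' Variability record of an ICSD family
#'
#' Computes each member's `W1` distance to the family's per-bin mean
#' distribution, the mean `W1` over members, and the mean `W1` normalized
#' by the family's average `M1` (so families at different energies, with
#' different numbers of occupied bins, become comparable).
#'
#' @param icsds list (>= 2) of `icsd` objects or probability vectors.
#' @param flavor which comparison this record represents: `"initial"`
#'   (original datasets), `"final"` (harmonized datasets) or `"delta"`
#'   (per-member original vs modified).
#' @return A list of class `variability_record`: `w1` (per member),
#'   `u_w1` (propagated, when inputs are `icsd`s), `mean_w1`, `mean_m1`,
#'   `w1_over_m1`, and a [dispersion()] summary of the member `W1` values.
#' @export
variability_record <- function(icsds, flavor = c("initial", "final", "delta")) {
  flavor <- match.arg(flavor)
  stopifnot(is.list(icsds), length(icsds) >= 2)
  mbar <- mean_distribution(icsds)
  w1 <- vapply(icsds, wasserstein1, numeric(1), y = mbar)
  all_icsd <- all(vapply(icsds, inherits, logical(1), what = "icsd"))
  u_w1 <- if (all_icsd) {
    nbar <- round(mean(vapply(icsds, function(z) z$n, numeric(1))))
    mbar_icsd <- icsd(round(mbar * nbar), sum(round(mbar * nbar)))
    vapply(icsds, u_wasserstein1, numeric(1), y = mbar_icsd)
  } else rep(NA_real_, length(icsds))
  m1 <- vapply(icsds, icsd_moment, numeric(1), k = 1)
  mean_m1 <- mean(m1)
  structure(list(flavor = flavor,
                 w1 = w1, u_w1 = u_w1,
                 mean_w1 = mean(w1),
                 mean_m1 = mean_m1,
                 w1_over_m1 = mean(w1) / mean_m1,
                 w1_dispersion = dispersion(w1,
                   if (all_icsd) u_w1 else NULL, rsd = FALSE)),
            class = "variability_record")
}

#' @export
print.variability_record <- function(x, ...) {
  cat(sprintf("<variability_record> %s: mean W1 = %.4g, mean M1 = %.4g, W1/M1 = %.4g\n",
              x$flavor, x$mean_w1, x$mean_m1, x$w1_over_m1))
  invisible(x)
}

#' Dispersion summary across datasets (MV, SD, RSD with uncertainties)
#'
#' For values `x_k` (one per dataset/code) with statistical uncertainties
#' `u(x_k)`:
#' * `MV` = arithmetic mean; `SD` = sample standard deviation (n - 1
#'   denominator); `RSD = SD / MV`.
#' * `u(MV) = sqrt(mean(u_k^2) + SD^2 / (n_c - 1))` — error propagation
#'   combined with the standard error of the mean.
#' * `u(SD) = sqrt(sum((x_k - MV)^2 u_k^2)) / (n_c * SD)` and
#'   `u(RSD) = RSD / (n_c * MV) * sqrt(sum((x_k/MV - 1 - RSD^2)^2 u_k^2))`
#'   — GUM-style propagation as conventionally quoted for these
#'   quantities; see the methods vignette for a caveat on their scaling.
#'
#' @param values numeric vector `x_k`, length >= 2.
#' @param uncertainties optional `u(x_k)`; zero if omitted.
#' @param rsd set `FALSE` to skip the RSD (e.g. when MV may be 0).
#' @return A list of class `dispersion_summary`.
#' @export
dispersion <- function(values, uncertainties = NULL, rsd = TRUE) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2) stop("dispersion needs at least 2 values")
  u <- if (is.null(uncertainties)) rep(0, n) else as.numeric(uncertainties)
  stopifnot(length(u) == n, all(u >= 0))
  mv <- mean(x)
  sd_ <- stats::sd(x)
  u_mv <- sqrt(mean(u^2) + sd_^2 / (n - 1))
  u_sd <- if (sd_ > 0) sqrt(sum((x - mv)^2 * u^2)) / (n * sd_) else NA_real_
  out <- list(n = n, MV = mv, SD = sd_, u_MV = u_mv, u_SD = u_sd,
              values = x, uncertainties = u)
  if (rsd) {
    if (mv == 0) stop("RSD undefined: mean value is zero")
    rsd_ <- sd_ / mv
    out$RSD <- rsd_
    out$u_RSD <- rsd_ / (n * mv) * sqrt(sum((x / mv - 1 - rsd_^2)^2 * u^2))
  }
  structure(out, class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf("<dispersion> n = %d: MV = %.4g +/- %.2g, SD = %.4g%s\n",
              x$n, x$MV, x$u_MV, x$SD,
              if (!is.null(x$RSD)) sprintf(", RSD = %.4g", x$RSD) else ""))
  invisible(x)
}
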