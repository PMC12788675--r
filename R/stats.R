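# Nanodosimetric quantities and their standard (k = 1) uncertainties.
#
# For an ICSD with probabilities P_nu (nu = 0..nu_m) over N histories:
#   M_k = sum_nu nu^k P_nu            (moments; M1 = mean cluster size)
#   F_k = sum_{nu >= k} P_nu          (complementary cumulative probabilities)
#   u(x) = sqrt(x (1 - x) / N)        (binomial, for P_nu and F_k)
#   u(M1) = sqrt((M2 - M1^2) / N)     (GUM propagation through the moments)

#' Moment of an ICSD
#'
#' `M_k = sum_nu nu^k P_nu`, computed in double precision directly from
#' counts / N.
#'
#' @param x an `icsd` or a numeric probability vector over nu = 0, 1, ...
#' @param k moment order (>= 1).
#' @return numeric `M_k`.
#' @export
icsd_moment <- function(x, k = 1) {
  stopifnot(k >= 1)
  p <- if (inherits(x, "icsd")) x$p else as.numeric(x)
  nu <- seq_along(p) - 1
  sum(nu^k * p)
}

#' Complementary cumulative probability of an ICSD
#'
#' `F_k = sum_{nu = k}^{nu_m} P_nu`, the probability of at least `k`
#' ionizations; non-increasing in `k`, and zero when the distribution has
#' no mass at or beyond `k`.
#'
#' @inheritParams icsd_moment
#' @param k threshold cluster size (>= 1).
#' @return numeric `F_k` in `[0, 1]`.
#' @export
icsd_cumulative <- function(x, k = 2) {
  stopifnot(k >= 1)
  p <- if (inherits(x, "icsd")) x$p else as.numeric(x)
  if (k + 1 > length(p)) return(0)
  sum(p[(k + 1):length(p)])
}

#' Binomial standard uncertainty of a probability
#'
#' `u(x) = sqrt(x (1 - x) / N)` for a probability estimated from `N`
#' independent histories.
#'
#' @param x probability value(s) in `[0, 1]`.
#' @param N number of histories (>= 1).
#' @return standard uncertainty (one s.d.).
#' @export
u_binomial <- function(x, N) {
  if (any(x < 0 | x > 1)) stop("probabilities must lie in [0, 1]")
  if (any(N < 1)) stop("N must be >= 1")
  sqrt(x * (1 - x) / N)
}

#' Standard uncertainty of the mean cluster size
#'
#' GUM propagation through the first two moments:
#' `u(M1) = sqrt((M2 - M1^2) / N)`.  For a two-bin ICSD this reduces
#' exactly to the binomial uncertainty of `P_1`.
#'
#' @param x an `icsd`.
#' @return standard uncertainty of `M1`.
#' @export
u_mean_cluster <- function(x) {
  stopifnot(inherits(x, "icsd"), x$n >= 2)
  m1 <- icsd_moment(x, 1)
  m2 <- icsd_moment(x, 2)
  v <- m2 - m1^2
  if (v < -1e-9) stop("M2 < M1^2 beyond rounding; corrupt distribution")
  sqrt(max(v, 0) / x$n)
}

#' Nanodosimetric summary of an ICSD
#'
#' @param x an `icsd`.
#' @return A one-row data.frame with `M1`, `M2`, `F2`, `F3`, their standard
#'   uncertainties, and `N`.
#' @export
nanodosim_summary <- function(x) {
  stopifnot(inherits(x, "icsd"))
  f2 <- icsd_cumulative(x, 2)
  f3 <- icsd_cumulative(x, 3)
  data.frame(M1 = icsd_moment(x, 1), M2 = icsd_moment(x, 2),
             F2 = f2, F3 = f3,
             u_M1 = u_mean_cluster(x),
             u_F2 = u_binomial(f2, x$n),
             u_F3 = u_binomial(f3, x$n),
             N = x$n)
}
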