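# Synthetic stand-ins for the cross-section tables of real track-structure
# codes, and directly synthesized cluster-size distributions.  The shapes
# below are phenomenological: they reproduce the gross energy dependence and
# magnitude of liquid-water electron cross sections well enough to exercise
# the transport, scoring and statistics layers, but carry no physics claim.

#' Default template energy grid
#'
#' Logarithmic grid from 8 eV to 1 MeV, at a fixed number of points per
#' decade (template minimum is 9; default 20).
#'
#' @param per_decade grid density, points per decade.
#' @return numeric vector of energies (eV).
#' @export
default_energy_grid <- function(per_decade = 20) {
  stopifnot(per_decade >= 9)
  g <- 10^seq(log10(8), 6, by = 1 / per_decade)
  if (g[length(g)] < 1e6) g <- c(g, 1e6)
  g
}

#' Parameters of the synthetic base cross-section model
#'
#' Per ionization shell: binding energy `B` (eV) and magnitude `C`; per
#' excitation level: excitation energy `W` (eV), magnitude `D` and shape
#' constant `c`; elastic: constants `a`, `b`.  The defaults give total
#' inelastic and elastic mean free paths of the order of nanometres at tens
#' to hundreds of eV, as in liquid water.
#'
#' @param ion_C,exc_D magnitudes per channel (nm^2 eV^2-ish scale factors).
#' @param exc_c excitation shape constant.
#' @param elastic_a,elastic_b elastic shape constants.
#' @param channels channel table; transition energies are taken from it.
#' @return An object of class `base_model_params`.
#' @export
base_model_params <- function(ion_C = c(2.0, 1.6, 1.2, 0.8, 0.3),
                              exc_D = c(0.012, 0.010, 0.008, 0.006, 0.005),
                              exc_c = 1,
                              elastic_a = 500, elastic_b = 50,
                              channels = water_channels()) {
  stopifnot(length(ion_C) == 5, all(ion_C > 0),
            length(exc_D) == 5, all(exc_D > 0),
            exc_c > 0, elastic_a > 0, elastic_b > 0)
  structure(list(ion_C = ion_C, exc_D = exc_D, exc_c = exc_c,
                 elastic_a = elastic_a, elastic_b = elastic_b,
                 channels = channels),
            class = "base_model_params")
}

#' Build the synthetic base dataset
#'
#' Ionization shells follow a thresholded Bethe-like shape
#' `sigma(E) = C * ln(E/B) / (E * B)` for `E > B` (zero otherwise), whose
#' single interior maximum sits at `E = e * B`.  Excitations follow a
#' thresholded peaked shape `D * (E/W - 1) / ((E/W)^2 + c)`, and elastic
#' scattering the strictly decreasing `a / (E * (E + b))`.
#'
#' @param params a `base_model_params`.
#' @param grid energy grid (eV); default [default_energy_grid()].
#' @param name dataset name.
#' @return An `xs_dataset` with provenance `"synthetic"`.
#' @export
base_dataset <- function(params = base_model_params(),
                         grid = default_energy_grid(), name = "base") {
  stopifnot(inherits(params, "base_model_params"))
  ch <- params$channels
  E <- as.numeric(grid)
  # refine the grid with the channel thresholds so that interpolated cross
  # sections vanish exactly at E = B (or W), not just at the nearest node
  thr <- ch$transition_energy[!is.na(ch$transition_energy)]
  E <- sort(unique(c(E, thr[thr > E[1] & thr < E[length(E)]])))
  S <- matrix(0, length(E), 11, dimnames = list(NULL, ch$channel))
  for (i in 1:5) {
    B <- ch$transition_energy[i]
    open <- E > B
    S[open, i] <- params$ion_C[i] * log(E[open] / B) / (E[open] * B)
  }
  for (i in 1:5) {
    W <- ch$transition_energy[5 + i]
    open <- E > W
    x <- E[open] / W
    S[open, 5 + i] <- params$exc_D[i] * (x - 1) / (x^2 + params$exc_c)
  }
  S[, 11] <- params$elastic_a / (E * (E + params$elastic_b))
  xs_dataset(E, S, channels = ch, name = name, provenance = "synthetic")
}

#' Spread profile for synthetic dataset families
#'
#' Describes the inter-member spread as the log-scale standard deviation of
#' a multiplicative perturbation: `amplitude_low` applies at 20 eV,
#' `amplitude_high` at 10 keV, with the standard deviation interpolated
#' linearly in log10(E) between the two anchors (clamped outside).
#' Perturbations vary smoothly in log E with correlation length
#' `correlation_scale` decades.  Defaults emulate a situation where member
#' cross sections disagree by factors of about two at the lowest energies
#' but only by a few percent in the keV range.
#'
#' @param amplitude_low log-scale s.d. at 20 eV (default `ln 2`).
#' @param amplitude_high log-scale s.d. at 10 keV (default 0.05).
#' @param correlation_scale decades of log10(E) over which the perturbation
#'   decorrelates.
#' @param seed integer seed for reproducible family generation.
#' @return An object of class `spread_profile`.
#' @export
spread_profile <- function(amplitude_low = log(2), amplitude_high = 0.05,
                           correlation_scale = 1, seed = 1L) {
  stopifnot(amplitude_low >= 0, amplitude_high >= 0,
            amplitude_low >= amplitude_high, correlation_scale > 0)
  structure(list(amplitude_low = amplitude_low,
                 amplitude_high = amplitude_high,
                 correlation_scale = correlation_scale,
                 E_low = 20, E_high = 1e4,
                 seed = as.integer(seed)),
            class = "spread_profile")
}

# run code under a private RNG stream without disturbing the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.profile_sd <- function(profile, E) {
  t <- (log10(E) - log10(profile$E_low)) /
       (log10(profile$E_high) - log10(profile$E_low))
  t <- pmin(pmax(t, 0), 1)
  profile$amplitude_low + t * (profile$amplitude_high - profile$amplitude_low)
}

#' Generate a perturbed family of cross-section datasets
#'
#' Member `k` carries `sigma_c(E) = base_sigma_c(E) * exp(g_kc(log10 E))`,
#' where `g_kc` is a smooth zero-mean Gaussian random function with
#' pointwise standard deviation given by the spread profile.  Smoothness is
#' obtained by drawing independent standard normals at nodes spaced
#' `correlation_scale` decades apart and blending neighbouring nodes with
#' cosine/sine weights, which preserves unit pointwise variance everywhere.
#' Multiplicative log-normal noise keeps cross sections positive and leaves
#' thresholds and grids untouched.
#'
#' @param base the base `xs_dataset`.
#' @param n_members number of members (>= 2); default 7.
#' @param profile a `spread_profile`.
#' @return List of `xs_dataset` members (provenance `"synthetic"`), with the
#'   profile attached as attribute `"profile"`.
#' @export
perturbed_family <- function(base, n_members = 7, profile = spread_profile()) {
  stopifnot(inherits(base, "xs_dataset"), n_members >= 2,
            inherits(profile, "spread_profile"))
  E <- base$energy
  lE <- log10(E)
  nodes <- seq(lE[1] - 1e-9, lE[length(lE)] + profile$correlation_scale,
               by = profile$correlation_scale)
  pos <- (lE - nodes[1]) / profile$correlation_scale
  j <- pmin(floor(pos) + 1, length(nodes) - 1)
  theta <- (pos - (j - 1)) * pi / 2
  sdE <- .profile_sd(profile, E)
  with_seed(profile$seed, {
    lapply(seq_len(n_members), function(k) {
      S <- base$sigma
      for (cidx in seq_len(11)) {
        z <- stats::rnorm(length(nodes))
        g <- sdE * (z[j] * cos(theta) + z[j + 1] * sin(theta))
        S[, cidx] <- S[, cidx] * exp(g)
      }
      ds <- xs_dataset(E, S, channels = base$channels,
                       name = sprintf("%s_m%d", base$name, k),
                       provenance = "synthetic")
      ds
    }) -> fam
    attr(fam, "profile") <- profile
    fam
  })
}

#' Directly synthesized family of cluster-size distributions
#'
#' Bypasses transport entirely: each member's per-history cluster size is a
#' binomial thinning (detection probability `thinning`) of a Poisson count
#' with member-specific mean drawn uniformly from `mean_range`, so the
#' member mean cluster size equals its drawn mean.  Used to exercise the
#' statistics and variability layers with controllable families.
#'
#' @param n_members number of members (>= 2).
#' @param energy_label nominal energy (eV), stored as metadata only.
#' @param mean_range length-2 numeric, range of member mean cluster sizes.
#' @param n_histories histories per member.
#' @param seed integer seed.
#' @param thinning binomial thinning probability in (0, 1].
#' @return List of `icsd` objects; drawn member means attached as attribute
#'   `"means"`.
#' @export
synthetic_icsd_family <- function(n_members, energy_label, mean_range,
                                  n_histories = 1e5, seed = 1L,
                                  thinning = 0.7) {
  stopifnot(n_members >= 2, length(mean_range) == 2, all(mean_range >= 0),
            diff(range(mean_range)) >= 0, n_histories >= 1,
            thinning > 0, thinning <= 1)
  with_seed(seed, {
    means <- stats::runif(n_members, mean_range[1], mean_range[2])
    fam <- lapply(seq_len(n_members), function(k) {
      base <- stats::rpois(n_histories, means[k] / thinning)
      nu <- stats::rbinom(n_histories, base, thinning)
      ic <- build_icsd(nu)
      ic$name <- sprintf("synthetic_m%d", k)
      ic$energy <- energy_label
      ic
    })
    attr(fam, "means") <- means
    fam
  })
}
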