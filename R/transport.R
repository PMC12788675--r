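#' Transport configuration
#'
#' Collects the knobs of the event-by-event electron transport engine.
#' Total interaction cross sections come from an `xs_dataset`; the
#' differential behaviour (elastic deflection, secondary-electron spectrum,
#' emission directions) is governed by the explicit stand-in models below,
#' whose parameters are configurable precisely because real track-structure
#' codes differ in these choices:
#'
#' * elastic: screened-Rutherford polar deflection with screening
#'   `eta(E) = eta_scale * Z^(2/3) / (tau (tau + 2))`, `tau = E / 511000`;
#' * ionization: secondary energy `eps` drawn from a density proportional
#'   to `1 / (eps^2 + epsilon0^2)` on `[0, (E - B)/2]`; secondary emitted
#'   isotropically; primary undeflected;
#' * excitation: local energy drop `W`, direction unchanged.
#'
#' @param cutoff_energy eV; electrons at or below it stop and deposit
#'   locally.  Track-structure practice uses 1--10 eV; default 10.
#' @param world_radius nm; electrons beyond it escape with their remaining
#'   energy (the world allows backscattering into the scoring sphere).
#' @param initial_direction `"fixed_z"` (default, reproducible) or
#'   `"isotropic"`; the centred-sphere geometry makes scored ICSDs
#'   invariant to this choice.
#' @param seed integer master seed; each history uses an independent
#'   counter-based substream, so results do not depend on execution order.
#' @param epsilon0 eV, secondary-spectrum shape parameter.
#' @param eta_scale,z_eff screened-Rutherford screening constants for water.
#' @param interpolation `"loglog"` or `"linear"` evaluation of the
#'   tabulated cross sections.
#' @param max_events_per_history safety valve against pathological media.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(cutoff_energy = 10, world_radius = 1000,
                             initial_direction = c("fixed_z", "isotropic"),
                             seed = 1L, epsilon0 = 13.6,
                             eta_scale = 1.7e-5, z_eff = 7.42,
                             interpolation = c("loglog", "linear"),
                             max_events_per_history = 5e6) {
  initial_direction <- match.arg(initial_direction)
  interpolation <- match.arg(interpolation)
  stopifnot(cutoff_energy > 0, world_radius > 0, epsilon0 > 0,
            eta_scale > 0, z_eff > 0)
  structure(list(cutoff_energy = cutoff_energy, world_radius = world_radius,
                 initial_direction = initial_direction, seed = as.integer(seed),
                 epsilon0 = epsilon0, eta_scale = eta_scale, z_eff = z_eff,
                 interpolation = interpolation,
                 max_events_per_history = max_events_per_history),
            class = "transport_config")
}

#' Electron state
#'
#' @param energy kinetic energy, eV (>= 0).
#' @param position 3-vector, nm.
#' @param direction unit 3-vector.
#' @return An object of class `electron_state`.
#' @export
electron_state <- function(energy, position = c(0, 0, 0),
                           direction = c(0, 0, 1)) {
  stopifnot(energy >= 0, length(position) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) stop("direction must be a unit vector")
  structure(list(energy = energy, position = as.numeric(position),
                 direction = as.numeric(direction) / nrm),
            class = "electron_state")
}

#' Sample exponential free path lengths
#'
#' @param Sigma macroscopic cross section, per nm (> 0).
#' @param n number of samples.
#' @return path lengths in nm, exponential with mean `1 / Sigma`.  Uses R's
#'   RNG (seed with [set.seed()]).
#' @export
sample_free_path <- function(Sigma, n = 1) {
  if (Sigma <= 0) stop("Sigma must be positive")
  stats::rexp(n, rate = Sigma)
}

#' Sample interaction channels from selection probabilities
#'
#' @param probs named probability vector summing to 1.
#' @param n number of draws.
#' @return character vector of channel names.  Uses R's RNG.
#' @export
select_channel <- function(probs, n = 1) {
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  if (is.null(names(probs))) names(probs) <- seq_along(probs)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Screening parameter of the screened-Rutherford elastic model
#'
#' `eta(E) = eta_scale * Z^(2/3) / (tau (tau + 2))` with `tau = E/511000`.
#'
#' @param E kinetic energy, eV.
#' @param eta_scale,z_eff model constants (water defaults).
#' @return dimensionless screening parameter.
#' @export
screening_eta <- function(E, eta_scale = 1.7e-5, z_eff = 7.42) {
  tau <- E / 511000
  eta_scale * z_eff^(2 / 3) / (tau * (tau + 2))
}

#' Sample the elastic polar deflection cosine
#'
#' Inverse-CDF sampling of `P(mu) propto (1 + 2 eta - mu)^-2` on
#' `[-1, 1]`.  In the `eta -> Inf` limit the distribution tends to uniform
#' on `[-1, 1]` (isotropic scattering).
#'
#' @param E kinetic energy, eV (used for `eta(E)` unless `eta` is given).
#' @param n number of samples.
#' @param eta optional explicit screening parameter.
#' @inheritParams screening_eta
#' @return sampled `cos(theta)` values.  Uses R's RNG.
#' @export
sample_elastic_mu <- function(E, n = 1, eta = NULL,
                              eta_scale = 1.7e-5, z_eff = 7.42) {
  if (is.null(eta)) eta <- screening_eta(E, eta_scale, z_eff)
  stopifnot(eta > 0)
  a <- 1 + 2 * eta
  u <- stats::runif(n)
  inv <- 1 / (a + 1) + u * (1 / (a - 1) - 1 / (a + 1))
  pmin(pmax(a - 1 / inv, -1), 1)
}

# rotate a unit vector by polar cosine mu and azimuth phi about itself
rotate_direction <- function(dir, mu, phi) {
  st <- sqrt(max(0, 1 - mu^2))
  if (abs(dir[3]) > 0.999999999) {
    out <- c(st * cos(phi), st * sin(phi), mu * sign(dir[3]))
  } else {
    den <- sqrt(1 - dir[3]^2)
    out <- c(mu * dir[1] + st * (dir[1] * dir[3] * cos(phi) - dir[2] * sin(phi)) / den,
             mu * dir[2] + st * (dir[2] * dir[3] * cos(phi) + dir[1] * sin(phi)) / den,
             mu * dir[3] - st * den * cos(phi))
  }
  out / sqrt(sum(out^2))
}

#' Apply an elastic collision to an electron state
#'
#' Energy is unchanged; the direction is deflected by a screened-Rutherford
#' polar angle and a uniform azimuth.
#'
#' @param state an `electron_state` with positive energy.
#' @inheritParams sample_elastic_mu
#' @return the updated `electron_state`.  Uses R's RNG.
#' @export
apply_elastic <- function(state, eta = NULL, eta_scale = 1.7e-5, z_eff = 7.42) {
  stopifnot(inherits(state, "electron_state"), state$energy > 0)
  mu <- sample_elastic_mu(state$energy, 1, eta, eta_scale, z_eff)
  phi <- stats::runif(1, 0, 2 * pi)
  state$direction <- rotate_direction(state$direction, mu, phi)
  state
}

#' Sample the secondary-electron energy of an ionization
#'
#' Density proportional to `1 / (eps^2 + epsilon0^2)` on `[0, (E - B)/2]`
#' (the upper bound reflects the indistinguishability convention that the
#' faster outgoing electron is the primary).
#'
#' @param E primary kinetic energy, eV (> B).
#' @param B shell binding energy, eV.
#' @param n number of samples.
#' @param epsilon0 shape parameter, eV.
#' @return secondary energies in `[0, (E - B)/2]`.  Uses R's RNG.
#' @export
sample_secondary_energy <- function(E, B, n = 1, epsilon0 = 13.6) {
  if (E <= B) stop("ionization channel not open: E <= B")
  emax <- (E - B) / 2
  epsilon0 * tan(stats::runif(n) * atan(emax / epsilon0))
}

#' Apply an inelastic collision to an electron state
#'
#' Excitation deposits the transition energy `W` locally and leaves the
#' direction unchanged.  Ionization deposits the binding energy `B`,
#' splits the remainder between the undeflected primary and an isotropic
#' secondary, and conserves energy exactly:
#' `E_in = E_primary_out + eps + B`.
#'
#' @param state an `electron_state`.
#' @param kind `"excitation"` or `"ionization"`.
#' @param transition_energy `W` or `B`, eV.
#' @param epsilon0 secondary-spectrum shape parameter, eV.
#' @return A list with `primary` (updated state), `secondary`
#'   (`electron_state` or `NULL`) and `event` (a one-row data.frame with
#'   the interaction position, kind, deposit and secondary energy).
#'   Uses R's RNG.
#' @export
apply_inelastic <- function(state, kind = c("excitation", "ionization"),
                            transition_energy, epsilon0 = 13.6) {
  kind <- match.arg(kind)
  stopifnot(inherits(state, "electron_state"))
  if (state$energy <= transition_energy)
    stop(sprintf("%s channel not open: E = %g eV <= %g eV",
                 kind, state$energy, transition_energy))
  pos <- state$position
  if (kind == "excitation") {
    state$energy <- state$energy - transition_energy
    secondary <- NULL
    eps <- NA_real_
    dep <- transition_energy
  } else {
    eps <- sample_secondary_energy(state$energy, transition_energy, 1, epsilon0)
    dep <- transition_energy
    state$energy <- state$energy - transition_energy - eps
    mu <- stats::runif(1, -1, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    st <- sqrt(1 - mu^2)
    secondary <- electron_state(eps, pos, c(st * cos(phi), st * sin(phi), mu))
  }
  list(primary = state, secondary = secondary,
       event = data.frame(x = pos[1], y = pos[2], z = pos[3], kind = kind,
                          energy_deposit = dep, secondary_energy = eps))
}

.engine_call <- function(E0, ds, mat, cfg, n_histories, sphere_radius,
                         keep_events) {
  validate_xs_dataset(ds)
  stopifnot(inherits(mat, "material"), inherits(cfg, "transport_config"),
            E0 > cfg$cutoff_energy, n_histories >= 1)
  kind_code <- match(ds$channels$kind, c("ionization", "excitation", "elastic")) - 1L
  .transport_engine(E0, as.integer(n_histories),
                    ds$energy, ds$sigma,
                    kind_code, ds$channels$transition_energy,
                    mat$number_density, cfg$cutoff_energy,
                    cfg$world_radius, sphere_radius,
                    cfg$seed, cfg$initial_direction == "isotropic",
                    cfg$epsilon0, cfg$eta_scale, cfg$z_eff,
                    cfg$interpolation == "loglog", keep_events,
                    cfg$max_events_per_history)
}

#' Simulate one electron history
#'
#' Transports a primary of energy `E0` starting at the origin, plus its
#' full secondary cascade, through the medium described by `ds` and `mat`.
#' Returns the complete ordered event list with energy bookkeeping:
#' `E0 = sum(deposits) + terminated_energy + escaped_energy`.
#'
#' @param E0 primary kinetic energy, eV (> cutoff).
#' @param ds an `xs_dataset`.
#' @param mat a `material`.
#' @param cfg a `transport_config`.
#' @return An object of class `track`: `primary_energy`, `events`
#'   (data.frame with `event`, `channel`, `kind`, `x`, `y`, `z`, `deposit`,
#'   `secondary_energy`), `terminated_energy`, `escaped_energy`.
#' @export
simulate_history <- function(E0, ds, mat = water_material(),
                             cfg = transport_config()) {
  res <- .engine_call(E0, ds, mat, cfg, 1L, -1, TRUE)
  ev <- res$events
  ev$kind <- ds$channels$kind[ev$channel]
  ev$channel <- ds$channels$channel[ev$channel]
  structure(list(primary_energy = E0,
                 events = ev[, c("event", "channel", "kind", "x", "y", "z",
                                 "deposit", "secondary_energy")],
                 terminated_energy = res$terminated,
                 escaped_energy = res$escaped),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> E0 = %g eV, %d events (%d ionizations), terminated %.3g eV, escaped %.3g eV\n",
              x$primary_energy, nrow(x$events),
              sum(x$events$kind == "ionization"),
              x$terminated_energy, x$escaped_energy))
  invisible(x)
}

#' Run many independent histories
#'
#' Histories use per-history counter-based substreams of `cfg$seed`:
#' identical inputs give bitwise-identical output regardless of how the
#' histories are batched.  For performance the engine scores cluster sizes
#' on the fly; set `keep_events = TRUE` (small runs only) to retain the
#' full event tables.
#'
#' @inheritParams simulate_history
#' @param n_histories number of primaries (>= 1).
#' @param sphere a `scoring_sphere` (or `NULL` to skip on-the-fly scoring).
#' @param keep_events retain per-event records (memory-heavy).
#' @return An object of class `track_ensemble`: per-history vectors `nu`
#'   (cluster size in `sphere`), `first_channel`, `n_events`, `deposited`,
#'   `terminated`, `escaped`, `truncated`, and optionally `events`.
#' @export
run_simulation <- function(E0, ds, mat = water_material(),
                           cfg = transport_config(), n_histories = 1e5,
                           sphere = NULL, keep_events = FALSE) {
  radius <- if (is.null(sphere)) -1 else sphere$radius
  res <- .engine_call(E0, ds, mat, cfg, n_histories, radius, keep_events)
  res$first_channel <- ifelse(res$first_channel > 0,
                              ds$channels$channel[res$first_channel],
                              NA_character_)
  res$primary_energy <- E0
  res$n_histories <- n_histories
  if (keep_events) res$events$kind <- ds$channels$kind[res$events$channel]
  class(res) <- "track_ensemble"
  res
}

#' @export
print.track_ensemble <- function(x, ...) {
  cat(sprintf("<track_ensemble> %d histories at E0 = %g eV, mean nu = %.4g\n",
              x$n_histories, x$primary_energy, mean(x$nu)))
  invisible(x)
}
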