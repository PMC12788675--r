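#' Standard interaction channels of the water molecule
#'
#' The channel set used throughout the package: ionization of the five
#' molecular orbitals of liquid water, five discrete electronic excitation
#' levels, and total elastic scattering.  Binding energies (`B`, eV) and
#' excitation energies (`W`, eV) default to values commonly adopted by
#' track-structure codes for liquid water; they can be overridden because
#' each simulation code historically carries its own level scheme.
#'
#' @param binding_energies numeric(5), ionization binding energies in eV
#'   (outer to inner shell).
#' @param excitation_energies numeric(5), electronic excitation energies in eV.
#' @return A data.frame with one row per channel and columns `channel`
#'   (label), `kind` (`"ionization"`, `"excitation"` or `"elastic"`),
#'   `index` (1--5 within kind, `NA` for elastic) and `transition_energy`
#'   (eV; `NA` for elastic).
#' @export
#' @examples
#' water_channels()
water_channels <- function(binding_energies = c(10.79, 13.39, 16.05, 32.30, 539.0),
                           excitation_energies = c(8.22, 10.00, 11.26, 11.93, 14.10)) {
  stopifnot(length(binding_energies) == 5, length(excitation_energies) == 5,
            all(binding_energies > 0), all(excitation_energies > 0))
  data.frame(
    channel = c(paste0("ion", 1:5), paste0("exc", 1:5), "elastic"),
    kind = c(rep("ionization", 5), rep("excitation", 5), "elastic"),
    index = c(1:5, 1:5, NA_integer_),
    transition_energy = c(binding_energies, excitation_energies, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Liquid-water material model
#'
#' Holds the molecular number density used to convert microscopic cross
#' sections (nm^2) into macroscopic ones (nm^-1).  The default corresponds
#' to liquid water at unit density (1.0 g/cm^3, M = 18.0153 g/mol), i.e.
#' n = 33.43 molecules/nm^3.
#'
#' @param number_density molecules per nm^3; must be positive.
#' @return An object of class `material`.
#' @export
water_material <- function(number_density = 33.43) {
  if (!is.numeric(number_density) || length(number_density) != 1 ||
      !is.finite(number_density) || number_density <= 0)
    stop("number_density must be a single positive number")
  structure(list(number_density = number_density), class = "material")
}

#' Construct and validate a cross-section dataset
#'
#' A dataset couples the standard 11 interaction channels (see
#' [water_channels()]) with total cross sections tabulated on a shared,
#' strictly increasing energy grid.  Validation rejects (rather than
#' repairs) negative cross sections, non-monotone grids, and non-zero
#' ionization cross sections at or below the shell binding energy.
#'
#' @param energy strictly increasing numeric vector of kinetic energies (eV).
#' @param sigma numeric matrix, `length(energy)` rows by 11 columns named as
#'   in `channels$channel`; total cross sections in nm^2.
#' @param channels channel table as returned by [water_channels()].
#' @param name dataset label.
#' @param provenance one of `"original"`, `"common"`, `"synthetic"`.
#' @return An object of class `xs_dataset`.
#' @export
xs_dataset <- function(energy, sigma, channels = water_channels(),
                       name = "dataset",
                       provenance = c("original", "common", "synthetic")) {
  provenance <- match.arg(provenance)
  sigma <- as.matrix(sigma)
  ds <- structure(list(name = name, provenance = provenance,
                       energy = as.numeric(energy), sigma = sigma,
                       channels = channels),
                  class = "xs_dataset")
  validate_xs_dataset(ds)
  ds
}

#' Validate a cross-section dataset
#'
#' Checks the structural invariants of an `xs_dataset`: grid monotonicity,
#' shape agreement, non-negativity, and the ionization-threshold rule
#' (sigma = 0 for E <= binding energy).  Errors name the offending channel
#' and row.
#'
#' @param ds an `xs_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_xs_dataset <- function(ds) {
  if (!inherits(ds, "xs_dataset")) stop("not an xs_dataset")
  E <- ds$energy
  if (length(E) < 2) stop("energy grid needs at least 2 points")
  if (any(!is.finite(E)) || any(E <= 0)) stop("energies must be finite and positive")
  if (any(diff(E) <= 0)) {
    i <- which(diff(E) <= 0)[1]
    stop(sprintf("energy grid not strictly increasing at row %d (%g -> %g eV)",
                 i, E[i], E[i + 1]))
  }
  ch <- ds$channels
  if (nrow(ch) != 11 || sum(ch$kind == "ionization") != 5 ||
      sum(ch$kind == "excitation") != 5 || sum(ch$kind == "elastic") != 1)
    stop("channel table must contain 5 ionization, 5 excitation and 1 elastic channel")
  inel <- ch$kind != "elastic"
  if (any(!is.finite(ch$transition_energy[inel])) ||
      any(ch$transition_energy[inel] <= 0))
    stop("inelastic channels need positive transition energies")
  S <- ds$sigma
  if (!is.matrix(S) || nrow(S) != length(E) || ncol(S) != 11)
    stop("sigma must be a matrix with one row per grid energy and 11 channel columns")
  if (is.null(colnames(S))) colnames(S) <- ch$channel
  if (!identical(colnames(S), ch$channel))
    stop("sigma column names must match the channel table")
  if (any(!is.finite(S))) stop("cross sections must be finite")
  if (any(S < 0)) {
    idx <- which(S < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative cross section in channel '%s' at row %d (E = %g eV)",
                 ch$channel[idx[2]], idx[1], E[idx[1]]))
  }
  for (j in which(ch$kind == "ionization")) {
    bad <- which(E <= ch$transition_energy[j] & S[, j] > 0)
    if (length(bad))
      stop(sprintf(
        "channel '%s': sigma = %g nm^2 at E = %g eV, at or below binding energy %g eV",
        ch$channel[j], S[bad[1], j], E[bad[1]], ch$transition_energy[j]))
  }
  invisible(ds)
}

#' Check template grid coverage
#'
#' The reporting template prescribes a grid spanning 8 eV to 1 MeV with at
#' least 9 points per decade.  Small toy grids are legal datasets (and load
#' fine); this check is applied where full template compliance matters,
#' e.g. for generated dataset families.
#'
#' @param ds an `xs_dataset`.
#' @param min_per_decade minimum grid density (points per decade).
#' @return `TRUE` invisibly, or an error.
#' @export
check_grid_coverage <- function(ds, min_per_decade = 9) {
  E <- ds$energy
  if (E[1] > 8 || E[length(E)] < 1e6)
    stop(sprintf("grid spans %g eV - %g eV; template requires 8 eV - 1 MeV",
                 E[1], E[length(E)]))
  dens <- 1 / diff(log10(E))
  if (any(dens < min_per_decade - 1e-9))
    stop(sprintf("grid density drops to %.2f points/decade; >= %d required",
                 min(dens), min_per_decade))
  invisible(TRUE)
}

#' @export
print.xs_dataset <- function(x, ...) {
  cat(sprintf("<xs_dataset> '%s' (%s): %d grid points, %g-%g eV, 11 channels\n",
              x$name, x$provenance, length(x$energy),
              x$energy[1], x$energy[length(x$energy)]))
  invisible(x)
}

.resolve_channel <- function(ds, channel) {
  if (is.character(channel)) {
    j <- match(channel, ds$channels$channel)
    if (is.na(j)) stop(sprintf("unknown channel '%s'", channel))
  } else {
    j <- as.integer(channel)
    if (j < 1 || j > 11) stop("channel index out of 1..11")
  }
  j
}

#' Interpolate a channel's total cross section
#'
#' Log-log interpolation is the default since cross sections vary over
#' decades; linear interpolation is available because historical codes
#' differ in this choice.  Grid nodes are reproduced exactly.  Segments
#' where either neighbouring value is zero (e.g. straddling an inelastic
#' threshold) fall back to linear interpolation, which keeps the result
#' finite and preserves the zero at threshold.  Extrapolation is an error.
#'
#' @param ds an `xs_dataset`.
#' @param channel channel label (e.g. `"ion1"`, `"elastic"`) or index 1--11.
#' @param E energies (eV), each within the grid span.
#' @param mode `"loglog"` (default) or `"linear"`.
#' @return numeric vector of cross sections (nm^2).
#' @export
interpolate_sigma <- function(ds, channel, E, mode = c("loglog", "linear")) {
  mode <- match.arg(mode)
  j <- .resolve_channel(ds, channel)
  Eg <- ds$energy
  s <- ds$sigma[, j]
  if (any(E < Eg[1] | E > Eg[length(Eg)]))
    stop(sprintf("E outside tabulated span [%g, %g] eV for channel '%s'",
                 Eg[1], Eg[length(Eg)], ds$channels$channel[j]))
  i <- findInterval(E, Eg, rightmost.closed = TRUE)
  i[i == length(Eg)] <- length(Eg) - 1
  at_node <- E == Eg[i]
  lo <- s[i]; hi <- s[i + 1]
  out <- numeric(length(E))
  if (mode == "loglog") {
    pos <- lo > 0 & hi > 0
    t_log <- (log(E) - log(Eg[i])) / (log(Eg[i + 1]) - log(Eg[i]))
    out[pos] <- exp(log(lo[pos]) + t_log[pos] * (log(hi[pos]) - log(lo[pos])))
    lin <- !pos
    t_lin <- (E - Eg[i]) / (Eg[i + 1] - Eg[i])
    out[lin] <- lo[lin] + t_lin[lin] * (hi[lin] - lo[lin])
  } else {
    t_lin <- (E - Eg[i]) / (Eg[i + 1] - Eg[i])
    out <- lo + t_lin * (hi - lo)
  }
  out[at_node] <- s[i][at_node]
  out
}

#' Per-channel interaction probabilities at a given energy
#'
#' Normalizes the 11 channel cross sections at energy `E` into selection
#' probabilities, the standard first step of event-by-event channel
#' sampling.  Channels whose tabulated value is zero at `E` (e.g. below
#' threshold) simply contribute zero probability.
#'
#' @inheritParams interpolate_sigma
#' @param E a single energy (eV) within the grid span.
#' @return A list with `probabilities` (named numeric(11), summing to 1),
#'   `sigma` (named per-channel cross sections, nm^2), `sigma_tot` and
#'   `sigma_inelastic` (nm^2).
#' @export
channel_probabilities <- function(ds, E, mode = c("loglog", "linear")) {
  mode <- match.arg(mode)
  stopifnot(length(E) == 1)
  sig <- vapply(seq_len(11), function(j) interpolate_sigma(ds, j, E, mode),
                numeric(1))
  names(sig) <- ds$channels$channel
  tot <- sum(sig)
  if (tot <= 0)
    stop(sprintf("degenerate medium: total cross section is zero at E = %g eV", E))
  list(probabilities = sig / tot,
       sigma = sig,
       sigma_tot = tot,
       sigma_inelastic = sum(sig[ds$channels$kind != "elastic"]))
}

#' Mean free path
#'
#' lambda = 1 / (n * sigma_tot(E)), with `n` the molecular number density
#' of the medium.
#'
#' @inheritParams channel_probabilities
#' @param mat a `material` (see [water_material()]).
#' @return mean free path in nm.
#' @export
mean_free_path <- function(ds, mat, E, mode = c("loglog", "linear")) {
  cp <- channel_probabilities(ds, E, match.arg(mode))
  1 / (mat$number_density * cp$sigma_tot)
}

#' Average several datasets into a common dataset
#'
#' Builds the channel-wise arithmetic-mean ("common") dataset: for every
#' channel and every target-grid energy, the unweighted mean of the member
#' values is taken, each member being evaluated by [interpolate_sigma()].
#' Inelastic and elastic channels may be averaged over different member
#' subsets, mirroring harmonization exercises where the elastic average
#' includes additional sources.
#'
#' @param datasets list of `xs_dataset` objects (>= 2).
#' @param target_grid energies (eV) for the averaged dataset; default is the
#'   union of the member grids restricted to their common span.
#' @param inelastic_members,elastic_members integer or character vectors
#'   selecting which members enter the inelastic / elastic averages
#'   (default: all).  An empty selection is a configuration error.
#' @param mode interpolation mode used to evaluate members off-grid.
#' @param name name for the averaged dataset.
#' @param channels channel table for the result; defaults to the first
#'   member's (member level schemes are deliberately not averaged).
#' @return An `xs_dataset` with provenance `"common"`.
#' @export
average_datasets <- function(datasets, target_grid = NULL,
                             inelastic_members = NULL, elastic_members = NULL,
                             mode = c("loglog", "linear"), name = "common",
                             channels = NULL) {
  mode <- match.arg(mode)
  if (!is.list(datasets) || length(datasets) < 2)
    stop("need at least 2 datasets to average")
  lapply(datasets, validate_xs_dataset)
  nm <- vapply(datasets, function(d) d$name, character(1))
  pick <- function(sel) {
    if (is.null(sel)) return(seq_along(datasets))
    if (is.character(sel)) sel <- match(sel, nm)
    sel <- as.integer(sel)
    if (length(sel) == 0 || any(is.na(sel)) || any(sel < 1 | sel > length(datasets)))
      stop("empty or invalid member selection for averaging")
    sel
  }
  inel_m <- pick(inelastic_members)
  el_m <- pick(elastic_members)
  if (is.null(target_grid)) {
    lo <- max(vapply(datasets, function(d) d$energy[1], numeric(1)))
    hi <- min(vapply(datasets, function(d) d$energy[length(d$energy)], numeric(1)))
    if (lo >= hi) stop("member grids have no common span")
    g <- sort(unique(unlist(lapply(datasets, function(d) d$energy))))
    target_grid <- g[g >= lo & g <= hi]
  }
  target_grid <- sort(unique(as.numeric(target_grid)))
  if (is.null(channels)) channels <- datasets[[1]]$channels
  S <- matrix(0, length(target_grid), 11, dimnames = list(NULL, channels$channel))
  for (j in seq_len(11)) {
    members <- if (channels$kind[j] == "elastic") el_m else inel_m
    vals <- vapply(members, function(k)
      interpolate_sigma(datasets[[k]], j, target_grid, mode),
      numeric(length(target_grid)))
    S[, j] <- rowMeans(matrix(vals, nrow = length(target_grid)))
  }
  # interpolation across a threshold can leave tiny positive values at or
  # below an ionization binding energy; clamp them so the invariant holds
  for (j in which(channels$kind == "ionization"))
    S[target_grid <= channels$transition_energy[j], j] <- 0
  xs_dataset(target_grid, S, channels = channels, name = name,
             provenance = "common")
}

#' Replace a dataset's cross sections by a common dataset's values
#'
#' Produces the "modified" counterpart of a member dataset in a
#' harmonization experiment: total cross sections are taken from the common
#' dataset (interpolated onto the member grid restricted to the common
#' span), while the member's channel scheme (binding/excitation energies)
#' is retained.  Ionization values at or below the member's binding
#' energies are clamped to zero so the result is a valid dataset.
#'
#' @param ds member `xs_dataset`.
#' @param common the averaged `xs_dataset`.
#' @param mode interpolation mode.
#' @return An `xs_dataset` with provenance `"common"`.
#' @export
harmonize_dataset <- function(ds, common, mode = c("loglog", "linear")) {
  mode <- match.arg(mode)
  E <- ds$energy
  E <- E[E >= common$energy[1] & E <= common$energy[length(common$energy)]]
  if (length(E) < 2) stop("member grid does not overlap the common grid")
  S <- vapply(seq_len(11), function(j) interpolate_sigma(common, j, E, mode),
              numeric(length(E)))
  colnames(S) <- ds$channels$channel
  for (j in which(ds$channels$kind == "ionization"))
    S[E <= ds$channels$transition_energy[j], j] <- 0
  xs_dataset(E, S, channels = ds$channels,
             name = paste0(ds$name, "_common"), provenance = "common")
}
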