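#' Scoring sphere
#'
#' A sphere of the given diameter centred at the origin.  Ionizations are
#' scored inside the open ball (strict `|r| < d/2`); the boundary rule is a
#' measure-zero choice for continuous interaction positions but is fixed
#' and documented here.
#'
#' @param diameter sphere diameter in nm (8 and 100 nm in typical
#'   nanodosimetric work; any positive value is allowed).
#' @return An object of class `scoring_sphere`.
#' @export
scoring_sphere <- function(diameter) {
  stopifnot(is.numeric(diameter), length(diameter) == 1, diameter > 0)
  structure(list(diameter = diameter, radius = diameter / 2),
            class = "scoring_sphere")
}

#' Count ionizations of one track inside a sphere
#'
#' Counts ionization events whose interaction point lies strictly inside
#' the sphere; excitation and elastic events never contribute.  Every
#' ionization inside the sphere is counted regardless of whether the
#' electron had previously left and re-entered the volume.
#'
#' @param track a `track` (see [simulate_history()]).
#' @param sphere a `scoring_sphere`.
#' @return integer cluster size `nu`.
#' @export
count_ionizations <- function(track, sphere) {
  ev <- track$events
  if (is.null(ev) || nrow(ev) == 0) return(0L)
  ion <- ev$kind == "ionization"
  if (!any(ion)) return(0L)
  r2 <- ev$x[ion]^2 + ev$y[ion]^2 + ev$z[ion]^2
  sum(r2 < sphere$radius^2)
}

#' Ionization cluster size distribution (ICSD)
#'
#' Stores raw per-cluster-size counts together with the number of histories
#' `N`, so every downstream uncertainty remains recomputable.  `counts[i]`
#' is the number of histories with cluster size `nu = i - 1`.
#'
#' @param counts non-negative counts indexed by cluster size 0, 1, 2, ...
#' @param n_histories total number of histories `N`; defaults to
#'   `sum(counts)` and must equal it.
#' @return An object of class `icsd` with elements `counts`, `n` and the
#'   normalized probabilities `p`.
#' @export
icsd <- function(counts, n_histories = sum(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) < 1 || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be whole numbers")
  if (abs(sum(counts) - n_histories) > 1e-9)
    stop("sum of counts must equal n_histories")
  if (n_histories < 1) stop("need at least one history")
  # trim trailing zero bins beyond the largest observed cluster size
  nz <- which(counts > 0)
  keep <- if (length(nz)) max(nz) else 1L
  counts <- counts[seq_len(keep)]
  structure(list(counts = counts, n = n_histories, p = counts / n_histories),
            class = "icsd")
}

#' @export
print.icsd <- function(x, ...) {
  cat(sprintf("<icsd> N = %g histories, nu = 0..%d, M1 = %.4g\n",
              x$n, length(x$counts) - 1L, icsd_moment(x, 1)))
  invisible(x)
}

#' Build an ICSD from tracks or per-history cluster sizes
#'
#' @param tracks either a list of `track` objects (scored against `sphere`),
#'   a `track_ensemble` from [run_simulation()] (whose stored `nu` is used),
#'   or directly an integer vector of per-history cluster sizes.
#' @param sphere a `scoring_sphere`; required when `tracks` is a list of
#'   track objects.
#' @return An `icsd`.
#' @export
build_icsd <- function(tracks, sphere = NULL) {
  nu <- if (inherits(tracks, "track_ensemble")) {
    tracks$nu
  } else if (is.numeric(tracks)) {
    tracks
  } else if (is.list(tracks)) {
    if (is.null(sphere)) stop("a scoring_sphere is required to score track objects")
    vapply(tracks, count_ionizations, integer(1), sphere = sphere)
  } else stop("unsupported input for build_icsd")
  if (length(nu) < 1) stop("need at least one history")
  if (any(nu < 0)) stop("cluster sizes must be non-negative")
  icsd(tabulate(as.integer(nu) + 1L, nbins = max(nu) + 1L))
}

#' Merge two ICSDs by pooling their histories
#'
#' Equivalent to building one ICSD from the concatenated track sets.
#'
#' @param a,b `icsd` objects.
#' @return An `icsd` with `N = a$n + b$n`.
#' @export
merge_icsd <- function(a, b) {
  stopifnot(inherits(a, "icsd"), inherits(b, "icsd"))
  m <- max(length(a$counts), length(b$counts))
  pad <- function(x) c(x, rep(0, m - length(x)))
  icsd(pad(a$counts) + pad(b$counts))
}

#' Write an ICSD as TSV
#'
#' Columns: `nu`, `count`, `P`, `u_P` (binomial standard uncertainty of
#' `P`); the history count is carried in a `# n_histories:` comment so the
#' raw counts round-trip losslessly.
#'
#' @param x an `icsd`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_icsd <- function(x, path) {
  stopifnot(inherits(x, "icsd"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_histories: %.0f", x$n),
               "nu\tcount\tP\tu_P"), con)
  df <- data.frame(nu = seq_along(x$counts) - 1L,
                   count = format(x$counts, digits = 17, trim = TRUE),
                   P = format(x$p, digits = 17, trim = TRUE),
                   u_P = format(u_binomial(x$p, x$n), digits = 17, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ICSD written by [write_icsd()]
#'
#' Validates counts (non-negative integers summing to `N`), normalization,
#' and that the stored `u_P` column is consistent with recomputation from
#' the counts.
#'
#' @param path file path.
#' @return An `icsd`.
#' @export
read_icsd <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  nline <- grep("^#\\s*n_histories:", lines, value = TRUE)
  if (!length(nline)) stop("missing '# n_histories:' header")
  N <- as.numeric(sub("^#\\s*n_histories:", "", nline[1]))
  body <- lines[!startsWith(lines, "#")]
  if (!length(body) || trimws(body[1]) != "nu\tcount\tP\tu_P")
    stop("malformed ICSD header row; expected 'nu count P u_P'")
  df <- utils::read.table(text = paste(body[-1], collapse = "\n"), sep = "\t",
                          col.names = c("nu", "count", "P", "u_P"))
  if (any(df$count < 0))
    stop(sprintf("negative count at nu = %d", df$nu[which(df$count < 0)[1]]))
  if (!identical(as.numeric(df$nu), as.numeric(seq_len(nrow(df)) - 1)))
    stop("nu column must run 0, 1, 2, ... without gaps")
  if (abs(sum(df$P) - 1) > 1e-9) stop("stored probabilities do not sum to 1")
  x <- icsd(df$count, N)
  if (max(abs(df$P - x$p)) > 1e-12)
    stop("stored P column inconsistent with counts / N")
  if (max(abs(df$u_P - u_binomial(x$p, N))) > 1e-8)
    stop("stored u_P column inconsistent with binomial recomputation")
  x
}
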