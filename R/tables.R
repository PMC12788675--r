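#' Published intercomparison reference tables
#'
#' Loads the per-code nanodosimetric values from the seven-code liquid
#' water intercomparison shipped with the package as plain TSV: mean
#' cluster sizes `M1` and cumulative probabilities `F2`, for the codes
#' running their original cross sections (`*_original`) or the common
#' (averaged) dataset (`*_common`), each with one-s.d. uncertainties at
#' N = 100,000 histories.  `"w1_reference"` holds the published mean
#' Wasserstein-1 distances and their `W1/M1` normalizations.  The
#' `*_summary` variants hold the published MV/SD/RSD cells, used as
#' reference outputs when testing the dispersion machinery.
#'
#' @param name one of `"m1_original"`, `"f2_original"`, `"m1_common"`,
#'   `"f2_common"`, their `"_summary"` variants, or `"w1_reference"`.
#' @return A data.frame.
#' @export
#' @examples
#' head(intercomparison_table("m1_original"))
intercomparison_table <- function(name = c("m1_original", "f2_original",
                                           "m1_common", "f2_common",
                                           "m1_original_summary",
                                           "f2_original_summary",
                                           "m1_common_summary",
                                           "f2_common_summary",
                                           "w1_reference")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "nanodosim")
  if (!nzchar(path)) stop("reference table not found; package not installed?")
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Two-bin ICSDs implied by a 20 eV M1 row
#'
#' At 20 eV in an 8 nm sphere at most one ionization is possible, so each
#' code's ICSD is fully determined by its `M1`: `{1 - M1, M1}`.  This turns
#' printed `M1` values into complete distributions for the Wasserstein
#' machinery.
#'
#' @param m1 vector of mean cluster sizes in `[0, 1]`.
#' @param N histories per value (default 100,000).
#' @return list of `icsd` objects (counts rounded to the nearest history).
#' @export
two_bin_icsds <- function(m1, N = 1e5) {
  stopifnot(all(m1 >= 0 & m1 <= 1))
  lapply(m1, function(m) icsd(c(round((1 - m) * N), round(m * N))))
}
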