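# Template layout (TSV):
#   optional '#' comment lines; '# name:' and '# provenance:' are recognized
#   header row 1: energy_eV  ion1..ion5  exc1..exc5  elastic
#   header row 2: transition_eV  B1..B5  W1..W5  NA
#   data rows:    E  sigma x 11   (eV, nm^2), full float precision

.template_cols <- c("energy_eV", paste0("ion", 1:5), paste0("exc", 1:5), "elastic")

#' Write a cross-section dataset to the template TSV layout
#'
#' The file carries two header rows (channel labels, then channel
#' transition energies in eV) followed by one row per grid energy.  Values
#' are written with 17 significant digits so that a read/write round trip
#' is lossless at double precision.
#'
#' @param ds an `xs_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xs_dataset <- function(ds, path) {
  validate_xs_dataset(ds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", ds$name),
               sprintf("# provenance: %s", ds$provenance),
               paste(.template_cols, collapse = "\t"),
               paste(c("transition_eV",
                       format(ds$channels$transition_energy[1:10], digits = 17),
                       "NA"), collapse = "\t")), con)
  body <- cbind(ds$energy, ds$sigma)
  utils::write.table(format(body, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cross-section dataset from the template TSV layout
#'
#' Parses and validates a template file (see [write_xs_dataset()] for the
#' layout).  Violated invariants are rejected with an error naming the
#' offending channel/row, never silently repaired.
#'
#' @param path file path.
#' @param name dataset name; default taken from a `# name:` comment or the
#'   file name.
#' @return An `xs_dataset`.
#' @export
read_xs_dataset <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) < 3) stop("template file too short: need 2 header rows and data")
  grab <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])) else NULL
  }
  if (is.null(name))
    name <- grab("name") %||% sub("\\.[^.]*$", "", basename(path))
  provenance <- grab("provenance") %||% "original"
  if (!provenance %in% c("original", "common", "synthetic")) provenance <- "original"

  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 12 || !identical(trimws(hdr), .template_cols)) {
    missing <- setdiff(.template_cols, trimws(hdr))
    stop(sprintf("template header mismatch; missing/unexpected columns: %s",
                 paste(if (length(missing)) missing else hdr, collapse = ", ")))
  }
  trow <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(trow) != 12 || trimws(trow[1]) != "transition_eV")
    stop("second header row must start with 'transition_eV' and list 11 values")
  trans <- suppressWarnings(as.numeric(trow[2:12]))
  if (any(is.na(trans[1:10])))
    stop("transition energies for the 10 inelastic channels must be numeric")

  body <- utils::read.table(text = paste(lines[-(1:2)], collapse = "\n"),
                            sep = "\t", header = FALSE,
                            colClasses = "numeric", col.names = .template_cols)
  ch <- water_channels(binding_energies = trans[1:5],
                       excitation_energies = trans[6:10])
  xs_dataset(body$energy_eV, as.matrix(body[, -1]), channels = ch,
             name = name, provenance = provenance)
}

#' Write a family of datasets plus a JSON manifest
#'
#' One template TSV per member, plus `manifest.json` recording member file
#' names and any generation metadata supplied.
#'
#' @param family list of `xs_dataset` objects.
#' @param dir output directory (created if needed).
#' @param meta named list of metadata stored verbatim in the manifest
#'   (e.g. spread-profile parameters and seed).
#' @return The manifest path, invisibly.
#' @export
write_xs_family <- function(family, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(family, function(d) paste0(d$name, ".tsv"), character(1))
  for (i in seq_along(family))
    write_xs_dataset(family[[i]], file.path(dir, files[i]))
  manifest <- c(list(members = files), meta)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset family written by [write_xs_family()]
#'
#' @param dir directory containing member TSVs and `manifest.json`.
#' @return A list of `xs_dataset` objects, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
read_xs_family <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  family <- lapply(manifest$members, function(f) read_xs_dataset(file.path(dir, f)))
  attr(family, "manifest") <- manifest
  family
}

`%||%` <- function(a, b) if (is.null(a)) b else a
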