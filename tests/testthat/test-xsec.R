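test_that("template files parse, validate and round-trip", {
  ds <- random_dataset(1, grid = c(10, 100, 1000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_xs_dataset(ds, path)
  back <- read_xs_dataset(path)
  expect_equal(back$energy, ds$energy)
  expect_equal(back$sigma, ds$sigma)
  expect_equal(back$channels, ds$channels)
  expect_identical(back$name, ds$name)
  expect_identical(back$provenance, ds$provenance)

  # toy 3-row file parses into 11 channels x 3 grid points
  expect_length(back$energy, 3)
  expect_equal(ncol(back$sigma), 11)

  # header tampering is rejected with the offending column named
  lines <- readLines(path)
  bad <- sub("\\bexc3\\b", "exc_three", lines)
  writeLines(bad, path)
  expect_error(read_xs_dataset(path), "exc3")
})

test_that("invariant violations are rejected, not repaired", {
  g <- c(10, 100, 1000)
  ds <- random_dataset(2, grid = g)
  # sigma > 0 at E <= binding energy
  S <- ds$sigma; S[1, "ion2"] <- 0.1   # E = 10 < B2 = 13.39
  expect_error(xs_dataset(g, S, name = "bad"), "ion2")
  # negative sigma
  S <- ds$sigma; S[2, "elastic"] <- -1e-3
  expect_error(xs_dataset(g, S), "negative")
  # non-monotone grid
  expect_error(xs_dataset(c(10, 1000, 100), ds$sigma), "increasing")
  # file-level: below-threshold ionization names the channel
  path <- withr::local_tempfile(fileext = ".tsv")
  write_xs_dataset(ds, path)
  lines <- readLines(path)
  row <- strsplit(lines[5], "\t")[[1]]   # first data row, E = 10 eV
  row[2] <- "0.1"                        # ion1 at 10 eV < B1 = 10.79 eV
  lines[5] <- paste(row, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_xs_dataset(path), "ion1")
})

test_that("interpolation honours nodes, closed forms, and range limits", {
  ch <- water_channels()
  g <- c(10, 20, 1000)
  S <- matrix(0, 3, 11, dimnames = list(NULL, ch$channel))
  S[, "elastic"] <- c(1, 3, 0.01)
  ds <- xs_dataset(g, S, name = "interp")
  # node identity in both modes
  expect_identical(interpolate_sigma(ds, "elastic", 20, "loglog"), 3)
  expect_identical(interpolate_sigma(ds, "elastic", 20, "linear"), 3)
  # linear midpoint: (10, 1) and (20, 3) -> 2 at E = 15
  expect_equal(interpolate_sigma(ds, "elastic", 15, "linear"), 2)
  # log-log power law: (10 eV, 1 nm^2) and (1000 eV, 0.01 nm^2) follow
  # sigma = 10/E, so E = 100 -> 0.1
  S2 <- S; S2[, "elastic"] <- c(1, 10 / 20, 0.01)
  ds2 <- xs_dataset(g, S2, name = "pl")
  expect_equal(interpolate_sigma(ds2, "elastic", 100, "loglog"), 0.1,
               tolerance = 1e-12)
  # monotone bracketing between nodes
  e_mid <- 10^stats::runif(50, log10(10), log10(20))
  v <- interpolate_sigma(ds, "elastic", e_mid, "loglog")
  expect_true(all(v >= 1 & v <= 3))
  # extrapolation forbidden
  expect_error(interpolate_sigma(ds, "elastic", 5), "span")
  expect_error(interpolate_sigma(ds, "elastic", 2000), "span")
})

test_that("channel probabilities normalize and handle thresholds", {
  ds <- const_dataset(ion = c(2, 0, 0, 0, 0), exc = c(1, 0, 0, 0, 0), el = 7)
  cp <- channel_probabilities(ds, 1000)
  expect_equal(unname(cp$probabilities[c("ion1", "exc1", "elastic")]),
               c(0.2, 0.1, 0.7))
  expect_equal(sum(cp$probabilities), 1, tolerance = 1e-12)
  expect_equal(cp$sigma_tot, 10)
  expect_equal(cp$sigma_inelastic, 3)
  # below every inelastic threshold only elastic remains
  cp_low <- channel_probabilities(ds, 8)
  expect_equal(unname(cp_low$probabilities["elastic"]), 1)
  # degenerate medium is an error
  ds0 <- const_dataset(el = 0)
  expect_error(channel_probabilities(ds0, 8), "degenerate")
  # random dataset: matches brute-force renormalization of the 11 sigmas
  dsr <- random_dataset(3)
  for (E in c(25, 400, 2e5)) {
    cpr <- channel_probabilities(dsr, E)
    sig <- vapply(1:11, function(j) interpolate_sigma(dsr, j, E), numeric(1))
    expect_equal(unname(cpr$probabilities), sig / sum(sig), tolerance = 1e-12)
    expect_equal(sum(cpr$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("dataset averaging is the channel-wise arithmetic mean", {
  a <- const_dataset(ion = rep(1, 5), exc = rep(0.5, 5), el = 2)
  b <- const_dataset(ion = rep(3, 5), exc = rep(1.5, 5), el = 6)
  avg <- average_datasets(list(a, b))
  expect_identical(avg$provenance, "common")
  expect_equal(avg$sigma[avg$energy > 600, "ion1"],
               rep(2, sum(avg$energy > 600)))
  expect_equal(avg$sigma[, "elastic"], rep(4, length(avg$energy)))
  # idempotence: averaging identical members returns the same values
  same <- average_datasets(list(a, a, a))
  expect_equal(same$sigma, a$sigma[match(same$energy, a$energy), ])
  # random members: per-node mean equals the elementwise oracle
  ms <- lapply(4:6, random_dataset)
  avg3 <- average_datasets(ms, target_grid = ms[[1]]$energy)
  oracle <- (ms[[1]]$sigma + ms[[2]]$sigma + ms[[3]]$sigma) / 3
  for (j in which(ms[[1]]$channels$kind == "ionization"))
    oracle[ms[[1]]$energy <= ms[[1]]$channels$transition_energy[j], j] <- 0
  expect_equal(avg3$sigma, oracle, tolerance = 1e-12)
  # linearity: scaling every member scales the average
  ms2 <- lapply(ms, function(d) xs_dataset(d$energy, d$sigma * 2.5,
                                           channels = d$channels,
                                           name = d$name, provenance = d$provenance))
  avg_scaled <- average_datasets(ms2, target_grid = ms[[1]]$energy)
  expect_equal(avg_scaled$sigma, avg3$sigma * 2.5, tolerance = 1e-12)
  # per-kind member lists: elastic average may use a different subset
  mix <- average_datasets(list(a, b), inelastic_members = 1, elastic_members = 1:2)
  expect_equal(unname(mix$sigma[nrow(mix$sigma), "ion1"]), 1)
  expect_equal(unname(mix$sigma[1, "elastic"]), 4)
  expect_error(average_datasets(list(a, b), elastic_members = integer(0)),
               "member selection")
  expect_error(average_datasets(list(a)), "at least 2")
})

test_that("mean free path follows 1/(n sigma_tot)", {
  ds <- const_dataset(el = 0.01)
  mat <- water_material()
  expect_equal(mean_free_path(ds, mat, 50), 1 / (33.43 * 0.01), tolerance = 1e-12)
  expect_equal(round(mean_free_path(ds, mat, 50), 3), 2.991)
  ds2 <- const_dataset(el = 0.02)
  expect_equal(mean_free_path(ds2, mat, 50), mean_free_path(ds, mat, 50) / 2)
  ds1 <- const_dataset(el = 1)
  expect_equal(mean_free_path(ds1, water_material(1), 50), 1)
})
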