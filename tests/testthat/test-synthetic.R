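test_that("base dataset shapes behave as designed", {
  ds <- base_dataset()
  expect_s3_class(ds, "xs_dataset")
  expect_silent(validate_xs_dataset(ds))
  expect_silent(check_grid_coverage(ds))
  ch <- ds$channels
  B1 <- ch$transition_energy[1]
  # zero at threshold, exactly (threshold is a grid node)
  expect_identical(interpolate_sigma(ds, "ion1", B1), 0)
  # single interior maximum of C ln(E/B)/(E B) at E = e * B
  E <- 10^seq(log10(B1 + 0.01), 5, length.out = 2000)
  s <- interpolate_sigma(ds, "ion1", E)
  e_hat <- E[which.max(s)]
  expect_equal(e_hat, exp(1) * B1, tolerance = 0.07)  # within grid resolution
  expect_equal(sum(diff(sign(diff(s))) != 0), 1)  # one interior extremum
  # elastic strictly decreasing on the grid
  expect_true(all(diff(ds$sigma[, "elastic"]) < 0))
})

test_that("perturbed families respect the spread profile and determinism", {
  base <- base_dataset()
  # zero amplitudes reproduce the base exactly
  p0 <- spread_profile(0, 0, seed = 11)
  fam0 <- perturbed_family(base, 3, p0)
  for (m in fam0) expect_equal(m$sigma, base$sigma)
  # same seed, same family; different seed differs
  pa <- spread_profile(seed = 42)
  expect_equal(lapply(perturbed_family(base, 4, pa), `[[`, "sigma"),
               lapply(perturbed_family(base, 4, pa), `[[`, "sigma"))
  pb <- spread_profile(seed = 43)
  expect_false(identical(perturbed_family(base, 4, pa)[[1]]$sigma,
                         perturbed_family(base, 4, pb)[[1]]$sigma))
  # every member passes the full validator
  fam <- perturbed_family(base, 7, pa)
  for (m in fam) expect_silent(validate_xs_dataset(m))
  # thresholds and grids unchanged
  expect_equal(fam[[1]]$energy, base$energy)
  expect_identical(fam[[1]]$channels, base$channels)
})

test_that("empirical spread matches the stated noise law", {
  base <- base_dataset()
  prof <- spread_profile(amplitude_low = log(2), amplitude_high = 0.05, seed = 5)
  fam <- perturbed_family(base, 200, prof)
  E <- base$energy
  node_low <- max(which(E <= 20))     # in the clamped low-E region: s.d. = ln 2
  node_high <- max(which(E <= 1e4))
  ls_low <- log(vapply(fam, function(m) m$sigma[node_low, "elastic"], numeric(1)))
  ls_high <- log(vapply(fam, function(m) m$sigma[node_high, "elastic"], numeric(1)))
  se <- log(2) / sqrt(2 * (200 - 1))
  expect_lt(abs(sd(ls_low) - log(2)), 3 * se)
  # spread shrinks with energy; high-energy spread near amplitude_high
  expect_gt(sd(ls_low), sd(ls_high))
  expect_lt(sd(ls_high), 0.1)
  # family RSD of sigma is non-increasing in E on average (monotone trend)
  nodes <- vapply(c(10, 100, 1000, 1e4), function(e) max(which(E <= e)), 1L)
  sds <- vapply(nodes, function(i)
    sd(log(vapply(fam, function(m) m$sigma[i, "elastic"], numeric(1)))), numeric(1))
  expect_true(all(diff(sds) <= 1e-3))
})

test_that("synthetic ICSD families have the stated Poisson structure", {
  # degenerate mean range: all mass at nu = 0
  fam0 <- synthetic_icsd_family(3, 20, c(0, 0), n_histories = 500, seed = 1)
  for (m in fam0) expect_equal(m$p, 1)
  # determinism
  f1 <- synthetic_icsd_family(4, 100, c(1, 3), n_histories = 2000, seed = 9)
  f2 <- synthetic_icsd_family(4, 100, c(1, 3), n_histories = 2000, seed = 9)
  expect_equal(lapply(f1, `[[`, "counts"), lapply(f2, `[[`, "counts"))
  # member sample means track the drawn means within 3 Poisson s.e.
  n <- 2e4
  fam <- synthetic_icsd_family(5, 100, c(1, 4), n_histories = n, seed = 7)
  means <- attr(fam, "means")
  for (k in seq_along(fam)) {
    m1 <- icsd_moment(fam[[k]], 1)
    expect_lt(abs(m1 - means[k]), 3 * sqrt(means[k] / n))
  }
  # normalized
  for (m in fam) expect_equal(sum(m$p), 1, tolerance = 1e-12)
})
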