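test_that("free-path and channel sampling primitives are calibrated", {
  set.seed(1)
  s <- sample_free_path(0.5, 1e5)
  expect_true(all(s >= 0))
  expect_lt(abs(mean(s) - 2), 3 * 2 / sqrt(1e5))
  expect_error(sample_free_path(0), "positive")
  set.seed(2); a <- sample_free_path(1, 10)
  set.seed(2); b <- sample_free_path(1, 10)
  expect_identical(a, b)

  probs <- c(ion = 0.2, exc = 0.1, el = 0.7)
  set.seed(3)
  draws <- select_channel(probs, 1e5)
  f <- table(factor(draws, levels = names(probs))) / 1e5
  for (k in names(probs))
    expect_lt(abs(f[[k]] - probs[[k]]),
              3 * sqrt(probs[[k]] * (1 - probs[[k]]) / 1e5))
  expect_true(all(select_channel(c(elastic = 1), 50) == "elastic"))
  expect_error(select_channel(c(0.5, 0.4)), "sum to 1")
})

test_that("elastic collisions preserve energy and direction norm", {
  st <- electron_state(100)
  set.seed(4)
  out <- apply_elastic(st)
  expect_equal(out$energy, st$energy)
  expect_equal(sum(out$direction^2), 1, tolerance = 1e-12)
  # eta -> Inf limit: cos(theta) tends to uniform on [-1, 1]
  set.seed(5)
  mu <- sample_elastic_mu(100, 2e4, eta = 1e7)
  ks <- suppressWarnings(stats::ks.test(mu, "punif", -1, 1))
  expect_gt(ks$p.value, 1e-3)
  # small eta: strongly forward peaked
  set.seed(6)
  mu_f <- sample_elastic_mu(1e4, 2e4)
  expect_gt(mean(mu_f), 0.9)
})

test_that("inelastic kinematics conserve energy and honour bounds", {
  st <- electron_state(20)
  # E = 20 eV, B = 10.79 eV: secondary in [0, 4.605] eV and neither outgoing
  # electron can ionize again
  set.seed(7)
  for (i in 1:50) {
    r <- apply_inelastic(electron_state(20), "ionization", 10.79)
    eps <- r$event$secondary_energy
    expect_true(eps >= 0 && eps <= (20 - 10.79) / 2 + 1e-12)
    expect_lt(r$primary$energy, 10.79)
    expect_lt(r$secondary$energy, 10.79)
    expect_equal(r$primary$energy + eps + 10.79, 20, tolerance = 1e-12)
  }
  # excitation: deposit W, no secondary, direction unchanged
  r <- apply_inelastic(electron_state(20), "excitation", 8.4)
  expect_equal(r$event$energy_deposit, 8.4)
  expect_null(r$secondary)
  expect_equal(r$primary$energy, 20 - 8.4)
  expect_error(apply_inelastic(electron_state(5), "excitation", 8.4), "not open")
  expect_error(apply_inelastic(electron_state(10), "ionization", 10.79), "not open")
})

test_that("histories conserve energy and reproduce deterministically", {
  ds <- base_dataset()
  for (seed in 1:3) {
    E0 <- stats::runif(1, 15, 500)
    ens <- run_simulation(E0, ds, cfg = transport_config(seed = seed),
                          n_histories = 100)
    closure <- ens$deposited + ens$terminated + ens$escaped - E0
    expect_lt(max(abs(closure)), 1e-6)
  }
  cfg <- transport_config(seed = 17)
  a <- run_simulation(50, ds, cfg = cfg, n_histories = 200,
                      sphere = scoring_sphere(8))
  b <- run_simulation(50, ds, cfg = cfg, n_histories = 200,
                      sphere = scoring_sphere(8))
  expect_identical(a$nu, b$nu)
  expect_identical(a$deposited, b$deposited)
  # single history equals the first substream of the ensemble
  tr <- simulate_history(50, ds, cfg = cfg)
  expect_equal(sum(tr$events$deposit), a$deposited[1])
  expect_equal(tr$terminated_energy, a$terminated[1])
})

test_that("20 eV primaries produce at most one ionization", {
  ds <- base_dataset()   # all binding energies >= 10.79 eV
  ens <- run_simulation(20, ds, cfg = transport_config(seed = 2),
                        n_histories = 5000, sphere = scoring_sphere(8))
  expect_true(all(ens$nu %in% c(0L, 1L)))
  ic <- build_icsd(ens)
  expect_equal(icsd_cumulative(ic, 2), 0)
})

test_that("degenerate media reduce to closed-form limits", {
  # zero inelastic: pure elastic random walk until escape, no ionizations
  ds_el <- const_dataset(el = 0.5, grid = c(8, 100, 1e6))
  cfg <- transport_config(seed = 5, world_radius = 20)
  ens <- run_simulation(30, ds_el, cfg = cfg, n_histories = 50,
                        sphere = scoring_sphere(8), keep_events = TRUE)
  expect_true(all(ens$nu == 0))
  expect_true(all(ens$events$kind == "elastic"))
  expect_equal(ens$escaped, rep(30, 50))   # full energy escapes
  # single excitation channel, no elastic: floor((E0 - cutoff)/W) deposits
  ch <- water_channels(excitation_energies = c(8.4, 9, 10, 11, 12))
  ds_exc <- const_dataset(exc = c(0.1, 0, 0, 0, 0), el = 0,
                          grid = c(8, 100, 1e6), channels = ch)
  cfg1 <- transport_config(seed = 6, cutoff_energy = 1)
  ens2 <- run_simulation(100, ds_exc, cfg = cfg1, n_histories = 40,
                         keep_events = TRUE)
  n_expected <- floor((100 - 1) / 8.4)
  expect_true(all(ens2$n_events == n_expected))
  expect_true(all(ens2$events$kind == "excitation"))
  expect_equal(ens2$deposited, rep(8.4 * n_expected, 40))
})

test_that("first-collision channel frequencies match the cross sections", {
  ds <- base_dataset()
  E0 <- 100
  n <- 2e4
  ens <- run_simulation(E0, ds, cfg = transport_config(seed = 8), n_histories = n)
  cp <- channel_probabilities(ds, E0)
  kind_of <- ds$channels$kind[match(ens$first_channel, ds$channels$channel)]
  p_ion <- sum(cp$probabilities[ds$channels$kind == "ionization"])
  f_ion <- mean(kind_of == "ionization")
  expect_lt(abs(f_ion - p_ion), 3 * sqrt(p_ion * (1 - p_ion) / n))
})

test_that("first flight lengths are exponential at the initial energy", {
  ds <- base_dataset()
  E0 <- 20
  n <- 3000
  ens <- run_simulation(E0, ds, cfg = transport_config(seed = 9),
                        n_histories = n, keep_events = TRUE)
  first <- ens$events[ens$events$event == 1 & ens$events$history <= n, ]
  d <- sqrt(first$x^2 + first$y^2 + first$z^2)
  Sigma <- 33.43 * channel_probabilities(ds, E0)$sigma_tot
  ks <- suppressWarnings(stats::ks.test(d, "pexp", Sigma))
  expect_gt(ks$p.value, 1e-3)
})

test_that("scored ICSDs are invariant to the initial direction", {
  ds <- base_dataset()
  n <- 5000
  sp <- scoring_sphere(8)
  a <- run_simulation(20, ds, cfg = transport_config(seed = 10),
                      n_histories = n, sphere = sp)
  b <- run_simulation(20, ds,
                      cfg = transport_config(seed = 11,
                                             initial_direction = "isotropic"),
                      n_histories = n, sphere = sp)
  ia <- build_icsd(a); ib <- build_icsd(b)
  diff_m1 <- abs(icsd_moment(ia, 1) - icsd_moment(ib, 1))
  u_comb <- sqrt(u_mean_cluster(ia)^2 + u_mean_cluster(ib)^2)
  expect_lt(diff_m1, 4 * u_comb)
})
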