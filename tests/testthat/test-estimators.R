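test_that("growth-rate estimator recovers constructed exponentials exactly", {
  tt <- seq(0, 8, 0.5)
  d <- tibble::tibble(time_h = tt, value = 1e6 * exp(0.18 * tt))
  est <- estimate_growth_rate(d)
  expect_equal(est$r, 0.18, tolerance = 1e-10)
  expect_equal(est$doubling_time_h, log(2) / 0.18, tolerance = 1e-10)
  # doubling time 4.2 h corresponds to r = ln2 / 4.2
  d2 <- tibble::tibble(time_h = tt, value = 5e5 * 2^(tt / 4.2))
  expect_equal(estimate_growth_rate(d2)$r, log(2) / 4.2, tolerance = 1e-10)
  # constant series: r = 0 with a warning
  d3 <- tibble::tibble(time_h = tt, value = rep(1e6, length(tt)))
  expect_warning(est3 <- estimate_growth_rate(d3), "<= 0")
  expect_equal(est3$r, 0)
})

test_that("growth window selection and validation", {
  # lag then exponential then saturation: the auto-window finds the middle
  tt <- seq(0, 12, 0.5)
  val <- 1e6 * pmin(exp(0.3 * pmax(tt - 2, 0)), 15)
  d <- tibble::tibble(time_h = tt, value = val)
  est <- estimate_growth_rate(d)
  expect_equal(est$r, 0.3, tolerance = 0.05)
  expect_gte(est$window_start, 1.5)
  expect_error(estimate_growth_rate(d, window = c(0, 0.6)), "fewer than 3")
  d$value[3] <- -1
  expect_error(estimate_growth_rate(d, window = c(0, 3)), "non-positive")
})

test_that("adsorption-rate estimator recovers phi from free-phage decay", {
  tt <- seq(0, 25 / 60, 4 / 60)
  d <- tibble::tibble(time_h = tt, value = 1e7 * exp(-2e-7 * 1e8 * tt))
  est <- estimate_adsorption_rate(d, cell_density = 1e8)
  expect_equal(est$phi, 2e-7, tolerance = 1e-12)
  # constant free phage: phi = 0
  d0 <- tibble::tibble(time_h = tt, value = rep(1e7, length(tt)))
  expect_equal(estimate_adsorption_rate(d0, 1e8)$phi, 0)
  expect_error(estimate_adsorption_rate(d, cell_density = 0), "positive")
  # noisy assays across the study regime stay inside the printed envelope
  set.seed(11)
  for (phi in c(2e-8, 6e-8, 2e-7)) {
    noisy <- tibble::tibble(
      time_h = rep(tt, 3),
      value = 1e7 * exp(-phi * 1e8 * rep(tt, 3)) * 10^rnorm(3 * length(tt), 0, 0.02))
    est <- estimate_adsorption_rate(noisy, 1e8)
    expect_equal(est$phi, phi, tolerance = 0.15)
    expect_true(est$phi >= 1.5e-8 && est$phi <= 2.5e-7)
  }
})

test_that("estimators are equivariant under a time-unit rescaling", {
  tt <- seq(0, 6, 0.5)
  d_h <- tibble::tibble(time_h = tt, value = 1e6 * exp(0.25 * tt))
  d_min <- tibble::tibble(time_h = tt * 60, value = d_h$value)
  expect_equal(estimate_growth_rate(d_min)$r * 60,
               estimate_growth_rate(d_h)$r, tolerance = 1e-10)
  a_h <- tibble::tibble(time_h = tt / 10, value = 1e7 * exp(-1e-7 * 1e8 * tt / 10))
  a_min <- tibble::tibble(time_h = tt / 10 * 60, value = a_h$value)
  expect_equal(estimate_adsorption_rate(a_min, 1e8)$phi * 60,
               estimate_adsorption_rate(a_h, 1e8)$phi, tolerance = 1e-10)
})

test_that("first-rise latent period detects a clean step and flags no-burst", {
  tt <- seq(0, 2, 0.1)
  val <- ifelse(tt < 1.0, 1e5, 5e6)
  d <- tibble::tibble(time_h = rep(tt, 2), replicate = rep(1:2, each = length(tt)),
                      value = rep(val, 2))
  est <- estimate_latent_period(d)
  expect_false(est$no_burst)
  expect_equal(est$latent_period_h, 1.0, tolerance = 0.11)
  flat <- tibble::tibble(time_h = tt, value = rep(1e5, length(tt)))
  est_flat <- estimate_latent_period(flat)
  expect_true(est_flat$no_burst)
  expect_true(is.na(est_flat$latent_period_h))
  expect_error(estimate_latent_period(d, baseline_points = 1), ">= 2")
})

test_that("first-rise estimates sit below the true mean latent period", {
  tr <- trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 99, beta = 50)
  ests <- vapply(1:20, function(s) {
    ds <- generate_onestep(tr, noise = noise_model(sigma = 0.15),
                           seed = 300 + s)
    free <- dplyr::filter(ds, .data$observable == "PFU_free",
                          .data$time_h >= 0.25)
    estimate_latent_period(free)$latent_period_h
  }, numeric(1))
  expect_true(all(is.finite(ests)))
  expect_gte(mean(ests < 1), 0.95)
})

test_that("conventional burst size follows its defining ratio", {
  expect_equal(conventional_burst_size(1e5, 6e5, 1.1e5)$beta, 50)
  expect_equal(conventional_burst_size(1e5, 1e5, 2e5)$beta, 0)
  # averaging invariance under replicate permutation
  v1 <- c(1.0e5, 1.2e5, 0.9e5); v2 <- c(6e5, 5e5, 7e5); t1 <- c(1.1e5, 1.3e5, 1.2e5)
  set.seed(1)
  p <- sample(3)
  expect_equal(conventional_burst_size(v1, v2, t1)$beta,
               conventional_burst_size(v1[p], v2[p], t1[p])$beta)
  expect_error(conventional_burst_size(2e5, 6e5, 1e5), "infected centers")
})

test_that("OD to CFU calibration is a log-log regression", {
  od <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  cfu <- 1e9 * od^1.1
  cal <- od_to_cfu_calibration(od, cfu)
  expect_equal(cal$slope, 1.1, tolerance = 1e-8)
  expect_equal(cal$predict(0.3), 1e9 * 0.3^1.1, tolerance = 1e-6)
})

test_that("estimate_traits combines the assays into one tidy row", {
  tr <- trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 99, beta = 50)
  ds <- generate_onestep(tr, noise = noise_model(sigma = 0.05), seed = 5)
  tt <- seq(0, 8, 0.5)
  growth <- tibble::tibble(time_h = tt, value = 1e6 * exp(log(2) / 4 * tt))
  est <- estimate_traits(growth = growth, onestep = ds)
  expect_equal(est$r, log(2) / 4, tolerance = 1e-6)
  expect_false(est$no_burst)
  expect_lt(est$latent_period_h, 1)
  expect_equal(est$beta, 50, tolerance = 0.35)
})
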