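test_that("one-step fit recovers truth at vanishing noise", {
  tr <- t4_traits()
  ds <- generate_onestep(tr, noise = noise_model(sigma = 0.01), seed = 17)
  fit <- fit_pairwise_onestep(ds, r = tr$r, n_steps = 1500, seed = 4)
  mode_row <- fit$draws[which.max(fit$log_post[
    seq.int(length(fit$log_post) - nrow(fit$draws) + 1,
            length(fit$log_post))]), ]
  expect_equal(mode_row$beta, 50, tolerance = 0.05)
  expect_equal(mode_row$tau, 1, tolerance = 0.05)
  expect_equal(mode_row$phi, 1e-7, tolerance = 0.10)
  # posterior latent CV is tied to the rounded stage count by construction
  expect_equal(fit$draws$latent_cv,
               1 / sqrt(fit$draws$n_e_rounded + 1))
  g <- glance(fit)
  expect_gt(g$acceptance_rate, 0)
  expect_lt(g$acceptance_rate, 1)
})

test_that("posterior-predictive envelope wraps the fitted one-step data", {
  tr <- t4_traits()
  ds <- generate_onestep(tr, noise = noise_model(sigma = 0.1), seed = 11)
  fit <- fit_pairwise_onestep(ds, r = tr$r, n_steps = 1500, seed = 7)
  pp <- posterior_predictive(fit, n_draws = 80, seed = 3)
  expect_gt(pp$coverage, 0.8)
  expect_true(all(pp$band$q2.5 <= pp$band$q97.5))
  expect_s3_class(autoplot(pp, data = ds), "ggplot")
})

test_that("a fit window before the first lysis leaves tau prior-dominated", {
  b <- benchmark_2x2()
  ds <- generate_community(b$traits, b$matrix, d_c = b$d_c,
                           noise = noise_model(0.1), seed = 8)
  fit <- fit_community(ds, b$matrix, b$growth_rates, fit_window = 0.6,
                       n_steps = 2000, seed = 2)
  for (nm in c("tau_H1|P1", "beta_H1|P1")) {
    prior_sd <- fit$priors[[nm]]$scale
    post_sd <- stats::sd(log10(fit$draws[[nm]]))
    # no sharpening beyond what the (coordinate-descent-centred) prior gives
    expect_gt(post_sd, 0.5 * prior_sd)
    within <- abs(log10(stats::median(fit$draws[[nm]])) -
                    fit$priors[[nm]]$location) < 2 * prior_sd
    expect_true(within)
  }
})

test_that("an SEIV fit to debris-attenuated data undershoots late-time hosts", {
  b <- benchmark_2x2()
  ds <- generate_community(b$traits, b$matrix, d_c = b$d_c,
                           noise = noise_model(0.1), seed = 12)
  fit <- fit_community(ds, b$matrix, b$growth_rates, fit_d_c = FALSE,
                       fit_window = 6.4, n_steps = 2500, seed = 5)
  med <- purrr::map_dbl(fit$draws, stats::median)
  sim <- fit$simulator(med)
  final <- dplyr::filter(sim, .data$observable == "qINT",
                         .data$time_h == max(sim$time_h))
  truth_final <- dplyr::filter(ds, .data$observable == "qINT",
                               .data$replicate == 1,
                               .data$time_h == max(ds$time_h))
  cmp <- dplyr::inner_join(final, truth_final, by = "id")
  expect_true(all(cmp$value.x < cmp$value.y))
  expect_true(any(cmp$value.x < cmp$value.y / 10))
})

test_that("a community burst-size shift is detected with the right sign", {
  b <- benchmark_2x2()
  # pairwise-context posterior for pair H2|P2
  tr <- trait_set(r = log(2) / 3.7, phi = 8e-8, tau = 0.8, n_e = 99,
                  beta = 60)
  ds1 <- generate_onestep(tr, noise = noise_model(sigma = 0.1), seed = 31)
  fit_pair <- fit_pairwise_onestep(ds1, r = tr$r, n_steps = 1500, seed = 6)
  # community data generated with that pair's burst size shifted up 2.5x
  shifted <- scenario_traitshift(b$traits, data.frame(
    host_id = "H2", phage_id = "P2", trait = "beta", factor = 2.5))
  ds2 <- generate_community(shifted, b$matrix, d_c = b$d_c,
                            noise = noise_model(0.1), seed = 32)
  fit_comm <- fit_community(ds2, b$matrix, b$growth_rates, n_steps = 6000,
                            seed = 7)
  shifted_res <- equivalence_test(fit_pair$draws$beta,
                                  fit_comm$draws[["beta_H2|P2"]],
                                  trait = "beta shifted", seed = 2)
  expect_identical(shifted_res$verdict, "moderate/strong shift")
  expect_lt(shifted_res$median_diff, 0) # community-context beta is larger
  # the unshifted H1|P1 burst size shows a smaller displacement
  unshifted_res <- equivalence_test(
    10^stats::rnorm(2000, log10(50), 0.05),
    fit_comm$draws[["beta_H1|P1"]], trait = "beta unshifted", seed = 2)
  expect_lt(abs(unshifted_res$median_diff), abs(shifted_res$median_diff))
})
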