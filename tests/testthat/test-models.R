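test_that("seiv_rhs reduces correctly in degenerate regimes", {
  tr <- trait_set(r = 0.2, phi = 1e-7, tau = 1, n_e = 3, beta = 50)
  # no phage: pure exponential growth, infection compartments untouched
  y <- pairwise_state(S = 1e6, V = 0, n_e = 3)
  dy <- seiv_rhs(y, tr)
  expect_equal(unname(dy["S"]), 0.2 * 1e6)
  expect_true(all(dy[c("E1", "E2", "E3", "I", "V", "D")] == 0))
  # beta = 0 and S = 0: V constant
  tr0 <- trait_set(r = 0.2, phi = 1e-7, tau = 1, n_e = 3, beta = 0)
  y0 <- pairwise_state(S = 0, V = 1e7, n_e = 3)
  expect_equal(unname(seiv_rhs(y0, tr0)["V"]), 0)
  # hand arithmetic: dS = rS - phi*S*V with r = 0
  trs <- trait_set(r = 0, phi = 1e-7, tau = 1, n_e = 3, beta = 50)
  ys <- pairwise_state(S = 1e6, V = 1e7, n_e = 3)
  expect_equal(unname(seiv_rhs(ys, trs)["S"]), -1e6)
  expect_error(seiv_rhs(replace(ys, 1, NaN), trs), "NaN")
})

test_that("seivd_rhs equals seiv_rhs at infinite d_c and halves flux at D = d_c", {
  tr_inf <- trait_set(r = 0.15, phi = 5e-8, tau = 0.8, n_e = 4, beta = 30)
  y <- pairwise_state(S = 2e6, V = 3e5, n_e = 4,
                      E = c(1e3, 2e3, 500, 100), I = 50, D = 1e5)
  expect_equal(seivd_rhs(y, tr_inf), seiv_rhs(y, tr_inf))
  tr_dc <- trait_set(r = 0.15, phi = 5e-8, tau = 0.8, n_e = 4, beta = 30,
                     d_c = 1e5)
  d_seiv <- seiv_rhs(y, tr_inf)
  d_seivd <- seivd_rhs(y, tr_dc)
  full_flux <- 5e-8 * 2e6 * 3e5
  # dS loses exactly half the infection flux relative to SEIV
  expect_equal(unname(d_seiv["S"] - d_seivd["S"]), -full_flux / 2)
  expect_equal(unname(d_seiv["E1"] - d_seivd["E1"]), full_flux / 2)
  expect_equal(unname(d_seiv["V"] - d_seivd["V"]), -full_flux / 2)
})

test_that("seivd_rhs matches an independent re-derivation on random states", {
  set.seed(42)
  for (rep in 1:20) {
    n_e <- sample(0:6, 1)
    tr <- trait_set(r = runif(1, 0, 0.3), phi = 10^runif(1, -8, -6.5),
                    tau = runif(1, 0.5, 2), n_e = n_e,
                    beta = runif(1, 5, 100), d_c = 10^runif(1, 5, 7))
    S <- runif(1, 0, 1e7); V <- runif(1, 0, 1e8)
    E <- runif(n_e, 0, 1e5); I <- runif(1, 0, 1e5); D <- runif(1, 0, 1e7)
    y <- pairwise_state(S = S, V = V, n_e = n_e, E = E, I = I, D = D)
    dy <- seivd_rhs(y, tr)
    # independent: write the equations out directly
    k <- (n_e + 1) / tr$tau
    theta <- 1 / (1 + (D / tr$d_c)^2)
    inf <- theta * tr$phi * S * V
    exp_dS <- tr$r * S - inf
    chain <- c(E, I)
    inflow <- c(inf, k * utils::head(chain, -1))
    exp_chain <- inflow - k * chain
    exp_dV <- tr$beta * k * I - inf
    exp_dD <- k * I
    expect_equal(unname(dy), c(exp_dS, exp_chain, exp_dV, exp_dD),
                 tolerance = 1e-12)
  }
})

test_that("adsorptive sink on exposed/infected cells is off by default", {
  tr <- trait_set(r = 0, phi = 1e-7, tau = 1, n_e = 2, beta = 0)
  y <- pairwise_state(S = 0, V = 1e6, n_e = 2, E = c(1e4, 1e4), I = 1e4)
  expect_equal(unname(seiv_rhs(y, tr)["V"]), 0)
  dy <- seiv_rhs(y, tr, adsorb_to_infected = TRUE)
  expect_equal(unname(dy["V"]), -1e-7 * 1e6 * 3e4)
})

test_that("community_rhs of a single-pair mask reduces to the pairwise rhs", {
  mask <- matrix(TRUE, 1, 1, dimnames = list("H", "P"))
  mat <- infection_matrix(mask)
  tb <- trait_table("H", "P", r = 0.18, phi = 8e-8, tau = 1.1, n_e = 5,
                    beta = 40)
  for (dc in list(NULL, c(H = 2e5))) {
    lay <- community_layout(tb, mat, d_c = dc)
    y <- community_state(lay, S = c(H = 1.5e6), V = c(P = 4e5), D = 3e5)
    y[2:7] <- c(1e3, 2e3, 3e3, 400, 50, 10)[1:6]
    dy <- community_rhs(y, lay)
    tr <- trait_set(r = 0.18, phi = 8e-8, tau = 1.1, n_e = 5, beta = 40,
                    d_c = if (is.null(dc)) Inf else dc[["H"]])
    yp <- pairwise_state(S = y[[1]], V = y[[8]], n_e = 5, E = unname(y[2:6]),
                         I = y[[7]], D = y[[9]])
    dyp <- seivd_rhs(yp, tr)
    expect_equal(unname(dy), unname(dyp)[c(1:7, 7 + 1, 7 + 2)],
                 tolerance = 1e-12)
  }
})

test_that("community_rhs: phage-free state grows each host; 9-pair layout", {
  tb <- default_trait_table()
  mat <- default_infection_matrix()
  lay <- community_layout(tb, mat)
  expect_equal(length(lay$host_idx), 9) # one dynamical block per interaction
  y0 <- community_state(lay, S = stats::setNames(rep(2e6, 5), mat$hosts),
                        V = stats::setNames(rep(0, 5), mat$phages))
  dy <- community_rhs(y0, lay)
  expect_equal(unname(dy[1:5]), unname(lay$r_host) * 2e6)
  expect_true(all(dy[-(1:5)] == 0)) # infection blocks and D stay put
})

test_that("community_layout demands traits for every interacting pair", {
  tb <- default_trait_table()[-1, ]
  expect_error(community_layout(tb, default_infection_matrix()),
               "missing traits")
})

test_that("community trajectory of a 1-pair mask matches the pairwise model", {
  mask <- matrix(TRUE, 1, 1, dimnames = list("H", "P"))
  mat <- infection_matrix(mask)
  tb <- trait_table("H", "P", r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 9,
                    beta = 50)
  times <- seq(0, 12, 0.5)
  cm <- community_model(tb, mat, d_c = c(H = 5e5))
  y0 <- community_state(cm$layout, S = c(H = 2e6), V = c(P = 2e5))
  traj_c <- integrate_dynamics(cm, y0, times, rtol = 1e-8)
  tr <- trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 9, beta = 50,
                  d_c = 5e5)
  traj_p <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5),
                               times, rtol = 1e-8)
  reorder <- c(1, 2:11, 12, 13) # S,E1..9,I then V,D share positions here
  expect_lt(max(abs(traj_c$state - traj_p$state[, reorder])) /
              max(traj_p$state), 1e-8)
})

test_that("debris is non-decreasing and states non-negative along SEIVD runs", {
  tr <- t4_traits(d_c = 3e5)
  traj <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5),
                             seq(0, 16, 0.1))
  expect_true(all(traj$state >= 0))
  expect_true(all(diff(traj$state[, "D"]) >= -1e-6 * max(traj$state[, "D"])))
  # SEIVD with infinite d_c equals SEIV on the same inputs
  tr_inf <- t4_traits(d_c = Inf)
  a <- integrate_dynamics(pairwise_model(tr_inf), list(S = 2e6, V = 2e5),
                          seq(0, 8, 0.25))
  tr_seiv <- trait_set(r = tr$r, phi = tr$phi, tau = tr$tau, n_e = tr$n_e,
                       beta = tr$beta)
  b <- integrate_dynamics(pairwise_model(tr_seiv), list(S = 2e6, V = 2e5),
                          seq(0, 8, 0.25))
  expect_equal(a$state, b$state)
})

test_that("stochastic chain transit times have mean tau and CV 1/sqrt(n_e+1)", {
  set.seed(7)
  n_e <- 24; tau <- 1.2
  k <- (n_e + 1) / tau
  # exponential stage sampling through E1..En and the terminal I stage
  transit <- rowSums(matrix(stats::rexp(2e4 * (n_e + 1), rate = k),
                            nrow = 2e4))
  expect_equal(mean(transit), tau, tolerance = 0.01)
  expect_equal(stats::sd(transit) / mean(transit), latent_cv(n_e),
               tolerance = 0.02)
})

test_that("burst accounting: phage produced per lysed cell converges to beta", {
  # r = 0 and a short adsorption pulse; after V-driven infection stops,
  # total phage produced / cells lysed -> beta
  tr <- trait_set(r = 0, phi = 1e-7, tau = 0.5, n_e = 9, beta = 37)
  times <- seq(0, 8, 0.05)
  traj <- integrate_dynamics(pairwise_model(tr), list(S = 1e5, V = 1e7),
                             times, rtol = 1e-10, atol = 1e-6)
  st <- traj$state[nrow(traj$state), ]
  lysed <- st[["D"]]
  # virions adsorbed equal cells infected (one virion per entry), so the
  # net production V_end - V0 + adsorbed must equal beta * lysed
  adsorbed <- 1e5 - st[["S"]]
  produced <- st[["V"]] - 1e7 + adsorbed
  expect_gt(lysed, 5e4) # most cells have lysed by 16 latent periods
  expect_equal(produced / lysed, 37, tolerance = 0.01)
})
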