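test_that("phage-free integration reproduces closed-form exponential growth", {
  tr <- trait_set(r = 0.2, phi = 1e-7, tau = 1, n_e = 4, beta = 50)
  traj <- integrate_dynamics(pairwise_model(tr), list(S = 1e6, V = 0),
                             times = c(0, 2.5, 5), rtol = 1e-8)
  expect_equal(unname(traj$state[3, "S"]), 1e6 * exp(1), tolerance = 1e-6)
  expect_true(all(traj$state[, c("I", "V", "D")] == 0))
})

test_that("halving tolerances changes the solution consistently", {
  tr <- t4_traits()
  times <- seq(0, 10, 0.5)
  a <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5), times,
                          rtol = 1e-6)
  b <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5), times,
                          rtol = 5e-7)
  expect_lt(trajectory_rel_supnorm(a, b), 1e-5)
})

test_that("SEIV benchmark host collapse agrees with a fixed-step RK4 oracle", {
  tr <- t4_traits()
  times <- seq(0, 16, 0.5)
  adaptive <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5),
                                 times)
  host <- observe(adaptive, "host_qINT")$value
  expect_lte(min(host), 2e6 / 100)
  rk4 <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5),
                            times, engine = "rk4", dt = 1e-3)
  expect_lte(min(observe(rk4, "host_qINT")$value), 2e6 / 100)
  expect_lt(trajectory_rel_supnorm(adaptive, rk4), 1e-4)
})

test_that("integration input validation and failure modes", {
  tr <- t4_traits()
  m <- pairwise_model(tr)
  expect_error(integrate_dynamics(m, list(S = -1, V = 0), c(0, 1)),
               "non-negative")
  expect_error(integrate_dynamics(m, list(S = 1e6, V = 0), c(0, 0)),
               "strictly increasing")
  expect_error(integrate_dynamics(m, list(S = 1e6, V = 0), c(2, 1)),
               "strictly increasing")
})

test_that("observe projects states onto assay observables", {
  tr <- trait_set(r = 0.1, phi = 1e-7, tau = 1, n_e = 3, beta = 20)
  traj <- integrate_dynamics(pairwise_model(tr, host_id = "H", phage_id = "P"),
                             list(S = 1e6, V = 1e5), seq(0, 4, 0.5))
  free <- observe(traj, "free_phage")
  tot <- observe(traj, "total_phage")
  qint <- observe(traj, "host_qINT")
  # brute-force projection from the raw state matrix
  st <- traj$state
  chain <- rowSums(st[, c("E1", "E2", "E3", "I")])
  expect_equal(free$value, unname(st[, "V"]))
  expect_equal(tot$value, unname(st[, "V"] + chain))
  expect_equal(qint$value, unname(st[, "S"] + chain))
  expect_equal(observe(traj, "phage_qEXT")$value, free$value)
  expect_equal(observe(traj, "total_host")$value, qint$value)
  expect_identical(unique(free$id), "P")
  expect_identical(unique(qint$id), "H")
  expect_error(observe(traj, "nope"), "unknown observable")
})

test_that("observe handles the degenerate infected-centre cases", {
  tr <- trait_set(r = 0, phi = 0, tau = 1, n_e = 2, beta = 10)
  # no infected cells: total phage equals free phage
  traj <- integrate_dynamics(pairwise_model(tr), list(S = 1e6, V = 1e5),
                             c(0, 1))
  expect_equal(observe(traj, "total_phage")$value,
               observe(traj, "free_phage")$value)
  # all phage adsorbed: 1e4 infected centres count once
  y <- pairwise_state(S = 1e6, V = 0, n_e = 2, I = 1e4)
  traj2 <- integrate_dynamics(pairwise_model(tr), y, c(0, 1e-6))
  expect_equal(observe(traj2, "total_phage")$value[1], 1e4)
})

test_that("community observables sum their pair blocks correctly", {
  b <- benchmark_2x2()
  cm <- community_model(b$traits, b$matrix, d_c = b$d_c)
  y0 <- initial_conditions_from_moi(cm$layout, 2e6, 0.1)
  traj <- integrate_dynamics(cm, y0, seq(0, 6, 0.5), rtol = 1e-6)
  st <- traj$state
  lay <- cm$layout
  qint <- observe(traj, "host_qINT")
  # brute force: H2 hosts pairs 2 (P1) and 3 (P2)
  chain_cols <- function(p) lay$pair_off[p] + seq_len(lay$n_e[p] + 1)
  h2 <- st[, 2] + rowSums(st[, chain_cols(2)]) + rowSums(st[, chain_cols(3)])
  expect_equal(qint$value[qint$id == "H2"], unname(h2))
  totp <- observe(traj, "total_phage")
  p1 <- st[, lay$v_off + 1] + rowSums(st[, chain_cols(1)]) +
    rowSums(st[, chain_cols(2)])
  expect_equal(totp$value[totp$id == "P1"], unname(p1))
  th <- observe(traj, "total_host")
  expect_equal(th$value,
               unname(rowSums(cbind(qint$value[qint$id == "H1"], h2))))
})

test_that("tidy and autoplot provide the tibble/plot surface of a trajectory", {
  tr <- trait_set(r = 0.1, phi = 1e-7, tau = 1, n_e = 2, beta = 20)
  traj <- integrate_dynamics(pairwise_model(tr), list(S = 1e6, V = 1e5),
                             seq(0, 2, 0.5))
  td <- tidy(traj)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time_h", "variable", "value"))
  expect_equal(nrow(td), 5 * 6)
  expect_s3_class(autoplot(traj), "ggplot")
})
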