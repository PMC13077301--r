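# shared ground-truth fixtures used across test files

# representative one-step-regime trait set (aggressive lytic pair)
t4_traits <- function(d_c = Inf) {
  trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 99, beta = 50,
            d_c = d_c)
}

# small two-host / two-phage community benchmark with known truth
benchmark_2x2 <- function() {
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                 dimnames = list(c("H1", "H2"), c("P1", "P2")))
  mat <- infection_matrix(mask)
  traits <- trait_table(
    host_id = c("H1", "H2", "H2"), phage_id = c("P1", "P1", "P2"),
    r = log(2) / c(4, 3.7, 3.7), phi = c(1e-7, 5e-8, 8e-8),
    tau = c(1, 1.2, 0.8), n_e = 99, beta = c(50, 30, 60))
  list(matrix = mat, traits = traits,
       d_c = c(H1 = 1e6, H2 = 8e5),
       growth_rates = stats::setNames(log(2) / c(4, 3.7), c("H1", "H2")),
       truth = stats::setNames(
         c(1e-7, 5e-8, 8e-8, 1, 1.2, 0.8, 50, 30, 60, 99, 1e6, 8e5, 0.1),
         c("phi_H1|P1", "phi_H2|P1", "phi_H2|P2",
           "tau_H1|P1", "tau_H2|P1", "tau_H2|P2",
           "beta_H1|P1", "beta_H2|P1", "beta_H2|P2",
           "n_e", "d_c_H1", "d_c_H2", "sigma")))
}

# uniform aggressive trait table over the default 9-pair network
uniform_community_traits <- function() {
  pairs <- interacting_pairs(default_infection_matrix())
  trait_table(pairs$host_id, pairs$phage_id, r = log(2) / 4, phi = 1e-7,
              tau = 1, n_e = 99, beta = 50)
}

# per-component relative sup-norm between two trajectories on a shared grid:
# for each state, the max absolute difference over time scaled by that
# state's own trajectory magnitude (floored at 1 density unit)
trajectory_rel_supnorm <- function(a, b) {
  stopifnot(identical(dim(a$state), dim(b$state)))
  d <- apply(abs(a$state - b$state), 2, max)
  s <- pmax(apply(abs(b$state), 2, max), 1)
  max(d / s)
}
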