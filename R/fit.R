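#' Default priors for a one-step growth fit
#'
#' Log-normal priors centred on the conventional trait estimates when those
#' can be computed from the data (adsorption slope over the adsorption phase,
#' first-rise latent period, plateau burst size), with fallback centres in
#' the experimentally typical ranges otherwise. The number of exposed stages
#' and the measurement noise scale get weakly informative log-normal priors.
#'
#' @param data One-step `ts_dataset`.
#' @param design The assay [experiment_design()] (for the adsorption-phase
#'   cell density).
#' @return Named list of [prior()] specs for `phi, tau, n_e, beta, sigma`.
#' @export
onestep_default_priors <- function(data, design = NULL) {
  design <- design %||% design_from_manifest(data) %||% onestep_design()
  free <- dplyr::filter(tibble::as_tibble(data),
                        .data$observable == "PFU_free")
  phi_c <- tryCatch({
    ads <- dplyr::filter(free, .data$time_h <= design$dilution_time + 1e-9)
    est <- estimate_adsorption_rate(ads, cell_density = design$cells_per_ml)
    if (is.finite(est$phi) && est$phi > 0) est$phi else 1e-7
  }, error = function(e) 1e-7)
  tau_c <- tryCatch({
    lp <- estimate_latent_period(dplyr::filter(
      free, .data$time_h >= (design$dilution_time %||% 0)))
    if (!lp$no_burst) lp$latent_period_h else 1
  }, error = function(e) 1)
  beta_c <- tryCatch({
    est <- estimate_traits(onestep = data)
    if (is.finite(est$beta) && est$beta > 0) est$beta else 50
  }, error = function(e) 50)
  list(
    phi = prior("lognormal", location = log10(phi_c), scale = 0.5),
    tau = prior("lognormal", location = log10(tau_c), scale = 0.3),
    n_e = prior("lognormal", location = log10(30), scale = 0.6, upper = 300),
    beta = prior("lognormal", location = log10(beta_c), scale = 0.5),
    sigma = prior("lognormal", location = log10(0.12), scale = 0.3)
  )
}

# build a sampling-space log posterior from priors and a natural-scale
# log-likelihood closure
make_log_posterior <- function(priors, loglik) {
  function(z) {
    lp <- priors_logdensity(priors, z)
    if (!is.finite(lp)) return(-Inf)
    x <- purrr::imap_dbl(priors, function(p, nm) from_sampling(p, z[[nm]]))
    ll <- loglik(x)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
}

sampling_init <- function(priors) {
  purrr::imap_dbl(priors, function(p, nm) p$location)
}

sampling_cov0 <- function(priors, shrink = 0.1) {
  diag(vapply(priors, function(p) (shrink * p$scale)^2, numeric(1)),
       length(priors))
}

draws_to_natural <- function(chain_draws, priors) {
  out <- chain_draws
  for (nm in colnames(out)) {
    out[, nm] <- from_sampling(priors[[nm]], out[, nm])
  }
  tibble::as_tibble(out)
}

#' Bayesian SEIV fit to a one-step growth curve
#'
#' Fits the pairwise SEIV model to replicated free/total phage series from a
#' one-step growth experiment by DRAM MCMC. The posterior covers the
#' adsorption rate, mean latent period, number of exposed stages (sampled
#' continuously, rounded inside the likelihood), burst size, and the
#' measurement noise scale; the host growth rate is fixed from growth
#' assays. Priors default to [onestep_default_priors()].
#'
#' @param data One-step `ts_dataset` (observables `PFU_free`/`PFU_total`).
#' @param r Fixed host growth rate (per hour).
#' @param priors Named list of [prior()] specs (default from the data).
#' @param design Assay design (default: dataset manifest).
#' @param n_steps MCMC steps (default 3000; burn-in 50%).
#' @param seed Chain seed.
#' @param rtol Solver tolerance inside the likelihood (default 1e-6).
#' @return A `posterior_ensemble`; draws include the rounded `n_e` and the
#'   implied latent-period CV.
#' @export
fit_pairwise_onestep <- function(data, r, priors = NULL, design = NULL,
                                 n_steps = 3000, seed = 1, rtol = 1e-6) {
  design <- design %||% design_from_manifest(data) %||% onestep_design()
  priors <- priors %||% onestep_default_priors(data, design)
  loglik <- onestep_loglik(data, design = design, r = r, rtol = rtol)
  log_post <- make_log_posterior(priors, loglik)
  init <- sampling_init(priors)
  if (!is.finite(log_post(init))) {
    # fall back to a prior-predictive search for a finite starting point
    ok <- FALSE
    for (i in 1:50) {
      cand <- purrr::imap_dbl(priors, function(p, nm)
        to_sampling(p, with_seed_local(child_seed(seed, i), prior_sample(p))))
      if (is.finite(log_post(cand))) { init <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("prior predictive check failed: no prior draw yields a ",
                  "finite posterior", call. = FALSE)
  }
  ch <- dram_sample(log_post, init, n_steps = n_steps, seed = seed,
                    cov0 = sampling_cov0(priors))
  nat <- draws_to_natural(ch$draws, priors)
  nat$n_e_rounded <- pmax(0, round(nat$n_e))
  nat$latent_cv <- latent_cv(nat$n_e_rounded)
  simulator <- function(params) {
    tr <- trait_set(r = r, phi = params[["phi"]], tau = params[["tau"]],
                    n_e = max(0, round(params[["n_e"]])),
                    beta = params[["beta"]])
    d <- design
    d$times <- sort(unique(data$time_h))
    simulate_onestep(tr, d, rtol = rtol)$series
  }
  new_posterior_ensemble(ch, priors, nat, simulator, data,
                         label = "pairwise one-step SEIV",
                         extra = list(r_fixed = r))
}

#' Bayesian SEIV/SEIVD fit to community time series
#'
#' Joint DRAM fit of per-pair adsorption rates, latent periods, and burst
#' sizes, one shared latent-period shape (`n_e`), per-host critical debris
#' densities (SEIVD mode), and a common noise scale, to replicated
#' qINT/qEXT community series. Host growth rates are fixed. Following the
#' two-stage scheme used for multi-cycle data, one replicate is first fitted
#' by coordinate descent to centre the priors and the remaining replicates
#' enter the likelihood.
#'
#' @param data Community `ts_dataset`.
#' @param matrix An [infection_matrix()].
#' @param growth_rates Named per-host growth rates (per hour, fixed).
#' @param fit_d_c SEIVD fit with per-host critical debris densities
#'   (default TRUE); FALSE fits plain community SEIV.
#' @param fit_window Optional upper time bound (hours) on the fitted data,
#'   e.g. 6.4 for an early-window SEIV refit; default uses the full series.
#' @param prior_replicate Replicate used for the coordinate-descent prior
#'   centring (default 1); the others inform the likelihood. With a single
#'   replicate, it is used for both stages.
#' @param prior_centers Optional named natural-scale vector of starting
#'   centres for the coordinate-descent stage (e.g. pairwise-fit medians);
#'   defaults to mid-range values.
#' @param prior_scale Log10 prior SD around the coordinate-descent centres
#'   (default 0.5; the latent-period shape `n_e` gets twice this, the noise
#'   scale a fixed 0.25).
#' @param n_steps,seed MCMC settings.
#' @param cd_sweeps Coordinate-descent sweep cap (default 6).
#' @param rtol Solver tolerance inside the likelihood.
#' @return A `posterior_ensemble` with per-pair parameters named
#'   `phi_<host>|<phage>` etc.
#' @export
fit_community <- function(data, matrix, growth_rates, fit_d_c = TRUE,
                          fit_window = NULL, prior_replicate = 1,
                          prior_centers = NULL, prior_scale = 0.5,
                          n_steps = 4000, seed = 1, cd_sweeps = 6,
                          rtol = 1e-5) {
  reps <- sort(unique(data$replicate))
  lik_reps <- setdiff(reps, prior_replicate)
  if (!length(lik_reps)) lik_reps <- reps
  ll_prior_rep <- community_loglik(data, matrix, growth_rates,
                                   fit_d_c = fit_d_c, fit_window = fit_window,
                                   replicates = prior_replicate, rtol = rtol)
  param_names <- attr(ll_prior_rep, "param_names")
  centers <- default_community_centers(param_names)
  if (!is.null(prior_centers)) {
    centers[names(prior_centers)] <- prior_centers
  }
  # stage 1: coordinate descent on one replicate, in log10 space
  z0 <- log10(centers)
  obj <- function(z) {
    v <- -ll_prior_rep(stats::setNames(10^z, param_names))
    if (!is.finite(v)) 1e300 else v
  }
  cd <- coordinate_descent_fit(obj, z0, lower = z0 - 2, upper = z0 + 2,
                               span = rep(0.5, length(z0)), tol = 1e-6,
                               max_sweeps = cd_sweeps)
  centers_fit <- stats::setNames(10^cd$par, param_names)
  # the latent-period shape is only weakly informed by coarse community
  # sampling, so its prior is kept broader than the rate/size traits; hard
  # support bounds keep the chain away from degenerate regimes (enormous
  # stage counts, vanishing latent periods)
  scale_for <- function(nm) {
    if (nm == "n_e") return(2 * prior_scale)
    if (nm == "sigma") return(0.25)
    prior_scale
  }
  bounds_for <- function(nm) {
    if (nm == "n_e") return(c(0, 300))
    if (grepl("^tau_", nm)) return(c(0.05, 24))
    c(0, Inf)
  }
  priors <- purrr::imap(
    stats::setNames(param_names, param_names),
    function(x, nm) {
      b <- bounds_for(nm)
      prior("lognormal", location = log10(centers_fit[[nm]]),
            scale = scale_for(nm), lower = b[1], upper = b[2])
    })
  # stage 2: DRAM on the remaining replicates
  loglik <- community_loglik(data, matrix, growth_rates, fit_d_c = fit_d_c,
                             fit_window = fit_window, replicates = lik_reps,
                             rtol = rtol)
  log_post <- make_log_posterior(priors, loglik)
  init <- sampling_init(priors)
  if (!is.finite(log_post(init))) {
    stop("log posterior not finite at the coordinate-descent optimum",
         call. = FALSE)
  }
  ch <- dram_sample(log_post, init, n_steps = n_steps, seed = seed,
                    cov0 = sampling_cov0(priors))
  nat <- draws_to_natural(ch$draws, priors)
  design <- attr(loglik, "design")
  times <- sort(unique(c(0, data$time_h)))
  pairs <- attr(loglik, "pairs")
  pair_lab <- paste0(pairs$host_id, "|", pairs$phage_id)
  simulator <- function(params) {
    tb <- trait_table(pairs$host_id, pairs$phage_id,
                      r = unname(growth_rates[pairs$host_id]),
                      phi = unname(params[paste0("phi_", pair_lab)]),
                      tau = unname(params[paste0("tau_", pair_lab)]),
                      n_e = max(0, round(params[["n_e"]])),
                      beta = unname(params[paste0("beta_", pair_lab)]))
    d_c <- if (fit_d_c) {
      stats::setNames(unname(params[paste0("d_c_", matrix$hosts)]),
                      matrix$hosts)
    } else NULL
    model <- community_model(tb, matrix, d_c = d_c,
                             growth_rates = growth_rates)
    y0 <- initial_conditions_from_moi(model$layout, design$cells_per_ml,
                                      design$moi,
                                      moi_convention = design$moi_convention)
    traj <- integrate_dynamics(model, y0, times, rtol = rtol)
    dplyr::bind_rows(
      dplyr::mutate(observe(traj, "host_qINT"), observable = "qINT"),
      dplyr::mutate(observe(traj, "phage_qEXT"), observable = "qEXT"))
  }
  new_posterior_ensemble(
    ch, priors, nat, simulator,
    data = dplyr::filter(tibble::as_tibble(data),
                         .data$replicate %in% lik_reps,
                         !grepl("_control$", .data$id),
                         if (is.null(fit_window)) TRUE else
                           .data$time_h <= fit_window + 1e-9),
    label = if (fit_d_c) "community SEIVD" else "community SEIV",
    extra = list(coordinate_descent = cd, growth_rates = growth_rates,
                 fit_window = fit_window))
}

default_community_centers <- function(param_names) {
  centers <- numeric(length(param_names))
  names(centers) <- param_names
  centers[grepl("^phi_", param_names)] <- 1e-7
  centers[grepl("^tau_", param_names)] <- 1
  centers[grepl("^beta_", param_names)] <- 50
  centers[grepl("^d_c_", param_names)] <- 1e6
  centers["n_e"] <- 30
  centers["sigma"] <- 0.15
  centers
}
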