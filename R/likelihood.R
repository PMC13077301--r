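#' Gaussian log-likelihood of observed densities on the log10 scale
#'
#' Each observed record contributes a Gaussian log-density of
#' `log10(observed)` about `log10(simulated)` with scale `sigma` (per
#' observable); records are matched to simulated series by
#' (time, id, observable) and every replicate enters as an independent term.
#' Records flagged below the detection limit are excluded by default.
#'
#' @param sim Simulated series: tibble with `time_h, id, observable, value`.
#' @param data Observed `ts_dataset` (or compatible tibble with `replicate`
#'   and `below_detection` columns).
#' @param sigma Noise scale(s) on log10 densities: a single value or a named
#'   vector keyed by observable.
#' @param exclude_censored Drop below-detection records (default TRUE).
#' @param sim_floor Simulated densities are floored at this value before
#'   taking log10 (default 1e-6 per ml), so an extinct model population is
#'   heavily but finitely penalised.
#' @return The scalar log-likelihood; unmatched data records are an error.
#' @export
log_likelihood <- function(sim, data, sigma, exclude_censored = TRUE,
                           sim_floor = 1e-6) {
  stopifnot(all(sigma > 0))
  obs <- tibble::as_tibble(data)
  if (exclude_censored && "below_detection" %in% names(obs)) {
    obs <- obs[!obs$below_detection, ]
  }
  if (any(obs$value <= 0)) {
    stop("observed densities must be > 0 for the log-scale likelihood",
         call. = FALSE)
  }
  key <- function(df) paste(round(df$time_h, 9), df$id, df$observable)
  idx <- match(key(obs), key(sim))
  if (anyNA(idx)) {
    stop("data records with no matching simulated point: ",
         paste(utils::head(unique(key(obs)[is.na(idx)]), 5), collapse = "; "),
         call. = FALSE)
  }
  mu <- log10(pmax(sim$value[idx], sim_floor))
  sig <- if (length(sigma) == 1 && is.null(names(sigma))) {
    rep(sigma, nrow(obs))
  } else {
    unname(sigma[obs$observable])
  }
  if (anyNA(sig)) stop("no sigma supplied for some observable", call. = FALSE)
  sum(stats::dnorm(log10(obs$value), mu, sig, log = TRUE))
}

#' Log-likelihood builder for one-step growth data
#'
#' Returns a closure mapping a named parameter vector
#' (`phi, tau, n_e, beta, sigma`) to the log-likelihood of the observed free
#' and total phage series under the one-step SEIV simulation. Integration
#' failures yield `-Inf`.
#'
#' @param data One-step `ts_dataset` (observables `PFU_free`, `PFU_total`).
#' @param design The [experiment_design()] of the assay (defaults to the
#'   dataset manifest's design, if present, else [onestep_design()]).
#' @param r Fixed host growth rate (per hour).
#' @param rtol,atol Solver tolerances used inside the fit.
#' @return `function(params) -> log-likelihood`.
#' @export
onestep_loglik <- function(data, design = NULL, r, rtol = 1e-6, atol = 1e-2) {
  design <- design %||% design_from_manifest(data) %||% onestep_design()
  sample_times <- sort(unique(data$time_h))
  design$times <- sample_times
  t_dil <- design$dilution_time
  stopifnot(!is.null(t_dil))
  # observation bookkeeping, done once: each record maps to a slot in the
  # simulated (time x {free,total}) grid; the sampling time at the dilution
  # instant reads the post-dilution state
  pre_mask <- sample_times < t_dil - 1e-12
  pre_times <- sort(unique(c(0, sample_times[pre_mask], t_dil)))
  post_times <- sort(unique(c(t_dil, sample_times[!pre_mask])))
  pre_rows <- match(round(sample_times[pre_mask], 9), round(pre_times, 9))
  post_rows <- match(round(sample_times[!pre_mask], 9), round(post_times, 9))
  obs <- tibble::as_tibble(data)
  if ("below_detection" %in% names(obs)) obs <- obs[!obs$below_detection, ]
  obs <- obs[obs$observable %in% c("PFU_free", "PFU_total") & obs$value > 0, ]
  obs_t <- match(round(obs$time_h, 9), round(sample_times, 9))
  obs_slot <- obs_t + (obs$observable == "PFU_total") * length(sample_times)
  obs_log <- log10(obs$value)
  S0 <- design$cells_per_ml
  V0 <- design$moi * S0
  dil <- design$dilution_factor
  function(params) {
    phi <- params[["phi"]]; tau <- params[["tau"]]
    beta <- params[["beta"]]; sigma <- params[["sigma"]]
    n_e <- max(0, round(params[["n_e"]]))
    if (!all(is.finite(c(phi, tau, beta, sigma, n_e))) || phi < 0 ||
        tau <= 0 || beta < 0 || sigma <= 0) {
      return(-Inf)
    }
    pars <- list(r = r, phi = phi, tau = tau, n_e = as.integer(n_e),
                 beta = beta, d_c = Inf, hill = 2, carrying_capacity = Inf,
                 adsorb_to_infected = FALSE)
    y0 <- numeric(n_e + 4)
    y0[1] <- S0; y0[n_e + 3] <- V0
    sol <- tryCatch({
      pre <- dp45_pairwise(y0, pre_times, pars, rtol, atol, -1)
      post <- dp45_pairwise(pre[nrow(pre), ] * dil, post_times, pars, rtol,
                            atol, -1)
      list(pre = pre, post = post)
    }, error = function(e) NULL)
    if (is.null(sol)) return(-Inf)
    chain_sum <- function(m) {
      .rowSums(m[, 2:(n_e + 2), drop = FALSE], nrow(m), n_e + 1)
    }
    free <- c(sol$pre[pre_rows, n_e + 3], sol$post[post_rows, n_e + 3])
    total <- free + c(chain_sum(sol$pre)[pre_rows],
                      chain_sum(sol$post)[post_rows])
    mu <- log10(pmax(c(free, total), 1e-6))
    sum(stats::dnorm(obs_log, mu[obs_slot], sigma, log = TRUE))
  }
}

design_from_manifest <- function(data) {
  m <- dataset_manifest(data)
  if (is.null(m) || is.null(m$design)) return(NULL)
  d <- m$design
  structure(list(cells_per_ml = d$cells_per_ml, moi = d$moi,
                 times = as.numeric(d$times),
                 replicates = as.integer(d$replicates),
                 dilution_time = d$dilution_time,
                 dilution_factor = d$dilution_factor,
                 moi_convention = d$moi_convention %||% "flask_wide"),
            class = "experiment_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-likelihood builder for community time-series data
#'
#' Returns a closure over the community SEIV(D) model. The parameter vector
#' holds per-pair traits named `phi_<host>|<phage>`, `tau_...`, `beta_...`,
#' one shared `n_e` (one latent-period CV across pairs), per-host
#' `d_c_<host>` when `fit_d_c` is TRUE, and a shared `sigma`.
#'
#' @param data Community `ts_dataset` (observables `qINT` per host, `qEXT`
#'   per phage).
#' @param matrix An [infection_matrix()].
#' @param growth_rates Named per-host growth rates (fixed during the fit).
#' @param design The community [experiment_design()] (defaults to the
#'   manifest's, else [experiment_design()]).
#' @param fit_d_c Include per-host critical debris densities (SEIVD fit,
#'   default TRUE); FALSE fits plain SEIV.
#' @param fit_window Optional upper time bound (hours): only records with
#'   `time_h <= fit_window` enter the likelihood.
#' @param replicates Optional replicate subset to include.
#' @param rtol,atol Solver tolerances used inside the fit.
#' @return `function(params) -> log-likelihood`, with attributes
#'   `pairs` (tibble) and `param_names`.
#' @export
community_loglik <- function(data, matrix, growth_rates, design = NULL,
                             fit_d_c = TRUE, fit_window = NULL,
                             replicates = NULL, rtol = 1e-6, atol = 1e-2) {
  design <- design %||% design_from_manifest(data) %||% experiment_design()
  pairs <- interacting_pairs(matrix)
  obs_ids <- unique(data$id[data$observable %in% c("qINT", "qEXT")])
  known <- c(matrix$hosts, matrix$phages,
             paste0(matrix$hosts, "_control"))
  extra <- setdiff(obs_ids, known)
  if (length(extra)) {
    stop("data contain ids outside the infection matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  sub <- dplyr::filter(tibble::as_tibble(data),
                       .data$observable %in% c("qINT", "qEXT"),
                       !grepl("_control$", .data$id))
  if (!is.null(fit_window)) sub <- sub[sub$time_h <= fit_window + 1e-9, ]
  if (!is.null(replicates)) sub <- sub[sub$replicate %in% replicates, ]
  if ("below_detection" %in% names(sub)) sub <- sub[!sub$below_detection, ]
  sub <- sub[sub$value > 0, ]
  times <- sort(unique(c(0, sub$time_h)))
  pair_lab <- paste0(pairs$host_id, "|", pairs$phage_id)
  param_names <- c(paste0("phi_", pair_lab), paste0("tau_", pair_lab),
                   paste0("beta_", pair_lab), "n_e",
                   if (fit_d_c) paste0("d_c_", matrix$hosts), "sigma")
  hosts <- matrix$hosts; phages <- matrix$phages
  nh <- length(hosts); np <- length(phages); npair <- nrow(pairs)
  host_idx <- match(pairs$host_id, hosts)
  phage_idx <- match(pairs$phage_id, phages)
  r_host <- unname(growth_rates[hosts])
  # observation slots: qINT host i -> slot i; qEXT phage j -> slot nh + j
  obs_t <- match(round(sub$time_h, 9), round(times, 9))
  obs_series <- ifelse(sub$observable == "qINT",
                       match(sub$id, hosts), nh + match(sub$id, phages))
  if (anyNA(obs_series) || anyNA(obs_t)) {
    stop("data ids/times could not be mapped onto the community model",
         call. = FALSE)
  }
  obs_slot <- (obs_series - 1L) * length(times) + obs_t
  obs_log <- log10(sub$value)
  S0 <- rep_len(design$cells_per_ml, nh)
  v_each <- switch(design$moi_convention %||% "flask_wide",
                   flask_wide = design$moi * sum(S0) / np,
                   per_phage = design$moi * sum(S0))
  phi_ix <- paste0("phi_", pair_lab)
  tau_ix <- paste0("tau_", pair_lab)
  beta_ix <- paste0("beta_", pair_lab)
  dc_ix <- paste0("d_c_", hosts)
  # state layout bookkeeping depends only on the (shared, rounded) n_e
  layout_for <- local({
    cache <- list()
    function(n_e) {
      key <- as.character(n_e)
      if (!is.null(cache[[key]])) return(cache[[key]])
      pair_off <- nh + (seq_len(npair) - 1L) * (n_e + 1L)
      v_off <- nh + npair * (n_e + 1L)
      n_state <- v_off + np + 1L
      lay <- list(pair_off = pair_off, v_off = v_off, n_state = n_state,
                  n_e = rep.int(n_e, npair))
      cache[[key]] <<- lay
      lay
    }
  })
  fn <- function(params) {
    phi <- unname(params[phi_ix]); tau <- unname(params[tau_ix])
    beta <- unname(params[beta_ix]); sigma <- params[["sigma"]]
    n_e <- max(0, round(params[["n_e"]]))
    d_c <- if (fit_d_c) unname(params[dc_ix]) else rep(Inf, nh)
    if (!all(is.finite(c(phi, tau, beta, sigma))) || any(phi < 0) ||
        any(tau <= 0) || any(beta < 0) || sigma <= 0 || any(d_c <= 0)) {
      return(-Inf)
    }
    lay <- layout_for(n_e)
    pars <- list(nh = nh, np = np, npair = npair, n_state = lay$n_state,
                 v_off = lay$v_off, host_idx0 = host_idx - 1L,
                 phage_idx0 = phage_idx - 1L, n_e = lay$n_e,
                 pair_off0 = lay$pair_off, r_host = r_host, phi = phi,
                 beta = beta, k = (n_e + 1) / tau, d_c = d_c, hill = 2,
                 adsorb_to_infected = FALSE)
    y0 <- numeric(lay$n_state)
    y0[seq_len(nh)] <- S0
    y0[lay$v_off + seq_len(np)] <- v_each
    st <- tryCatch(dp45_community(y0, times, pars, rtol, atol, -1),
                   error = function(e) NULL)
    if (is.null(st)) return(-Inf)
    nt <- length(times)
    series <- matrix(0, nt, nh + np)
    for (i in seq_len(nh)) series[, i] <- st[, i]
    for (p in seq_len(npair)) {
      cols <- lay$pair_off[p] + seq_len(n_e + 1L)
      chain <- .rowSums(st[, cols, drop = FALSE], nt, n_e + 1L)
      series[, host_idx[p]] <- series[, host_idx[p]] + chain
    }
    for (j in seq_len(np)) series[, nh + j] <- st[, lay$v_off + j]
    mu <- log10(pmax(series[obs_slot], 1e-6))
    sum(stats::dnorm(obs_log, mu, sigma, log = TRUE))
  }
  attr(fn, "pairs") <- pairs
  attr(fn, "param_names") <- param_names
  attr(fn, "design") <- design
  fn
}
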