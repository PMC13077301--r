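new_posterior_ensemble <- function(dram, priors, draws_natural, simulator,
                                   data, label, extra = list()) {
  diag_tbl <- suppressWarnings(gelman_rubin(as.matrix(draws_natural)))
  diag_tbl$ess <- unname(effective_sample_size(as.matrix(draws_natural)))
  structure(c(list(
    draws = tibble::as_tibble(draws_natural),
    log_post = dram$log_post,
    acceptance_rate = dram$acceptance_rate,
    n_steps = dram$n_steps, seed = dram$seed,
    priors = priors, diagnostics = diag_tbl,
    simulator = simulator, data = data, label = label
  ), extra), class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("<posterior_ensemble> %s: %d draws of %d parameters\n",
              x$label, nrow(x$draws), ncol(x$draws)))
  cat(sprintf("  acceptance %.2f, max split-Rhat %.3f\n",
              x$acceptance_rate, max(x$diagnostics$rhat)))
  print(tidy(x), n = 8)
  invisible(x)
}

#' Tidy summary of a posterior ensemble
#'
#' @param x A `posterior_ensemble`.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with per-parameter posterior median, mean, SD, credible
#'   bounds, split-R-hat, and ESS.
#' @export
tidy.posterior_ensemble <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  draws <- as.matrix(x$draws)
  tibble::tibble(
    parameter = colnames(draws),
    median = apply(draws, 2, stats::median),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    conf.low = apply(draws, 2, stats::quantile, probs = a),
    conf.high = apply(draws, 2, stats::quantile, probs = 1 - a),
    rhat = x$diagnostics$rhat,
    ess = x$diagnostics$ess
  )
}

#' One-row summary of a posterior ensemble
#'
#' @param x A `posterior_ensemble`.
#' @param ... Unused.
#' @return Tibble with draw count, acceptance rate, worst R-hat, smallest
#'   ESS, and the maximum log posterior seen.
#' @export
glance.posterior_ensemble <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws),
    n_parameters = ncol(x$draws),
    acceptance_rate = x$acceptance_rate,
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess),
    max_log_post = max(x$log_post)
  )
}

#' Posterior density plot
#'
#' @param object A `posterior_ensemble`.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot with one density panel per parameter.
#' @export
autoplot.posterior_ensemble <- function(object, parameters = NULL, ...) {
  df <- tidyr::pivot_longer(object$draws, dplyr::everything(),
                            names_to = "parameter")
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density")
}

#' Posterior-predictive envelope and coverage
#'
#' Simulates the fitted model at `n_draws` posterior draws, projects the
#' observables, and reports pointwise 2.5/50/97.5 percentile bands plus the
#' fraction of (non-censored) observations falling inside the 95% band.
#'
#' @param ensemble A `posterior_ensemble` from [fit_pairwise_onestep()] or
#'   [fit_community()].
#' @param n_draws Number of posterior draws to simulate (default 100).
#' @param seed Seed for the draw subsample and replicated noise.
#' @param include_noise Add each draw's lognormal measurement noise (its
#'   `sigma`) to the simulated observables (default TRUE), so the band is a
#'   predictive envelope for new observations rather than a credible band of
#'   the latent trajectory.
#' @return A `posterior_predictive` list: `band` (tibble with `q2.5, q50,
#'   q97.5` per time/id/observable) and `coverage`.
#' @export
posterior_predictive <- function(ensemble, n_draws = 100, seed = 1,
                                 include_noise = TRUE) {
  stopifnot(inherits(ensemble, "posterior_ensemble"), nrow(ensemble$draws) > 0)
  n_draws <- min(n_draws, nrow(ensemble$draws))
  all <- with_seed_local(seed, {
    idx <- sample.int(nrow(ensemble$draws), n_draws)
    sims <- purrr::map(idx, function(i) {
      p <- unlist(ensemble$draws[i, ])
      sim <- ensemble$simulator(p)
      if (include_noise && "sigma" %in% names(p)) {
        sim$value <- sim$value * 10^stats::rnorm(nrow(sim), 0, p[["sigma"]])
      }
      sim$draw <- i
      sim
    })
    dplyr::bind_rows(sims)
  })
  band <- all |>
    dplyr::group_by(.data$time_h, .data$id, .data$observable) |>
    dplyr::summarise(
      q2.5 = unname(stats::quantile(.data$value, 0.025)),
      q50 = unname(stats::quantile(.data$value, 0.5)),
      q97.5 = unname(stats::quantile(.data$value, 0.975)),
      .groups = "drop")
  coverage <- NA_real_
  if (!is.null(ensemble$data)) {
    obs <- tibble::as_tibble(ensemble$data)
    if ("below_detection" %in% names(obs)) obs <- obs[!obs$below_detection, ]
    key <- function(df) paste(round(df$time_h, 9), df$id, df$observable)
    m <- match(key(obs), key(band))
    ok <- !is.na(m)
    if (any(ok)) {
      inside <- obs$value[ok] >= band$q2.5[m[ok]] &
        obs$value[ok] <= band$q97.5[m[ok]]
      coverage <- mean(inside)
    }
  }
  structure(list(band = band, coverage = coverage, n_draws = n_draws),
            class = "posterior_predictive")
}

#' @export
print.posterior_predictive <- function(x, ...) {
  cat(sprintf("<posterior_predictive> %d draws, 95%% band coverage %.3f\n",
              x$n_draws, x$coverage))
  invisible(x)
}

#' Plot a posterior-predictive envelope over the data
#'
#' @param object A `posterior_predictive`.
#' @param data Optional observed `ts_dataset` overlaid as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.posterior_predictive <- function(object, data = NULL, ...) {
  g <- ggplot2::ggplot(object$band,
                       ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$q2.5, 1),
                                      ymax = pmax(.data$q97.5, 1)),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = pmax(.data$q50, 1))) +
    ggplot2::facet_grid(observable ~ id, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "density (per ml)")
  if (!is.null(data)) {
    g <- g + ggplot2::geom_point(data = tibble::as_tibble(data),
                                 ggplot2::aes(y = pmax(.data$value, 1)),
                                 size = 0.7)
  }
  g
}
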