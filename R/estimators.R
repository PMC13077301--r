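#' Conventional growth-rate estimate from a growth curve
#'
#' Least-squares slope of log density versus time over an exponential-phase
#' window. If no window is given, the longest contiguous run of points whose
#' log-linear fit comes within 0.002 of the maximum R-squared over all
#' candidate windows is used. Replicates are pooled into one regression.
#'
#' @param series Data frame with columns `time_h` and `value` (optionally
#'   `replicate`); densities must be positive inside the window.
#' @param window Optional numeric length-2 vector of time bounds (hours)
#'   delimiting the exponential phase.
#' @param min_points Minimum window size for automatic selection (default 4).
#' @return A one-row tibble: `r` (per hour), `doubling_time_h`, `r_se`,
#'   `r_squared`, `window_start`, `window_end`, `n_points`.
#' @examples
#' d <- tibble::tibble(time_h = 0:8, value = 1e6 * exp(0.18 * (0:8)))
#' estimate_growth_rate(d)$r # 0.18
#' @export
estimate_growth_rate <- function(series, window = NULL, min_points = 4) {
  stopifnot(all(c("time_h", "value") %in% names(series)))
  df <- tibble::as_tibble(series)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    df <- dplyr::filter(df, .data$time_h >= window[1],
                        .data$time_h <= window[2])
    if (nrow(df) < 3) stop("window contains fewer than 3 readings",
                           call. = FALSE)
    if (any(df$value <= 0)) {
      stop("non-positive densities inside the fitting window", call. = FALSE)
    }
  } else {
    df <- select_exponential_window(df, min_points)
  }
  fit <- stats::lm(log(value) ~ time_h, data = df)
  r <- unname(stats::coef(fit)[2])
  if (!is.na(r) && r <= 0) {
    warning("estimated growth rate is <= 0; reporting as-is", call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit)) # noise-free fits warn cosmetically
  tibble::tibble(
    r = r,
    doubling_time_h = log(2) / r,
    r_se = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    window_start = min(df$time_h), window_end = max(df$time_h),
    n_points = nrow(df)
  )
}

# longest contiguous window (over distinct times) whose pooled log-linear fit
# comes within 0.002 of the best R-squared among all candidate windows
select_exponential_window <- function(df, min_points = 4) {
  df <- dplyr::filter(df, .data$value > 0)
  tt <- sort(unique(df$time_h))
  if (length(tt) < 3) stop("fewer than 3 positive readings", call. = FALSE)
  min_points <- min(min_points, length(tt))
  cand <- list()
  for (i in seq_along(tt)) {
    for (j in seq_along(tt)) {
      if (j - i + 1 < min_points) next
      sub <- df[df$time_h >= tt[i] & df$time_h <= tt[j], ]
      fit <- stats::lm(log(value) ~ time_h, data = sub)
      r2 <- suppressWarnings(summary(fit))$r.squared
      cand[[length(cand) + 1]] <- c(i = i, j = j, r2 = r2, len = j - i + 1)
    }
  }
  if (!length(cand)) return(df)
  cand <- do.call(rbind, cand)
  best_r2 <- max(cand[, "r2"], na.rm = TRUE)
  ok <- cand[cand[, "r2"] >= best_r2 - 0.002 | is.na(cand[, "r2"]), ,
             drop = FALSE]
  pick <- ok[order(-ok[, "len"], ok[, "i"]), , drop = FALSE][1, ]
  df[df$time_h >= tt[pick["i"]] & df$time_h <= tt[pick["j"]], ]
}

#' Conventional adsorption-rate estimate
#'
#' Free phage decaying onto a constant background of cells follow
#' `V(t) = V0 * exp(-phi * B * t)`; the adsorption rate is recovered as
#' minus the least-squares slope of `log(V)` versus time divided by the
#' cell density `B`.
#'
#' @param series Data frame with columns `time_h` and `value` (free-phage
#'   density, > 0; replicates pooled).
#' @param cell_density Background cell density B (cells/ml, > 0).
#' @return A one-row tibble: `phi` (ml/hour), `phi_se`, `r_squared`,
#'   `n_points`.
#' @examples
#' tt <- seq(0, 0.4, by = 0.05)
#' d <- tibble::tibble(time_h = tt, value = 1e7 * exp(-2e-7 * 1e8 * tt))
#' estimate_adsorption_rate(d, cell_density = 1e8)$phi # 2e-7
#' @export
estimate_adsorption_rate <- function(series, cell_density) {
  stopifnot(all(c("time_h", "value") %in% names(series)))
  if (!is.numeric(cell_density) || length(cell_density) != 1 ||
      cell_density <= 0) {
    stop("`cell_density` must be a single positive value", call. = FALSE)
  }
  df <- tibble::as_tibble(series)
  if (any(df$value <= 0)) {
    stop("free-phage densities must be positive for the log-linear fit",
         call. = FALSE)
  }
  fit <- stats::lm(log(value) ~ time_h, data = df)
  slope <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    phi = -slope / cell_density,
    phi_se = sm$coefficients[2, 2] / cell_density,
    r_squared = sm$r.squared,
    n_points = nrow(df)
  )
}

#' Conventional (first-rise) latent-period estimate
#'
#' Operationalises "time before a significant increase in phage
#' concentration": the baseline mean and across-replicate SD are computed
#' from the first `baseline_points` sampling times; the latent period is the
#' earliest time at which the replicate-mean free phage exceeds
#' `baseline mean + z * baseline SD`, linearly interpolated between the
#' bracketing samples. Because the earliest-lysing cells burst before the
#' mean of the latent-period distribution, this first-rise estimate is
#' biased low whenever the latent-period CV is positive.
#'
#' @param series Data frame with columns `time_h`, `value` and optionally
#'   `replicate` (free phage).
#' @param z Detection threshold in baseline SDs (default 3).
#' @param baseline_points Number of initial sampling times forming the
#'   baseline (default 3, minimum 2).
#' @return A one-row tibble: `latent_period_h` (NA if no rise detected),
#'   `no_burst` flag, `threshold`, `baseline_mean`, `baseline_sd`.
#' @export
estimate_latent_period <- function(series, z = 3, baseline_points = 3) {
  stopifnot(all(c("time_h", "value") %in% names(series)))
  if (baseline_points < 2) stop("need >= 2 baseline time points",
                                call. = FALSE)
  df <- tibble::as_tibble(series)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  prof <- df |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(.data$time_h)
  if (nrow(prof) < baseline_points + 1) {
    stop("too few time points to establish a baseline and detect a rise",
         call. = FALSE)
  }
  base <- prof[seq_len(baseline_points), ]
  base_mean <- mean(base$mean)
  base_sd <- stats::sd(df$value[df$time_h %in% base$time_h])
  if (!is.finite(base_sd)) base_sd <- 0
  threshold <- base_mean + z * base_sd
  above <- prof$mean > threshold
  above[seq_len(baseline_points)] <- FALSE
  result <- function(lp, none) {
    tibble::tibble(latent_period_h = lp, no_burst = none,
                   threshold = threshold, baseline_mean = base_mean,
                   baseline_sd = base_sd)
  }
  if (!any(above)) return(result(NA_real_, TRUE))
  k <- which(above)[1]
  t1 <- prof$time_h[k - 1]; t2 <- prof$time_h[k]
  v1 <- prof$mean[k - 1]; v2 <- prof$mean[k]
  lp <- if (v2 > v1) t1 + (threshold - v1) / (v2 - v1) * (t2 - t1) else t2
  lp <- min(max(lp, t1), t2)
  result(lp, FALSE)
}

#' Conventional burst-size estimate
#'
#' `beta = (<V2> - <V1>) / (<T1> - <V1>)`, where `V1`/`V2` are free-phage
#' densities before/after the burst event and `T1` the total-phage density
#' before the burst; averages are over the supplied time points and
#' replicates. The denominator `<T1> - <V1>` is the density of infected
#' centres.
#'
#' @param v1,v2,t1 Numeric vectors of pre-burst free, post-burst free, and
#'   pre-burst total phage densities (any mix of time points/replicates).
#' @return A one-row tibble: `beta`, `infected_centers`, and the three means.
#' @examples
#' conventional_burst_size(1e5, 6e5, 1.1e5)$beta # 50
#' @export
conventional_burst_size <- function(v1, v2, t1) {
  m_v1 <- mean(v1); m_v2 <- mean(v2); m_t1 <- mean(t1)
  if (!(m_t1 > m_v1)) {
    stop("no measurable infected centers: mean(T1) must exceed mean(V1)",
         call. = FALSE)
  }
  tibble::tibble(beta = (m_v2 - m_v1) / (m_t1 - m_v1),
                 infected_centers = m_t1 - m_v1,
                 v1_mean = m_v1, v2_mean = m_v2, t1_mean = m_t1)
}

#' OD600-to-CFU calibration
#'
#' Fits a log-log linear regression of CFU on OD600 from paired calibration
#' points and returns a prediction function.
#'
#' @param od,cfu Positive paired calibration readings.
#' @return A list with the fitted `slope`, `intercept` (log10 scale), and a
#'   `predict(od)` function returning CFU/ml.
#' @export
od_to_cfu_calibration <- function(od, cfu) {
  stopifnot(length(od) == length(cfu), all(od > 0), all(cfu > 0),
            length(od) >= 2)
  fit <- stats::lm(log10(cfu) ~ log10(od))
  co <- stats::coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       predict = function(od_new) unname(10^(co[1] + co[2] * log10(od_new))))
}

#' All conventional trait estimates from a set of assays
#'
#' Convenience wrapper combining the four conventional estimators on tidy
#' assay data.
#'
#' @param growth,adsorption,onestep Optional tidy assay tibbles
#'   (`time_h, replicate, value`).
#' @param cell_density Cell background for the adsorption assay.
#' @param onestep_windows List with integer vectors `v1`, `v2`, `t1` of time
#'   indices (into the sorted unique one-step sampling times) forming the
#'   pre-/post-burst averaging windows; default: `v1`/`t1` from pre-rise
#'   points, `v2` from the final quarter of the series.
#' @param dilution_time One-step adsorption-phase end (hours); samples before
#'   it are excluded from the latent-period and burst-size estimates. Taken
#'   from the dataset manifest when available, else 0.
#' @return A one-row tibble of the available estimates.
#' @export
estimate_traits <- function(growth = NULL, adsorption = NULL, onestep = NULL,
                            cell_density = NULL, onestep_windows = NULL,
                            dilution_time = NULL) {
  out <- tibble::tibble(.rows = 1)
  if (!is.null(growth)) {
    out <- dplyr::bind_cols(out, estimate_growth_rate(growth))
  }
  if (!is.null(adsorption)) {
    out <- dplyr::bind_cols(out,
                            estimate_adsorption_rate(adsorption, cell_density))
  }
  if (!is.null(onestep)) {
    if (is.null(dilution_time)) {
      des <- design_from_manifest(onestep)
      dilution_time <- if (is.null(des)) 0 else des$dilution_time %||% 0
    }
    onestep <- dplyr::filter(onestep,
                             .data$time_h >= dilution_time - 1e-12)
    free <- dplyr::filter(onestep, .data$observable == "PFU_free")
    total <- dplyr::filter(onestep, .data$observable == "PFU_total")
    lp <- estimate_latent_period(free)
    out <- dplyr::bind_cols(out, lp[, c("latent_period_h", "no_burst")])
    tt <- sort(unique(free$time_h))
    if (is.null(onestep_windows)) {
      prof <- vapply(tt, function(t) mean(free$value[free$time_h == t]),
                     numeric(1))
      pre <- seq_len(min(3, length(tt) - 1))
      if (!lp$no_burst) {
        pre <- pre[tt[pre] < lp$latent_period_h]
        if (length(pre) < 2) pre <- seq_len(2)
      }
      # post-burst window: first flattening of the free-phage profile after
      # the rise (guards against secondary infection cycles inflating the
      # plateau)
      after <- if (!lp$no_burst) which(tt > lp$latent_period_h) else
        seq(ceiling(3 * length(tt) / 4), length(tt))
      flat <- after[which(diff(prof)[pmin(after, length(tt) - 1)] <
                            0.1 * prof[after])]
      k <- if (length(flat)) flat[1] + 1 else ceiling(3 * length(tt) / 4)
      post <- seq(min(k, length(tt)), min(k + 2, length(tt)))
      onestep_windows <- list(v1 = pre, v2 = post, t1 = pre)
    }
    bs <- conventional_burst_size(
      v1 = free$value[free$time_h %in% tt[onestep_windows$v1]],
      v2 = free$value[free$time_h %in% tt[onestep_windows$v2]],
      t1 = total$value[total$time_h %in% tt[onestep_windows$t1]]
    )
    out <- dplyr::bind_cols(out, bs["beta"])
  }
  out
}
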