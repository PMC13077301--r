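#' Sampling schedule for a time-series experiment
#'
#' Regular grid `0, dt, 2*dt, ...` up to and including the last multiple of
#' the interval that does not exceed the duration. A 35-minute interval over
#' 15.75 h gives 28 points.
#'
#' @param interval Sampling interval (hours, > 0).
#' @param duration Experiment duration (hours, >= 0).
#' @return Numeric time grid (hours).
#' @examples
#' length(sampling_schedule(35 / 60, 15.75)) # 28
#' @export
sampling_schedule <- function(interval, duration) {
  stopifnot(is.numeric(interval), length(interval) == 1)
  if (!is.finite(interval) || interval <= 0) {
    stop("sampling interval must be > 0", call. = FALSE)
  }
  stopifnot(duration >= 0)
  n <- floor(duration / interval + 1e-9)
  seq(0, n) * interval
}

#' Experiment design descriptor
#'
#' Captures the sampling design of an infection experiment: initial cell
#' density per strain, MOI per phage, sampling grid, replicate count, and any
#' dilution events (time, multiplicative factor applied to all state
#' variables) such as the 1:100 dilution ending the adsorption phase of a
#' one-step growth experiment.
#'
#' @param cells_per_ml Initial density per bacterial strain (cells/ml).
#' @param moi Multiplicity of infection (phage per cell at inoculation).
#' @param interval,duration Sampling interval and duration (hours); ignored
#'   if `times` is given.
#' @param times Explicit sampling times (hours), overriding
#'   `interval`/`duration`.
#' @param replicates Number of experimental replicates (>= 1).
#' @param dilution_time,dilution_factor Optional single dilution event; e.g.
#'   `dilution_time = 0.25, dilution_factor = 1e-2` for a 15-min adsorption
#'   phase followed by a 1:100 dilution.
#' @param moi_convention `"per_phage"`: each phage added at `moi` times the
#'   total cell density; `"flask_wide"`: the *total* phage inoculum is `moi`
#'   times the total cell density, split equally across phage strains
#'   (default; matches a community inoculation of 2e8 total phage against
#'   2e9 total cells at MOI 0.1).
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(cells_per_ml = 2e6, moi = 0.1,
                              interval = 35 / 60, duration = 15.75,
                              times = NULL, replicates = 3,
                              dilution_time = NULL, dilution_factor = 1e-2,
                              moi_convention = c("flask_wide", "per_phage")) {
  moi_convention <- match.arg(moi_convention)
  stopifnot(moi >= 0, replicates >= 1, cells_per_ml > 0)
  if (is.null(times)) times <- sampling_schedule(interval, duration)
  stopifnot(length(times) >= 1, all(diff(times) > 0))
  if (!is.null(dilution_time)) {
    stopifnot(dilution_factor > 0, dilution_factor <= 1)
    if (dilution_time > max(times)) {
      stop("dilution time falls beyond the experiment duration", call. = FALSE)
    }
  }
  structure(list(cells_per_ml = cells_per_ml, moi = moi, times = times,
                 replicates = as.integer(replicates),
                 dilution_time = dilution_time,
                 dilution_factor = dilution_factor,
                 moi_convention = moi_convention),
            class = "experiment_design")
}

#' Measurement noise model
#'
#' Multiplicative lognormal measurement noise: observed densities are
#' `true * 10^eps` with `eps ~ Normal(0, sigma)` on the log10 scale, then
#' left-censored at a detection floor (censored records keep the floor value
#' and are flagged `below_detection`).
#'
#' @param sigma SD of the log10 measurement error (default 0.15, resembling
#'   qPCR replicate scatter).
#' @param floor Detection limit (per ml, default 100).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = 0.15, floor = 100) {
  stopifnot(sigma >= 0, floor >= 0)
  structure(list(sigma = sigma, floor = floor), class = "noise_model")
}

#' Initial community state from an MOI specification
#'
#' Translates a per-strain cell density and an MOI into the initial state of
#' the community model: susceptible hosts at the supplied densities, free
#' virions split across phage strains (see `moi_convention` in
#' [experiment_design()]), and empty infection/debris compartments.
#'
#' @param layout A [community_layout()].
#' @param cells_per_ml Per-host initial densities (scalar recycled, or named
#'   vector).
#' @param moi Multiplicity of infection (>= 0).
#' @param moi_convention `"flask_wide"` (default) or `"per_phage"`; see
#'   [experiment_design()].
#' @return Named community state vector.
#' @examples
#' lay <- community_layout(default_trait_table(), default_infection_matrix())
#' y0 <- initial_conditions_from_moi(lay, 2e6, 0.1)
#' sum(y0[grepl("^V", names(y0))]) / sum(y0[grepl("^S", names(y0))]) # 0.1
#' @export
initial_conditions_from_moi <- function(layout, cells_per_ml, moi,
                                        moi_convention = c("flask_wide",
                                                           "per_phage")) {
  moi_convention <- match.arg(moi_convention)
  stopifnot(moi >= 0)
  nh <- length(layout$hosts); np <- length(layout$phages)
  S <- rep_len(cells_per_ml, nh)
  names(S) <- layout$hosts
  if (!is.null(names(cells_per_ml))) S[names(cells_per_ml)] <- cells_per_ml
  total_cells <- sum(S)
  v_each <- switch(moi_convention,
    flask_wide = moi * total_cells / np,
    per_phage = moi * total_cells
  )
  V <- stats::setNames(rep(v_each, np), layout$phages)
  community_state(layout, S = S, V = V, D = 0)
}

# apply lognormal noise + detection floor to a tibble with a value column
apply_noise <- function(df, noise) {
  if (noise$sigma > 0) {
    df$value <- df$value * 10^stats::rnorm(nrow(df), 0, noise$sigma)
  }
  df$below_detection <- df$value < noise$floor
  df$value[df$below_detection] <- noise$floor
  df
}

new_ts_dataset <- function(records, manifest) {
  records <- dplyr::arrange(records, .data$observable, .data$id,
                            .data$replicate, .data$time_h)
  structure(tibble::as_tibble(records), manifest = manifest,
            class = c("ts_dataset", class(tibble::tibble())))
}

#' Plot a time-series dataset
#'
#' @param object A `ts_dataset`.
#' @param ... Unused.
#' @return A ggplot of log10 density vs time, faceted by observable, one
#'   colour per population, points per replicate.
#' @export
autoplot.ts_dataset <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h,
                                       y = pmax(.data$value, 1),
                                       colour = .data$id,
                                       shape = factor(.data$replicate))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "density (per ml)",
                  shape = "replicate")
}

#' Manifest of a generated dataset
#'
#' @param x A `ts_dataset`.
#' @return The provenance manifest list (scenario, design, ground-truth
#'   traits, noise model, seed) attached at generation time, or NULL for
#'   datasets read from unannotated files.
#' @export
dataset_manifest <- function(x) attr(x, "manifest")

#' Simulate a one-step growth experiment (noise-free core)
#'
#' SEIV(D) dynamics through a high-density adsorption phase followed by an
#' instantaneous dilution of all state variables, evaluated on the design's
#' sampling grid.
#'
#' @param traits A [trait_set()].
#' @param design An [experiment_design()] with a dilution event.
#' @param rtol,atol Solver tolerances.
#' @return A list of `sim_trajectory` segments (`pre`, `post`) plus the
#'   projected free/total phage series on the sampling grid (tibble).
#' @keywords internal
simulate_onestep <- function(traits, design, rtol = 1e-6, atol = 1e-2) {
  stopifnot(!is.null(design$dilution_time))
  model <- pairwise_model(traits)
  t_dil <- design$dilution_time
  S0 <- design$cells_per_ml
  V0 <- design$moi * S0
  times <- design$times
  pre_times <- sort(unique(c(times[times <= t_dil], 0, t_dil)))
  pre <- integrate_dynamics(model, list(S = S0, V = V0), pre_times,
                            rtol = rtol, atol = atol)
  y_dil <- pre$state[length(pre_times), ] * design$dilution_factor
  post_times <- sort(unique(c(t_dil, times[times > t_dil])))
  post <- integrate_dynamics(model, stats::setNames(y_dil, names(y_dil)),
                             post_times, rtol = rtol, atol = atol)
  project <- function(traj, tt, obs) {
    dplyr::filter(observe(traj, obs), .data$time_h %in% tt)
  }
  keep_pre <- times[times <= t_dil & abs(times - t_dil) > 1e-12]
  series <- dplyr::bind_rows(
    project(pre, keep_pre, "free_phage"),
    project(pre, keep_pre, "total_phage"),
    project(post, times[times >= t_dil], "free_phage"),
    project(post, times[times >= t_dil], "total_phage")
  )
  series$observable <- ifelse(series$observable == "free_phage",
                              "PFU_free", "PFU_total")
  list(pre = pre, post = post, series = series)
}

#' One-step growth experiment design
#'
#' Default design of a one-step growth assay: 1e8 cells/ml and MOI 0.1
#' (1e7 phage/ml), a 15-minute adsorption phase, then an instantaneous 1:100
#' dilution, with free and total phage enumerated every 5 minutes for 3 h.
#'
#' @param interval,duration Sampling interval and duration (hours).
#' @param replicates Replicate count (default 3).
#' @return An [experiment_design()].
#' @export
onestep_design <- function(interval = 5 / 60, duration = 3, replicates = 3) {
  experiment_design(cells_per_ml = 1e8, moi = 0.1, interval = interval,
                    duration = duration, replicates = replicates,
                    dilution_time = 0.25, dilution_factor = 1e-2)
}

#' Generate a synthetic one-step growth dataset
#'
#' Simulates the one-step protocol (adsorption phase, 1:100 dilution, free
#' and total phage enumeration) at known ground-truth traits, then applies
#' multiplicative lognormal measurement noise and the detection floor,
#' independently per replicate.
#'
#' @param traits A [trait_set()] (ground truth).
#' @param design An [experiment_design()]; default [onestep_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same inputs and seed reproduce the dataset
#'   exactly.
#' @return A `ts_dataset` tibble (`time_h, id, replicate, observable, value,
#'   below_detection`) with the ground truth recorded in its manifest.
#' @export
generate_onestep <- function(traits, design = onestep_design(),
                             noise = noise_model(), seed = 1) {
  sim <- simulate_onestep(traits, design)
  out <- with_seed_local(seed, {
    purrr::map(seq_len(design$replicates), function(rep) {
      df <- sim$series
      df$replicate <- rep
      apply_noise(df, noise)
    })
  })
  new_ts_dataset(
    dplyr::bind_rows(out),
    manifest = list(scenario = "onestep", design = unclass(design),
                    traits = unclass(traits), noise = unclass(noise),
                    seed = seed)
  )
}

#' Generate a synthetic pairwise multi-cycle infection dataset
#'
#' Emulates a multi-cycle pairwise infection: host at 2e6 cells/ml, one phage
#' at MOI 0.1, host qINT and phage qEXT sampled at a sparse schedule
#' (default 0, 3.5, 15.75 h), plus phage-free control replicates of the host.
#' SEIV vs SEIVD mode follows `traits$d_c`.
#'
#' @inheritParams generate_onestep
#' @param design Default: 2e6 cells/ml, MOI 0.1, samples at 0/3.5/15.75 h,
#'   triplicate.
#' @param controls Include phage-free control replicates (default TRUE),
#'   with ids suffixed `"_control"`.
#' @return A `ts_dataset`.
#' @export
generate_pairwise_multicycle <- function(traits,
                                         design = experiment_design(
                                           cells_per_ml = 2e6, moi = 0.1,
                                           times = c(0, 3.5, 15.75)),
                                         noise = noise_model(), seed = 1,
                                         controls = TRUE) {
  model <- pairwise_model(traits)
  S0 <- design$cells_per_ml
  V0 <- design$moi * S0
  traj <- integrate_dynamics(model, list(S = S0, V = V0), design$times,
                             rtol = 1e-6)
  base <- dplyr::bind_rows(observe(traj, "host_qINT"),
                           observe(traj, "phage_qEXT"))
  base$observable <- ifelse(base$observable == "host_qINT", "qINT", "qEXT")
  ctrl <- NULL
  if (controls) {
    ctrl_traj <- integrate_dynamics(model, list(S = S0, V = 0),
                                    design$times, rtol = 1e-6)
    ctrl <- observe(ctrl_traj, "host_qINT")
    ctrl$observable <- "qINT"
    ctrl$id <- paste0(ctrl$id, "_control")
  }
  out <- with_seed_local(seed, {
    purrr::map(seq_len(design$replicates), function(rep) {
      df <- dplyr::bind_rows(base, ctrl)
      df$replicate <- rep
      apply_noise(df, noise)
    })
  })
  new_ts_dataset(
    dplyr::bind_rows(out),
    manifest = list(scenario = "pairwise_multicycle",
                    design = unclass(design), traits = unclass(traits),
                    noise = unclass(noise), seed = seed)
  )
}

#' Generate a synthetic community experiment dataset
#'
#' Emulates the five-host / five-phage community protocol: all hosts at a
#' common initial density, all phage added at MOI 0.1 (flask-wide
#' convention by default), qINT per host and qEXT per phage sampled every
#' 35 min for 15.75 h (28 points), in triplicate, with lognormal measurement
#' noise. SEIVD ground truth is selected by supplying per-host `d_c`.
#'
#' @param traits Trait table (one row per interacting pair).
#' @param matrix An [infection_matrix()]; default
#'   [default_infection_matrix()].
#' @param design An [experiment_design()]; default the 28-point community
#'   design at 2e6 cells/ml per strain and MOI 0.1.
#' @param d_c Optional named per-host critical debris densities (SEIVD truth).
#' @inheritParams generate_onestep
#' @return A `ts_dataset`.
#' @export
generate_community <- function(traits, matrix = default_infection_matrix(),
                               design = experiment_design(), d_c = NULL,
                               noise = noise_model(), seed = 1) {
  model <- community_model(traits, matrix, d_c = d_c)
  y0 <- initial_conditions_from_moi(model$layout, design$cells_per_ml,
                                    design$moi,
                                    moi_convention = design$moi_convention)
  traj <- integrate_dynamics(model, y0, design$times, rtol = 1e-6)
  base <- dplyr::bind_rows(observe(traj, "host_qINT"),
                           observe(traj, "phage_qEXT"))
  base$observable <- ifelse(base$observable == "host_qINT", "qINT", "qEXT")
  out <- with_seed_local(seed, {
    purrr::map(seq_len(design$replicates), function(rep) {
      df <- base
      df$replicate <- rep
      apply_noise(df, noise)
    })
  })
  new_ts_dataset(
    dplyr::bind_rows(out),
    manifest = list(scenario = "community", design = unclass(design),
                    traits = traits, d_c = d_c, noise = unclass(noise),
                    seed = seed)
  )
}
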