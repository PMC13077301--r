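#' Pairwise infection model specification
#'
#' @param traits A [trait_set()]. `d_c = Inf` gives the SEIV model, a finite
#'   `d_c` the debris-attenuated SEIVD model.
#' @param host_id,phage_id Labels used in observable projections.
#' @param adsorb_to_infected Adsorptive loss of virions to exposed/infected
#'   cells (default FALSE; see [seiv_rhs()]).
#' @return A `pairwise_model` object for [integrate_dynamics()].
#' @export
pairwise_model <- function(traits, host_id = "host", phage_id = "phage",
                           adsorb_to_infected = FALSE) {
  stopifnot(inherits(traits, "trait_set"))
  structure(list(traits = traits, host_id = host_id, phage_id = phage_id,
                 adsorb_to_infected = adsorb_to_infected),
            class = c("pairwise_model", "phage_model"))
}

#' Community infection model specification
#'
#' @inheritParams community_layout
#' @param adsorb_to_infected See [community_rhs()].
#' @return A `community_model` object for [integrate_dynamics()].
#' @export
community_model <- function(traits, matrix, d_c = NULL, hill = 2,
                            growth_rates = NULL, adsorb_to_infected = FALSE) {
  layout <- community_layout(traits, matrix, d_c = d_c, hill = hill,
                             growth_rates = growth_rates)
  structure(list(layout = layout, adsorb_to_infected = adsorb_to_infected),
            class = c("community_model", "phage_model"))
}

default_initial_state <- function(model, S0, V0, D0 = 0) {
  if (inherits(model, "pairwise_model")) {
    pairwise_state(S = S0, V = V0, n_e = model$traits$n_e, D = D0)
  } else {
    community_state(model$layout, S = S0, V = V0, D = D0)
  }
}

rhs_function <- function(model) {
  if (inherits(model, "pairwise_model")) {
    function(y) pairwise_rhs_impl(y, model$traits,
                                  attenuate = is.finite(model$traits$d_c),
                                  adsorb_to_infected = model$adsorb_to_infected)
  } else {
    function(y) community_rhs(y, model$layout,
                              adsorb_to_infected = model$adsorb_to_infected)
  }
}

#' Integrate an infection model over a time grid
#'
#' Solves the model ODEs with an adaptive explicit Dormand-Prince 4(5)
#' scheme (the package default), or with `deSolve`'s `lsoda` or fixed-step
#' `rk4` using the pure-R right-hand sides (useful as an independent check of
#' the compiled path). Negative excursions beyond `-atol` abort with an
#' integration error; smaller ones are clipped to zero on output.
#'
#' @param model A [pairwise_model()] or [community_model()].
#' @param init Named initial state vector ([pairwise_state()] /
#'   [community_state()]), or a list with elements `S`, `V` (and optionally
#'   `D`) from which the state is built.
#' @param times Strictly increasing output time grid (hours), first element
#'   the initial time.
#' @param rtol,atol Relative / absolute solver tolerances (defaults `1e-8`
#'   and `1e-2` in density units).
#' @param engine `"dp45"` (compiled adaptive, default), `"lsoda"` (deSolve,
#'   R rhs), or `"rk4"` (deSolve fixed step, R rhs; step set by `dt`).
#' @param dt Fixed step size for `engine = "rk4"` (default `1e-3` h).
#' @param max_step Upper bound on the adaptive step (hours; default none).
#' @return A `sim_trajectory` object; see [observe()], [generics::tidy()].
#' @examples
#' tr <- trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 9, beta = 50)
#' traj <- integrate_dynamics(pairwise_model(tr), list(S = 2e6, V = 2e5),
#'                            times = seq(0, 16, by = 0.25))
#' @export
integrate_dynamics <- function(model, init, times, rtol = 1e-8, atol = 1e-2,
                               engine = c("dp45", "lsoda", "rk4"), dt = 1e-3,
                               max_step = -1) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "phage_model"))
  if (is.list(init) && !is.null(init$S)) {
    vals <- unlist(init[c("S", "V", "D")])
    if (any(!is.finite(vals)) || any(vals < 0)) {
      stop("initial state must be finite and non-negative", call. = FALSE)
    }
    init <- default_initial_state(model, init$S, init$V,
                                  D0 = if (is.null(init$D)) 0 else init$D)
  }
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with >= 2 points", call. = FALSE)
  }
  if (any(!is.finite(init)) || any(init < 0)) {
    stop("initial state must be finite and non-negative", call. = FALSE)
  }
  sol <- switch(engine,
    dp45 = integrate_dp45(model, init, times, rtol, atol, max_step),
    lsoda = integrate_desolve(model, init, times, rtol, atol, "lsoda", dt),
    rk4 = integrate_desolve(model, init, times, rtol, atol, "rk4", dt)
  )
  colnames(sol) <- names(init)
  neg <- min(sol)
  if (neg < -100 * (atol + rtol * max(abs(sol)))) {
    stop(sprintf(paste0("integration failure: negative excursion %.3g ",
                        "beyond solver tolerance"), neg), call. = FALSE)
  }
  sol[sol < 0] <- 0
  structure(list(time = times, state = sol, model = model,
                 solver = list(engine = engine, rtol = rtol, atol = atol)),
            class = "sim_trajectory")
}

integrate_dp45 <- function(model, init, times, rtol, atol, max_step) {
  if (inherits(model, "pairwise_model")) {
    pars <- c(model$traits,
              list(adsorb_to_infected = model$adsorb_to_infected))
    dp45_pairwise(unname(init), times, pars, rtol, atol, max_step)
  } else {
    lay <- model$layout
    pars <- list(
      nh = length(lay$hosts), np = length(lay$phages),
      npair = length(lay$host_idx), n_state = lay$n_state,
      v_off = lay$v_off,
      host_idx0 = as.integer(lay$host_idx - 1L),
      phage_idx0 = as.integer(lay$phage_idx - 1L),
      n_e = as.integer(lay$n_e),
      pair_off0 = as.integer(lay$pair_off),
      r_host = unname(lay$r_host), phi = lay$traits$phi,
      beta = lay$traits$beta, k = lay$k, d_c = unname(lay$d_c),
      hill = lay$hill, adsorb_to_infected = model$adsorb_to_infected
    )
    dp45_community(unname(init), times, pars, rtol, atol, max_step)
  }
}

integrate_desolve <- function(model, init, times, rtol, atol, method, dt) {
  rhs <- rhs_function(model)
  derivs <- function(t, y, parms) list(unname(rhs(y)))
  if (method == "rk4") {
    fine <- seq(times[1], times[length(times)], by = dt)
    if (fine[length(fine)] < times[length(times)]) {
      fine <- c(fine, times[length(times)])
    }
    fine <- sort(unique(c(fine, times)))
    out <- deSolve::ode(unname(init), fine, derivs, parms = NULL,
                        method = "rk4")
    out <- out[match(round(times, 10), round(out[, 1], 10)), , drop = FALSE]
  } else {
    out <- deSolve::ode(unname(init), times, derivs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
  }
  istate <- attr(out, "istate")
  if ((!is.null(istate) && is.finite(istate[1]) && istate[1] < 0) ||
      nrow(out) < length(times) || anyNA(out)) {
    stop("integration failure in deSolve at t = ",
         out[nrow(out), 1], call. = FALSE)
  }
  unclass(out)[, -1, drop = FALSE]
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("<sim_trajectory> %s, %d states, %d time points (%.3g-%.3g h)\n",
              class(x$model)[1], ncol(x$state), length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated trajectory into long format
#'
#' @param x A `sim_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_h`, `variable`, `value`.
#' @export
tidy.sim_trajectory <- function(x, ...) {
  tibble::tibble(
    time_h = rep(x$time, times = ncol(x$state)),
    variable = rep(colnames(x$state), each = length(x$time)),
    value = as.vector(x$state)
  )
}

trajectory_ids <- function(traj) {
  m <- traj$model
  if (inherits(m, "pairwise_model")) {
    list(hosts = m$host_id, phages = m$phage_id)
  } else {
    list(hosts = m$layout$hosts, phages = m$layout$phages)
  }
}

#' Project a trajectory onto a measurable observable
#'
#' Maps model states onto what the assays measure: `free_phage` (and its
#' qPCR analogue `phage_qEXT`) is the free-virion density V; `total_phage`
#' adds infected centres, counting each exposed/infected cell once
#' (V + sum(E) + I); `host_qINT` is the intracellular signal per host
#' (S + sum over its pairs of E and I); `total_host` sums `host_qINT` over
#' hosts.
#'
#' @param traj A `sim_trajectory` from [integrate_dynamics()].
#' @param observable One of `"free_phage"`, `"total_phage"`, `"host_qINT"`,
#'   `"phage_qEXT"`, `"total_host"`.
#' @return A tibble with columns `time_h`, `id`, `observable`, `value`.
#' @export
observe <- function(traj, observable) {
  stopifnot(inherits(traj, "sim_trajectory"))
  choices <- c("free_phage", "total_phage", "host_qINT", "phage_qEXT",
               "total_host")
  if (!is.character(observable) || length(observable) != 1 ||
      !observable %in% choices) {
    stop("unknown observable; must be one of: ",
         paste(choices, collapse = ", "), call. = FALSE)
  }
  st <- traj$state
  ids <- trajectory_ids(traj)
  m <- traj$model
  series <- function(id, values) {
    tibble::tibble(time_h = traj$time, id = id, observable = observable,
                   value = unname(values))
  }
  if (inherits(m, "pairwise_model")) {
    n_e <- m$traits$n_e
    e_cols <- if (n_e > 0) 1L + seq_len(n_e) else integer(0)
    chain <- if (length(e_cols)) {
      rowSums(st[, e_cols, drop = FALSE]) + st[, n_e + 2L]
    } else st[, n_e + 2L]
    out <- switch(observable,
      free_phage = series(ids$phages, st[, n_e + 3L]),
      phage_qEXT = series(ids$phages, st[, n_e + 3L]),
      total_phage = series(ids$phages, st[, n_e + 3L] + chain),
      host_qINT = series(ids$hosts, st[, 1L] + chain),
      total_host = series("total", st[, 1L] + chain)
    )
    return(out)
  }
  lay <- m$layout
  nh <- length(lay$hosts); np <- length(lay$phages)
  pair_chain <- function(p) {
    cols <- lay$pair_off[p] + seq_len(lay$n_e[p] + 1L)
    rowSums(st[, cols, drop = FALSE])
  }
  host_int <- function(i) {
    tot <- st[, i]
    for (p in which(lay$host_idx == i)) tot <- tot + pair_chain(p)
    tot
  }
  if (observable %in% c("free_phage", "phage_qEXT")) {
    out <- purrr::map(seq_len(np),
                      ~ series(lay$phages[.x], st[, lay$v_off + .x]))
  } else if (observable == "total_phage") {
    out <- purrr::map(seq_len(np), function(j) {
      tot <- st[, lay$v_off + j]
      for (p in which(lay$phage_idx == j)) tot <- tot + pair_chain(p)
      series(lay$phages[j], tot)
    })
  } else if (observable == "host_qINT") {
    out <- purrr::map(seq_len(nh), ~ series(lay$hosts[.x], host_int(.x)))
  } else { # total_host
    tot <- 0
    for (i in seq_len(nh)) tot <- tot + host_int(i)
    out <- list(series("total", tot))
  }
  dplyr::bind_rows(out)
}

#' Plot the observable projections of a trajectory
#'
#' @param object A `sim_trajectory`.
#' @param observables Character vector of observables to show (default host
#'   qINT and free phage).
#' @param ... Unused.
#' @return A ggplot object (log10 density vs time).
#' @export
autoplot.sim_trajectory <- function(object,
                                    observables = c("host_qINT", "free_phage"),
                                    ...) {
  df <- dplyr::bind_rows(purrr::map(observables, ~ observe(object, .x)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h,
                                   y = pmax(.data$value, 1),
                                   colour = .data$id,
                                   linetype = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "density (per ml)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
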