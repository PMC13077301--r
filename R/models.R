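#' Construct a pairwise SEIV/SEIVD state vector
#'
#' The pairwise state tracks susceptible cells (S), a chain of `n_e` exposed
#' stages (E1..En), lysis-committed infected cells (I), free virions (V), and
#' cumulative lysed-cell debris (D). All densities are per ml.
#'
#' @param S Susceptible density (cells/ml).
#' @param V Free-virion density (virions/ml).
#' @param n_e Number of exposed stages (default 0 exposed densities).
#' @param E Exposed-stage densities, length `n_e` (default zeros).
#' @param I Infected density (default 0).
#' @param D Debris density (default 0).
#' @return Named numeric state vector `S, E1..En, I, V, D`.
#' @export
pairwise_state <- function(S, V, n_e = length(E), E = numeric(n_e), I = 0,
                           D = 0) {
  stopifnot(length(E) == n_e, all(is.finite(c(S, E, I, V, D))),
            all(c(S, E, I, V, D) >= 0))
  y <- c(S = S, stats::setNames(E, paste0("E", seq_len(n_e))[seq_along(E)]),
         I = I, V = V, D = D)
  y
}

# split a flat pairwise state vector into components
split_pairwise_state <- function(state, n_e) {
  n_e <- as.integer(n_e)
  stopifnot(length(state) == n_e + 4L)
  list(S = state[[1L]],
       E = if (n_e > 0) unname(state[1L + seq_len(n_e)]) else numeric(0),
       I = state[[n_e + 2L]], V = state[[n_e + 3L]], D = state[[n_e + 4L]])
}

pairwise_rhs_impl <- function(state, traits, attenuate,
                              adsorb_to_infected = FALSE) {
  if (any(is.na(state))) stop("NaN/NA in state", call. = FALSE)
  n_e <- traits$n_e
  s <- split_pairwise_state(state, n_e)
  k <- (n_e + 1) / traits$tau
  theta <- if (attenuate) hill_attenuation(max(s$D, 0), traits$d_c, traits$hill) else 1
  infection <- theta * traits$phi * s$S * s$V
  host_tot <- s$S + sum(s$E) + s$I
  growth <- traits$r * s$S *
    (if (is.finite(traits$carrying_capacity)) 1 - host_tot / traits$carrying_capacity else 1)
  dS <- growth - infection
  if (n_e > 0) {
    dE <- numeric(n_e)
    dE[1] <- infection - k * s$E[1]
    if (n_e > 1) dE[2:n_e] <- k * (s$E[1:(n_e - 1)] - s$E[2:n_e])
    dI <- k * (s$E[n_e] - s$I)
  } else {
    dE <- numeric(0)
    dI <- infection - k * s$I
  }
  adsorption_loss <- theta * traits$phi * s$V *
    (s$S + if (adsorb_to_infected) sum(s$E) + s$I else 0)
  dV <- traits$beta * k * s$I - adsorption_loss
  dD <- k * s$I
  out <- c(dS, dE, dI, dV, dD)
  names(out) <- names(state)
  out
}

#' SEIV right-hand side (pairwise, no debris feedback)
#'
#' Time derivative of the pairwise susceptible-exposed-infected-virus model:
#' \deqn{dS/dt = rS - \phi S V}
#' \deqn{dE_1/dt = \phi S V - k E_1, \quad dE_m/dt = k(E_{m-1} - E_m)}
#' \deqn{dI/dt = k(E_{n_e} - I), \quad dV/dt = \beta k I - \phi S V, \quad
#'       dD/dt = k I}
#' with stage rate \eqn{k = (n_e + 1)/\tau}, so the adsorption-to-lysis chain
#' has mean \eqn{\tau} and CV \eqn{1/\sqrt{n_e + 1}}. Free phage adsorb only
#' to susceptible cells by default (no superinfection of exposed/infected
#' cells); set `adsorb_to_infected = TRUE` to add an adsorptive sink on E and
#' I cells.
#'
#' @param state Named state vector from [pairwise_state()].
#' @param traits A [trait_set()].
#' @param adsorb_to_infected Should virions also be lost to exposed/infected
#'   cells (default FALSE)?
#' @return Named derivative vector, same layout as `state`.
#' @export
seiv_rhs <- function(state, traits, adsorb_to_infected = FALSE) {
  pairwise_rhs_impl(state, traits, attenuate = FALSE,
                    adsorb_to_infected = adsorb_to_infected)
}

#' SEIVD right-hand side (pairwise, debris-attenuated infection)
#'
#' Identical to [seiv_rhs()] except every infection flux (the `phi*S*V`
#' terms in dS/dt, dE1/dt, and the adsorption loss in dV/dt) is multiplied by
#' the debris Hill factor [hill_attenuation()] `1/(1 + (D/d_c)^n)`. With
#' `d_c = Inf` this reduces exactly to the SEIV derivative.
#'
#' @inheritParams seiv_rhs
#' @return Named derivative vector, same layout as `state`.
#' @export
seivd_rhs <- function(state, traits, adsorb_to_infected = FALSE) {
  pairwise_rhs_impl(state, traits, attenuate = TRUE,
                    adsorb_to_infected = adsorb_to_infected)
}

#' Community model layout
#'
#' Precomputes the flat state layout of the multi-strain community model:
#' per-host susceptible densities, per-interacting-pair exposed chains and
#' infected densities, per-phage free-virion densities, and one shared debris
#' pool. Pairs outside the infection mask carry no state.
#'
#' @param traits Trait table with one row per interacting pair
#'   (see [trait_table()]); every TRUE entry of `matrix` must have a row.
#' @param matrix An [infection_matrix()].
#' @param d_c Named per-host critical debris concentrations (cells/ml);
#'   `NULL` (default) disables attenuation (SEIV mode, all `Inf`).
#' @param hill Hill coefficient (default 2).
#' @param growth_rates Optional named per-host growth rates (per hour);
#'   default taken from each host's trait rows (0 for a host with no
#'   interacting phage, e.g. in a phage-free control).
#' @return A `community_layout` list with state names and index bookkeeping.
#' @export
community_layout <- function(traits, matrix, d_c = NULL, hill = 2,
                             growth_rates = NULL) {
  stopifnot(inherits(matrix, "infection_matrix"))
  validate_trait_table(traits)
  pairs <- interacting_pairs(matrix)
  key <- paste(traits$host_id, traits$phage_id)
  pkey <- paste(pairs$host_id, pairs$phage_id)
  if (!all(pkey %in% key)) {
    stop("missing traits for interacting pair(s): ",
         paste(setdiff(pkey, key), collapse = "; "), call. = FALSE)
  }
  tr <- traits[match(pkey, key), ]
  hosts <- matrix$hosts; phages <- matrix$phages
  nh <- length(hosts); np <- length(phages); npair <- nrow(tr)
  if (is.null(d_c)) {
    d_c <- stats::setNames(rep(Inf, nh), hosts)
  } else {
    if (is.null(names(d_c)) && length(d_c) == nh) names(d_c) <- hosts
    stopifnot(all(hosts %in% names(d_c)), all(d_c > 0))
    d_c <- d_c[hosts]
  }
  host_idx <- match(tr$host_id, hosts)
  phage_idx <- match(tr$phage_id, phages)
  n_e <- as.integer(tr$n_e)
  # state: S(nh) | per pair: E1..En,I | V(np) | D
  pair_off <- nh + c(0L, cumsum(n_e + 1L))[seq_len(npair)]
  n_state <- nh + sum(n_e + 1L) + np + 1L
  v_off <- nh + sum(n_e + 1L)
  nm <- character(n_state)
  nm[seq_len(nh)] <- paste0("S.", hosts)
  for (p in seq_len(npair)) {
    lab <- paste0(tr$host_id[p], ".", tr$phage_id[p])
    if (n_e[p] > 0) {
      nm[pair_off[p] + seq_len(n_e[p])] <- paste0("E", seq_len(n_e[p]), ".", lab)
    }
    nm[pair_off[p] + n_e[p] + 1L] <- paste0("I.", lab)
  }
  nm[v_off + seq_len(np)] <- paste0("V.", phages)
  nm[n_state] <- "D"
  if (is.null(growth_rates)) {
    growth_rates <- vapply(seq_len(nh), function(i) {
      rows <- which(host_idx == i)
      if (length(rows)) tr$r[rows[1]] else 0
    }, numeric(1))
    names(growth_rates) <- hosts
  } else {
    if (is.null(names(growth_rates)) && length(growth_rates) == nh) {
      names(growth_rates) <- hosts
    }
    stopifnot(all(hosts %in% names(growth_rates)))
    growth_rates <- growth_rates[hosts]
  }
  structure(list(
    hosts = hosts, phages = phages, traits = tr,
    host_idx = host_idx, phage_idx = phage_idx,
    n_e = n_e, k = (n_e + 1) / tr$tau,
    d_c = d_c, hill = hill, r_host = growth_rates,
    pair_off = pair_off, v_off = v_off, n_state = n_state,
    state_names = nm
  ), class = "community_layout")
}

#' Build a community state vector
#'
#' @param layout A [community_layout()].
#' @param S Named per-host susceptible densities (cells/ml).
#' @param V Named per-phage free-virion densities (virions/ml).
#' @param D Shared debris density (default 0). Exposed/infected stages start
#'   at 0.
#' @return Named numeric state vector matching the layout.
#' @export
community_state <- function(layout, S, V, D = 0) {
  stopifnot(inherits(layout, "community_layout"))
  if (is.null(names(S)) && length(S) == length(layout$hosts)) names(S) <- layout$hosts
  if (is.null(names(V)) && length(V) == length(layout$phages)) names(V) <- layout$phages
  stopifnot(all(layout$hosts %in% names(S)), all(layout$phages %in% names(V)))
  y <- numeric(layout$n_state)
  names(y) <- layout$state_names
  y[seq_along(layout$hosts)] <- S[layout$hosts]
  y[layout$v_off + seq_along(layout$phages)] <- V[layout$phages]
  y[layout$n_state] <- D
  y
}

#' Community SEIV/SEIVD right-hand side
#'
#' Scaled-up multi-strain model: each susceptible host population i can be
#' infected by each of its associated phage j (per the infection matrix),
#' with pair-specific traits and exposed-stage chains, a shared cumulative
#' debris pool D, and per-host critical debris concentrations. Multiple
#' infection is excluded: only susceptible cells adsorb virions (optionally
#' exposed/infected cells add an adsorptive sink via `adsorb_to_infected`).
#'
#' \deqn{dS_i/dt = r_i S_i - \sum_j \theta_i(D)\phi_{ij} S_i V_j}
#' \deqn{dV_j/dt = \sum_i \beta_{ij} k_{ij} I_{ij} -
#'                 \sum_i \theta_i(D)\phi_{ij} S_i V_j}
#' \deqn{dD/dt = \sum_{ij} k_{ij} I_{ij}, \qquad
#'       \theta_i(D) = 1/(1 + (D/D_{c_i})^2)}
#' with per-pair chains as in [seiv_rhs()] and \eqn{k_{ij} =
#' (n_e^{ij}+1)/\tau_{ij}}. SEIV mode is the special case of all
#' \eqn{D_{c_i} = \infty} (\eqn{\theta_i \equiv 1}).
#'
#' @param state Named state vector from [community_state()].
#' @param layout A [community_layout()] (carries traits, mask, and `d_c`).
#' @param adsorb_to_infected Should virions also be lost to exposed/infected
#'   cells (default FALSE)?
#' @return Named derivative vector.
#' @export
community_rhs <- function(state, layout, adsorb_to_infected = FALSE) {
  stopifnot(inherits(layout, "community_layout"))
  if (any(is.na(state))) stop("NaN/NA in state", call. = FALSE)
  nh <- length(layout$hosts); np <- length(layout$phages)
  npair <- length(layout$host_idx)
  S <- state[seq_len(nh)]
  V <- state[layout$v_off + seq_len(np)]
  D <- state[[layout$n_state]]
  theta <- vapply(layout$d_c,
                  function(dc) hill_attenuation(max(D, 0), dc, layout$hill),
                  numeric(1))
  dy <- numeric(layout$n_state)
  dS <- unname(layout$r_host) * S
  dV <- numeric(np)
  dD <- 0
  for (p in seq_len(npair)) {
    i <- layout$host_idx[p]; j <- layout$phage_idx[p]
    n_e <- layout$n_e[p]; k <- layout$k[p]
    off <- layout$pair_off[p]
    E <- if (n_e > 0) state[off + seq_len(n_e)] else numeric(0)
    I <- state[[off + n_e + 1L]]
    infection <- theta[i] * layout$traits$phi[p] * S[i] * V[j]
    dS[i] <- dS[i] - infection
    if (n_e > 0) {
      dy[off + 1L] <- infection - k * E[1]
      if (n_e > 1) {
        dy[off + 2:n_e] <- k * (E[1:(n_e - 1)] - E[2:n_e])
      }
      dy[off + n_e + 1L] <- k * (E[n_e] - I)
    } else {
      dy[off + 1L] <- infection - k * I
    }
    sink <- if (adsorb_to_infected) {
      theta[i] * layout$traits$phi[p] * V[j] * (sum(E) + I)
    } else 0
    dV[j] <- dV[j] + layout$traits$beta[p] * k * I - infection - sink
    dD <- dD + k * I
  }
  dy[seq_len(nh)] <- dS
  dy[layout$v_off + seq_len(np)] <- dV
  dy[layout$n_state] <- dD
  names(dy) <- names(state)
  dy
}
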