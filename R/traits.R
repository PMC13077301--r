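#' Life-history trait set for one phage-bacteria pair
#'
#' Bundles the parameters of the SEIV/SEIVD infection model for a single
#' interacting pair: host growth rate, phage adsorption rate, the mean and
#' shape of the Erlang latent-period distribution, burst size, and (for the
#' debris-attenuated SEIVD variant) the critical debris concentration.
#'
#' The latent period is modelled with the linear chain trick: `n_e` exposed
#' stages plus one terminal infected stage, all progressing at rate
#' `(n_e + 1) / tau`, so the adsorption-to-lysis transit time is Erlang with
#' mean `tau` and coefficient of variation `1 / sqrt(n_e + 1)`.
#'
#' @param r Host growth rate (per hour, >= 0).
#' @param phi Adsorption rate (ml/hour, >= 0).
#' @param tau Mean latent period (hours, > 0).
#' @param n_e Number of exposed stages (integer >= 0). Non-integer values are
#'   rounded to the nearest integer (inference treats `n_e` as continuous and
#'   rounds before likelihood evaluation).
#' @param beta Burst size (virions per lysed cell, >= 0).
#' @param d_c Critical debris concentration (cells/ml, > 0) at which the Hill
#'   feedback halves the infection flux; `Inf` (default) disables attenuation,
#'   i.e. plain SEIV.
#' @param hill Hill coefficient of the debris feedback (default 2).
#' @param carrying_capacity Optional logistic carrying capacity (cells/ml) for
#'   host growth; `Inf` (default) gives pure exponential growth.
#'
#' @return An object of class `trait_set` (a named list).
#' @examples
#' trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 99, beta = 50)
#' @export
trait_set <- function(r, phi, tau, n_e, beta, d_c = Inf, hill = 2,
                      carrying_capacity = Inf) {
  n_e <- round(n_e)
  stopifnot(
    is.numeric(r), length(r) == 1, is.finite(r), r >= 0,
    is.numeric(phi), length(phi) == 1, is.finite(phi), phi >= 0,
    is.numeric(tau), length(tau) == 1, is.finite(tau), tau > 0,
    is.numeric(n_e), length(n_e) == 1, n_e >= 0,
    is.numeric(beta), length(beta) == 1, is.finite(beta), beta >= 0,
    is.numeric(d_c), length(d_c) == 1, d_c > 0,
    is.numeric(hill), length(hill) == 1, hill > 0,
    carrying_capacity > 0
  )
  structure(
    list(r = r, phi = phi, tau = tau, n_e = as.integer(n_e), beta = beta,
         d_c = d_c, hill = hill, carrying_capacity = carrying_capacity),
    class = "trait_set"
  )
}

#' @export
print.trait_set <- function(x, ...) {
  cat("<trait_set>\n")
  cat(sprintf("  r    = %g /h   (doubling %.3g h)\n", x$r,
              if (x$r > 0) log(2) / x$r else Inf))
  cat(sprintf("  phi  = %g ml/h\n", x$phi))
  cat(sprintf("  tau  = %g h   (n_e = %d, CV = %.4g)\n", x$tau, x$n_e,
              latent_cv(x$n_e)))
  cat(sprintf("  beta = %g virions/cell\n", x$beta))
  cat(sprintf("  d_c  = %g cells/ml (hill = %g)\n", x$d_c, x$hill))
  invisible(x)
}

#' Coefficient of variation of the Erlang latent period
#'
#' With `n_e` exposed stages plus one infected stage, the transit time from
#' adsorption to lysis is a sum of `n_e + 1` iid exponentials, so its
#' coefficient of variation is `1 / sqrt(n_e + 1)`.
#'
#' @param n_e Number of exposed stages (integer >= 0), vectorised.
#' @return Numeric vector of CVs.
#' @examples
#' latent_cv(99) # 0.1
#' @export
latent_cv <- function(n_e) {
  stopifnot(all(n_e >= 0))
  1 / sqrt(n_e + 1)
}

#' Number of exposed stages giving a target latent-period CV
#'
#' Inverse of [latent_cv()]: `n_e = 1 / cv^2 - 1`, rounded to the nearest
#' non-negative integer.
#'
#' @param cv Target coefficient of variation in (0, 1].
#' @return Integer number of exposed stages.
#' @export
n_e_for_cv <- function(cv) {
  stopifnot(all(cv > 0), all(cv <= 1))
  as.integer(pmax(0, round(1 / cv^2 - 1)))
}

#' Hill attenuation of infection by cellular debris
#'
#' Saturating inhibition factor `1 / (1 + (D / d_c)^n)` applied to the
#' infection (adsorption) flux in the SEIVD model. Equals 1 at zero debris,
#' 1/2 at `D = d_c`, and tends to 0 as debris accumulates. An infinite `d_c`
#' disables attenuation (factor exactly 1).
#'
#' @param d Debris density (cells/ml, >= 0), vectorised.
#' @param d_c Critical (half-saturation) debris concentration (cells/ml, > 0
#'   or `Inf`).
#' @param n Hill coefficient (> 0, default 2).
#' @return Attenuation factor in (0, 1].
#' @examples
#' hill_attenuation(0, 1e6)        # 1
#' hill_attenuation(1e6, 1e6)      # 0.5
#' hill_attenuation(3e6, 1e6)      # 0.1
#' @export
hill_attenuation <- function(d, d_c, n = 2) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("debris density `d` must be finite and >= 0", call. = FALSE)
  }
  if (length(d_c) != 1 || is.na(d_c) || d_c <= 0) {
    stop("`d_c` must be a single positive value (possibly Inf)", call. = FALSE)
  }
  if (n <= 0) stop("hill coefficient `n` must be > 0", call. = FALSE)
  if (is.infinite(d_c)) return(rep(1, length(d)))
  1 / (1 + (d / d_c)^n)
}

#' Per-pair trait table
#'
#' Assembles a tidy trait table (one row per interacting host-phage pair) as
#' consumed by the community model and the synthetic-data generators.
#'
#' @param host_id,phage_id Character vectors identifying each pair.
#' @param r,phi,tau,n_e,beta Trait vectors, recycled to the number of pairs.
#' @return A tibble with columns `host_id, phage_id, r, phi, tau, n_e, beta`.
#' @export
trait_table <- function(host_id, phage_id, r, phi, tau, n_e, beta) {
  tb <- tibble::tibble(
    host_id = as.character(host_id), phage_id = as.character(phage_id),
    r = r, phi = phi, tau = tau, n_e = as.integer(round(n_e)), beta = beta
  )
  validate_trait_table(tb)
  tb
}

validate_trait_table <- function(tb) {
  need <- c("host_id", "phage_id", "r", "phi", "tau", "n_e", "beta")
  missing <- setdiff(need, names(tb))
  if (length(missing)) {
    stop("trait table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tb[c("host_id", "phage_id")])) {
    stop("trait table has duplicated (host_id, phage_id) pairs", call. = FALSE)
  }
  with(tb, stopifnot(all(r >= 0), all(phi >= 0), all(tau > 0), all(n_e >= 0),
                     all(beta >= 0)))
  invisible(tb)
}

#' Apply a community-context trait shift to a trait table
#'
#' Builds a modified copy of a pairwise trait table in which named traits of
#' named pairs are multiplied by stated factors. Used to create
#' community-context ground truths that differ from the pairwise ones, for
#' end-to-end tests of whether the equivalence test detects higher-order
#' trait shifts.
#'
#' @param traits A trait table (see [trait_table()]).
#' @param shifts A data frame with columns `host_id, phage_id, trait, factor`;
#'   an empty data frame (default) returns `traits` unchanged.
#' @return The shifted trait table (tibble).
#' @examples
#' tb <- trait_table("H1", "P1", r = 0.17, phi = 1e-7, tau = 1, n_e = 99, beta = 50)
#' scenario_traitshift(tb, data.frame(host_id = "H1", phage_id = "P1",
#'                                    trait = "beta", factor = 2))
#' @export
scenario_traitshift <- function(traits, shifts = NULL) {
  validate_trait_table(traits)
  if (is.null(shifts) || nrow(shifts) == 0) return(tibble::as_tibble(traits))
  stopifnot(all(c("host_id", "phage_id", "trait", "factor") %in% names(shifts)))
  out <- tibble::as_tibble(traits)
  for (i in seq_len(nrow(shifts))) {
    s <- shifts[i, ]
    row <- which(out$host_id == s$host_id & out$phage_id == s$phage_id)
    if (length(row) != 1) {
      stop("unknown pair in shift spec: ", s$host_id, " x ", s$phage_id,
           call. = FALSE)
    }
    if (!s$trait %in% c("r", "phi", "tau", "beta", "n_e")) {
      stop("unknown trait in shift spec: ", s$trait, call. = FALSE)
    }
    out[row, s$trait] <- out[[s$trait]][row] * s$factor
    if (s$trait == "n_e") out$n_e[row] <- as.integer(round(out$n_e[row]))
  }
  out
}
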