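#' Delayed-rejection adaptive Metropolis (DRAM) sampler
#'
#' Random-walk Metropolis with (i) adaptation of the proposal covariance to
#' the running empirical covariance of the chain (scaled by `2.38^2/d`, with
#' a small diagonal regularisation), starting after an initial warm-up
#' fraction of the chain, and (ii) one delayed-rejection stage: when a
#' proposal is rejected, a second proposal with covariance shrunk by
#' `dr_scale^2` is attempted, accepted with the two-stage probability that
#' preserves detailed balance.
#'
#' @param log_target Function taking a named numeric vector and returning the
#'   log target density (may return `-Inf`).
#' @param init Named numeric initial point (finite log target required).
#' @param n_steps Number of MCMC steps.
#' @param seed Integer seed; the same seed reproduces the chain exactly.
#' @param cov0 Initial proposal covariance (matrix or diagonal vector);
#'   default `diag((0.1 * pmax(abs(init), 0.1))^2)`.
#' @param adapt_start Fraction of the chain before covariance adaptation
#'   begins (default 0.1).
#' @param dr_scale Shrink factor of the delayed-rejection proposal
#'   (default 0.2).
#' @param eps Diagonal regularisation added to the adapted covariance
#'   (default 1e-6).
#' @param burn_in Fraction of the chain discarded as burn-in in `draws`
#'   (default 0.5; the full chain is also returned).
#' @return A `dram_chain` list: `draws` (post burn-in matrix), `chain` (full
#'   matrix including the initial point), `log_post`, `acceptance_rate`,
#'   `n_steps`, `seed`, `settings`.
#' @examples
#' lt <- function(x) -0.5 * sum(x^2)
#' ch <- dram_sample(lt, c(a = 0, b = 0), n_steps = 2000, seed = 1)
#' colMeans(ch$draws)
#' @export
dram_sample <- function(log_target, init, n_steps, seed = 1, cov0 = NULL,
                        adapt_start = 0.1, dr_scale = 0.2, eps = 1e-6,
                        burn_in = 0.5) {
  d <- length(init)
  stopifnot(d >= 1, n_steps >= 10)
  nm <- names(init)
  lp0 <- log_target(init)
  if (!is.finite(lp0)) {
    stop("log target is not finite at the initial point", call. = FALSE)
  }
  if (is.null(cov0)) cov0 <- diag((0.1 * pmax(abs(init), 0.1))^2, d)
  if (is.vector(cov0)) cov0 <- diag(cov0, d)
  sd_scale <- 2.38^2 / d
  chol_of <- function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) R <- chol(S + diag(10 * eps, d))
    R
  }
  with_seed_local(seed, {
    chain <- matrix(NA_real_, n_steps + 1, d, dimnames = list(NULL, nm))
    lps <- numeric(n_steps + 1)
    chain[1, ] <- init
    lps[1] <- lp0
    x <- init; lp_x <- lp0
    # running moments for adaptation
    mean_run <- as.numeric(init)
    ssq <- matrix(0, d, d)
    n_adapt_from <- max(10L, floor(adapt_start * n_steps))
    R1 <- chol_of(cov0)
    accepts <- 0L
    prop <- function(center, R, scale) {
      as.numeric(center) + sqrt(scale) * as.numeric(stats::rnorm(d) %*% R)
    }
    # log density of N(center, scale * R'R) at y, up to the constant shared
    # by the DR numerator/denominator
    ld_gauss <- function(y, center, R, scale) {
      u <- backsolve(R, (y - as.numeric(center)), transpose = TRUE)
      -0.5 * sum(u^2) / scale
    }
    for (t in seq_len(n_steps)) {
      y1 <- stats::setNames(prop(x, R1, sd_scale), nm)
      lp_y1 <- log_target(y1)
      a1 <- min(1, exp(lp_y1 - lp_x))
      if (is.finite(lp_y1) && stats::runif(1) < a1) {
        x <- y1; lp_x <- lp_y1; accepts <- accepts + 1L
      } else {
        # delayed-rejection stage: shrunken proposal from the current point
        y2 <- stats::setNames(prop(x, R1, sd_scale * dr_scale^2), nm)
        lp_y2 <- log_target(y2)
        if (is.finite(lp_y2)) {
          a1_rev <- min(1, exp(lp_y1 - lp_y2)) # alpha1(y2 -> y1)
          num <- lp_y2 + ld_gauss(y1, y2, R1, sd_scale) +
            log1p(-a1_rev + 1e-300)
          den <- lp_x + ld_gauss(y1, x, R1, sd_scale) +
            log1p(-a1 + 1e-300)
          if (stats::runif(1) < exp(num - den)) {
            x <- y2; lp_x <- lp_y2; accepts <- accepts + 1L
          }
        } else {
          stats::runif(1) # keep RNG stream aligned regardless of branch
        }
      }
      chain[t + 1, ] <- x
      lps[t + 1] <- lp_x
      # update running covariance with the new chain state
      nseen <- t + 1
      delta <- as.numeric(x) - mean_run
      mean_run <- mean_run + delta / nseen
      ssq <- ssq + tcrossprod(delta, as.numeric(x) - mean_run)
      if (t >= n_adapt_from) {
        R1 <- chol_of(ssq / (nseen - 1) + diag(eps, d))
      }
    }
    keep <- seq.int(floor(burn_in * n_steps) + 1, n_steps + 1)
    structure(list(
      draws = chain[keep, , drop = FALSE],
      chain = chain, log_post = lps,
      acceptance_rate = accepts / n_steps,
      n_steps = n_steps, seed = seed,
      settings = list(adapt_start = adapt_start, dr_scale = dr_scale,
                      eps = eps, burn_in = burn_in)
    ), class = "dram_chain")
  })
}
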