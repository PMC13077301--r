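#' Split-R-hat convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction factor computed on split chains:
#' each chain is cut in half and the standard between-/within-chain variance
#' ratio is formed over the resulting 2m half-chains.
#'
#' @param chains A matrix (iterations x parameters; split into halves with a
#'   warning), or a list of such matrices with equal dimensions.
#' @return A tibble with `parameter` and `rhat`.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) {
    warning("single chain supplied; splitting into halves", call. = FALSE)
    chains <- list(chains)
  }
  stopifnot(length(chains) >= 1, all(vapply(chains, is.matrix, logical(1))))
  n <- nrow(chains[[1]])
  stopifnot(all(vapply(chains, nrow, integer(1)) == n), n >= 4)
  half <- floor(n / 2)
  halves <- unlist(lapply(chains, function(ch) {
    list(ch[seq_len(half), , drop = FALSE],
         ch[seq.int(n - half + 1, n), , drop = FALSE])
  }), recursive = FALSE)
  p <- ncol(chains[[1]])
  nm <- colnames(chains[[1]]) %||% paste0("par", seq_len(p))
  rhat <- vapply(seq_len(p), function(j) {
    draws <- vapply(halves, function(h) h[, j], numeric(half))
    m <- ncol(draws); nn <- nrow(draws)
    mu_chain <- colMeans(draws)
    B <- nn * stats::var(mu_chain)
    W <- mean(apply(draws, 2, stats::var))
    if (W <= 0) return(if (B > 0) Inf else 1)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }, numeric(1))
  tibble::tibble(parameter = nm, rhat = rhat)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence: the sum
#' of autocorrelations is truncated at the first negative pair of
#' consecutive lags.
#'
#' @param x Numeric draw vector or a matrix (iterations x parameters).
#' @return Numeric ESS (vector for matrices, named by column).
#' @export
effective_sample_size <- function(x) {
  if (is.matrix(x)) {
    return(vapply(seq_len(ncol(x)), function(j) effective_sample_size(x[, j]),
                  numeric(1)) |>
             stats::setNames(colnames(x)))
  }
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}
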