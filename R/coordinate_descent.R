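#' Coordinate-descent minimisation
#'
#' Cyclic single-parameter golden-section line searches: each sweep visits
#' every coordinate in turn, optimising it over a bracket around the current
#' value (clipped to the bounds) and accepting only improvements, so the
#' objective is non-increasing across sweeps. Stops when the relative
#' improvement of a sweep falls below `tol` or after `max_sweeps`.
#'
#' @param fn Objective to minimise: `function(par) -> scalar` (may be `Inf`).
#' @param init Named initial parameter vector.
#' @param lower,upper Bound vectors (recycled).
#' @param span Initial half-width of the per-coordinate search bracket
#'   (recycled; default `pmax(abs(init), 1)`), halved when a sweep brings no
#'   improvement.
#' @param tol Relative-improvement stopping threshold (default 1e-6).
#' @param max_sweeps Sweep cap (default 50).
#' @return List with `par`, `value`, `sweeps`, `improved` (FALSE when no
#'   sweep improved on the initial point), `trace` (objective after each
#'   sweep).
#' @examples
#' fn <- function(p) (p[1] - 2)^2 + 4 * (p[2] + 1)^2
#' coordinate_descent_fit(fn, c(a = 0, b = 0))$par
#' @export
coordinate_descent_fit <- function(fn, init, lower = -Inf, upper = Inf,
                                   span = NULL, tol = 1e-6, max_sweeps = 50) {
  d <- length(init)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(init < lower | init > upper)) {
    stop("initial point outside bounds", call. = FALSE)
  }
  if (is.null(span)) span <- pmax(abs(init), 1)
  span <- rep_len(span, d)
  x <- init
  f <- fn(x)
  if (!is.finite(f)) stop("objective not finite at the initial point",
                          call. = FALSE)
  f_init <- f
  trace <- numeric(0)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    f_before <- f
    for (i in seq_len(d)) {
      lo <- max(lower[i], x[i] - span[i])
      hi <- min(upper[i], x[i] + span[i])
      if (hi <= lo) next
      coord_fn <- function(v) {
        xx <- x; xx[i] <- v
        out <- fn(xx)
        if (!is.finite(out)) 1e300 else out
      }
      opt <- stats::optimize(coord_fn, c(lo, hi), tol = 1e-8)
      if (opt$objective < f) {
        x[i] <- opt$minimum
        f <- opt$objective
        # widen the bracket when the optimum sits at its edge
        if (min(opt$minimum - lo, hi - opt$minimum) < 1e-3 * (hi - lo)) {
          span[i] <- span[i] * 2
        }
      }
    }
    trace <- c(trace, f)
    improvement <- (f_before - f) / max(abs(f_before), 1e-12)
    if (improvement <= 0) span <- span / 2
    if (sweeps >= max_sweeps || (improvement >= 0 && improvement < tol)) break
  }
  list(par = x, value = f, sweeps = sweeps,
       improved = f < f_init, trace = trace)
}
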