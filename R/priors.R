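#' Prior specification for one parameter
#'
#' Two families are supported, matching the inference scheme: `"lognormal"`
#' (parameterised on the log10 scale: `location` is the log10 of the median,
#' `scale` the SD in log10 units; sampled in log10 space) and `"truncnorm"`
#' (truncated normal on the natural scale with bounds `lower`/`upper`).
#'
#' @param family `"lognormal"` or `"truncnorm"`.
#' @param location,scale Location and scale (log10 units for lognormal).
#' @param lower,upper Support bounds (natural scale; lognormal is always
#'   positive, bounds may tighten it further).
#' @return A `prior_spec` object.
#' @examples
#' prior("lognormal", location = log10(50), scale = 0.5)   # burst size
#' prior("truncnorm", location = 1, scale = 0.5, lower = 0) # latent period
#' @export
prior <- function(family = c("lognormal", "truncnorm"), location, scale,
                  lower = if (family == "lognormal") 0 else -Inf,
                  upper = Inf) {
  family <- match.arg(family)
  stopifnot(is.finite(location), is.finite(scale), scale > 0, lower < upper)
  if (family == "lognormal" && lower < 0) lower <- 0
  structure(list(family = family, location = location, scale = scale,
                 lower = lower, upper = upper),
            class = "prior_spec")
}

# transform natural value -> sampling space
to_sampling <- function(p, x) {
  if (p$family == "lognormal") log10(x) else x
}

# transform sampling-space value -> natural
from_sampling <- function(p, z) {
  if (p$family == "lognormal") 10^z else z
}

# log prior density in sampling space (Jacobian absorbed: lognormal sampled
# as a normal on log10 x)
prior_logdensity_sampling <- function(p, z) {
  x <- from_sampling(p, z)
  if (x < p$lower || x > p$upper) return(-Inf)
  stats::dnorm(z, p$location, p$scale, log = TRUE)
}

#' Draw from a prior
#'
#' @param p A [prior()] spec.
#' @param n Number of draws.
#' @return Numeric vector on the natural scale.
#' @export
prior_sample <- function(p, n = 1) {
  stopifnot(inherits(p, "prior_spec"))
  out <- numeric(0)
  while (length(out) < n) {
    z <- stats::rnorm(n, p$location, p$scale)
    x <- from_sampling(p, z)
    out <- c(out, x[x >= p$lower & x <= p$upper])
  }
  out[seq_len(n)]
}

# combined log prior over a named sampling-space vector
priors_logdensity <- function(priors, z) {
  tot <- 0
  for (nm in names(priors)) {
    tot <- tot + prior_logdensity_sampling(priors[[nm]], z[[nm]])
    if (!is.finite(tot)) return(-Inf)
  }
  tot
}
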