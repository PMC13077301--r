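#' Bayesian test of practical equivalence between two posteriors
#'
#' Compares the same trait inferred in two contexts (e.g. pairwise versus
#' community) through the posterior probability of practical equivalence:
#' `p_eq` is the fraction of paired posterior-difference draws falling inside
#' a prespecified region of practical equivalence (ROPE). Positive traits are
#' compared on the log10 scale, so the default half-width 0.1 corresponds to
#' about +/-26% multiplicatively. Pairing is independent with a fixed seed;
#' each ensemble's pairing indices are derived from the same seed applied to
#' its own draw count, making `p_eq` exactly symmetric in its arguments.
#'
#' Verdicts: `"minor difference"` when `p_eq >= minor_threshold` (default
#' 0.95), `"moderate/strong shift"` when `p_eq <= shift_threshold` (default
#' 0.05), otherwise `"inconclusive"`.
#'
#' @param post_a,post_b Posterior draws of the same trait: numeric vectors,
#'   or `posterior_ensemble`s together with `trait`.
#' @param trait Parameter name to extract when ensembles are supplied.
#' @param rope_halfwidth ROPE half-width (log10 units for `log_scale = TRUE`;
#'   default 0.1).
#' @param log_scale Compare on the log10 scale (default TRUE; requires
#'   positive draws).
#' @param n_pairs Number of difference draws (default 4000).
#' @param seed Pairing seed.
#' @param minor_threshold,shift_threshold Verdict cutoffs.
#' @return An `equivalence_result` tibble row: `trait, p_eq, rope_halfwidth,
#'   median_diff, verdict`.
#' @examples
#' a <- rnorm(1000, 1, 0.05); b <- rnorm(1000, 1, 0.05)
#' equivalence_test(10^a, 10^b, trait = "beta")$verdict
#' @export
equivalence_test <- function(post_a, post_b, trait = NULL,
                             rope_halfwidth = 0.1, log_scale = TRUE,
                             n_pairs = 4000, seed = 1,
                             minor_threshold = 0.95, shift_threshold = 0.05) {
  get_draws <- function(p) {
    if (inherits(p, "posterior_ensemble")) {
      if (is.null(trait)) stop("`trait` required with posterior ensembles",
                               call. = FALSE)
      if (!trait %in% names(p$draws)) {
        stop("trait not found in ensemble: ", trait, call. = FALSE)
      }
      p$draws[[trait]]
    } else {
      as.numeric(p)
    }
  }
  a <- get_draws(post_a)
  b <- get_draws(post_b)
  if (!length(a) || !length(b)) stop("empty posterior draws", call. = FALSE)
  if (log_scale) {
    if (any(a <= 0) || any(b <= 0)) {
      stop("log-scale comparison requires positive draws", call. = FALSE)
    }
    a <- log10(a); b <- log10(b)
  }
  # symmetric pairing: each ensemble is resampled with the same seed applied
  # to its own length
  pick <- function(x) x[with_seed_local(seed,
                                        sample.int(length(x), n_pairs,
                                                   replace = TRUE))]
  diff <- pick(a) - pick(b)
  p_eq <- mean(abs(diff) <= rope_halfwidth)
  verdict <- if (p_eq >= minor_threshold) {
    "minor difference"
  } else if (p_eq <= shift_threshold) {
    "moderate/strong shift"
  } else {
    "inconclusive"
  }
  structure(
    tibble::tibble(trait = trait %||% "trait", p_eq = p_eq,
                   rope_halfwidth = rope_halfwidth,
                   median_diff = stats::median(diff),
                   scale = if (log_scale) "log10" else "natural",
                   verdict = verdict),
    class = c("equivalence_result", class(tibble::tibble())))
}

#' Equivalence tests across shared traits of two ensembles
#'
#' Runs [equivalence_test()] for every parameter present in both ensembles
#' (optionally filtered), one row per trait. No multiplicity correction is
#' applied: verdicts are per-trait.
#'
#' @param post_a,post_b `posterior_ensemble`s.
#' @param traits Character vector of parameter names (default: the shared
#'   ones, excluding derived columns).
#' @inheritParams equivalence_test
#' @return A tibble of `equivalence_result` rows.
#' @export
equivalence_table <- function(post_a, post_b, traits = NULL,
                              rope_halfwidth = 0.1, n_pairs = 4000,
                              seed = 1) {
  shared <- intersect(names(post_a$draws), names(post_b$draws))
  shared <- setdiff(shared, c("n_e_rounded", "latent_cv", "sigma"))
  traits <- traits %||% shared
  dplyr::bind_rows(purrr::map(traits, function(tr) {
    equivalence_test(post_a, post_b, trait = tr,
                     rope_halfwidth = rope_halfwidth, n_pairs = n_pairs,
                     seed = seed)
  }))
}
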