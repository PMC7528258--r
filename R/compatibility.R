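#' Build a compatibility (P-value) curve over a hypothesis grid
#'
#' Evaluates the full evidential panel over an ordered grid of hypothesis
#' values spanning at least the `span_level` compatibility interval,
#' spaced uniformly on the analysis scale (log-uniform for ratio
#' measures). The curve peaks at p = 1 at the point estimate and falls
#' away on both sides; its complement read as `1 - p` gives the interval
#' percentile at each hypothesis, so every compatibility interval can be
#' read off the same graph.
#'
#' The curve exists for display and export; interval endpoints are always
#' computed from the closed-form Wald expressions
#' ([compatibility_interval()]), never interpolated from the grid, so
#' reported numbers carry no grid-resolution artifacts.
#'
#' @param est An [effect_estimate()].
#' @param span_level Interval level the grid must cover (default 0.999).
#' @param n_points Number of grid points (default 400, minimum 3); rounded
#'   up to an odd count so the point estimate is itself a grid point.
#' @return A tibble of class `compatibility_curve`: columns `hypothesis`,
#'   `z`, `p`, `s_bits`, `mlr`, `deviance`, `rel_likelihood`
#'   (`exp(-z^2/2) = 1/mlr`), with the source estimate attached as an
#'   attribute.
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' curve <- compatibility_curve(est)
#' curve[which.max(curve$p), ]  # peak at the point estimate
#' @export
compatibility_curve <- function(est, span_level = 0.999, n_points = 400L) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.numeric(n_points) || n_points < 3) {
    stop("`n_points` must be at least 3", call. = FALSE)
  }
  if (!is.numeric(span_level) || span_level <= 0 || span_level >= 1) {
    stop("`span_level` must be a proportion in (0, 1)", call. = FALSE)
  }
  tr <- trans_fun(est); inv <- trans_inv(est)
  q <- stats::qnorm((1 + span_level) / 2)
  center <- tr(est$point)
  # symmetric offsets around the point estimate, which is itself a grid
  # point, so the peak is p = 1 exactly; realized length is the nearest
  # odd count >= n_points
  offsets <- seq(0, q * est$se, length.out = floor(n_points / 2) + 1)[-1]
  grid_t <- c(center - rev(offsets), center, center + offsets)
  panel <- test_panel(est, inv(grid_t))
  out <- tibble::tibble(
    hypothesis = panel$hypothesis,
    z = panel$z,
    p = panel$p,
    s_bits = panel$s_bits,
    mlr = panel$mlr,
    deviance = panel$deviance,
    rel_likelihood = exp(-panel$z^2 / 2))
  class(out) <- c("compatibility_curve", class(out))
  attr(out, "estimate") <- est
  out
}

new_interval <- function(kind, level_or_cutoff, lower, upper, est) {
  out <- tibble::tibble(kind = kind, level_or_cutoff = level_or_cutoff,
                        lower = lower, upper = upper)
  class(out) <- c("interval_estimate", class(out))
  attr(out, "estimate") <- est
  out
}

#' Compatibility interval at an arbitrary level
#'
#' The level-`L` compatibility interval is the set of hypothesis values
#' with `p > 1 - L`: exactly the conventional confidence interval, renamed
#' for what it shows about the data rather than what it promises over
#' hypothetical repetitions. Closed-form Wald endpoints
#' `Tinv(T(point) +/- qnorm((1+L)/2) * SE)`; the two endpoints have
#' `p = 1 - L` by construction. Vectorized over `level`, and intervals at
#' increasing levels are strictly nested.
#'
#' @param est An [effect_estimate()].
#' @param level Interval level(s) in (0, 1); default the proportionally
#'   spaced trio 0.75, 0.95, 0.99 (p > 0.25, 0.05, 0.01).
#' @return An `interval_estimate` tibble, one row per level.
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' compatibility_interval(est, 0.95)  # recovers (0.997, 2.59)
#' compatibility_interval(est)        # nested 75/95/99% intervals
#' @export
compatibility_interval <- function(est, level = c(0.75, 0.95, 0.99)) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.numeric(level) || any(level <= 0) || any(level >= 1)) {
    stop("`level` must lie strictly inside (0, 1)", call. = FALSE)
  }
  tr <- trans_fun(est); inv <- trans_inv(est)
  q <- stats::qnorm((1 + level) / 2)
  new_interval("compatibility", level,
               inv(tr(est$point) - q * est$se),
               inv(tr(est$point) + q * est$se), est)
}

#' Likelihood interval at a relative-likelihood cutoff
#'
#' The set of hypothesis values whose relative likelihood
#' `exp(-z^2 / 2)` is at least `cutoff`; closed form
#' `Tinv(T(point) +/- SE * sqrt(-2 * log(cutoff)))`. Under the Wald model
#' the cutoff `1 / mlr_from_p(1 - L)` reproduces the level-`L`
#' compatibility interval exactly -- e.g. 1/6.83 corresponds to the 95%
#' interval.
#'
#' @param est An [effect_estimate()].
#' @param cutoff Relative-likelihood cutoff(s) in (0, 1].
#' @return An `interval_estimate` tibble (degenerate at the point estimate
#'   when `cutoff = 1`).
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' likelihood_interval(est, 1 / 6.83)  # ~ the 95% compatibility interval
#' @export
likelihood_interval <- function(est, cutoff) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.numeric(cutoff) || any(cutoff <= 0) || any(cutoff > 1)) {
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  }
  tr <- trans_fun(est); inv <- trans_inv(est)
  half <- est$se * sqrt(-2 * log(cutoff))
  new_interval("likelihood", cutoff,
               inv(tr(est$point) - half),
               inv(tr(est$point) + half), est)
}

#' Hypothesis values more compatible with the data than a reference value
#'
#' Returns the interval of parameter values whose two-sided P-value
#' exceeds that of a stated reference hypothesis. By the symmetry of the
#' Wald model on the analysis scale this is the open interval between the
#' reference and its mirror image about the point estimate,
#' `Tinv(2 * T(point) - T(reference))`. With the canonical hazard-ratio
#' example and reference HR = 1, every value from 1 up to about 2.59 is
#' more compatible with the data than "no association" is -- the
#' observation that makes "the study found no association" untenable as a
#' summary.
#'
#' @param est An [effect_estimate()].
#' @param reference Reference hypothesis value on the natural scale; must
#'   differ from the point estimate (at which the set is degenerate).
#' @return An `interval_estimate` tibble with `kind = "compatibility"` and
#'   `level_or_cutoff` equal to `1 - p(reference)`.
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' values_more_compatible_than(est, 1)
#' @export
values_more_compatible_than <- function(est, reference) {
  stopifnot(inherits(est, "effect_estimate"),
            is.numeric(reference), length(reference) == 1L)
  tr <- trans_fun(est); inv <- trans_inv(est)
  if (isTRUE(all.equal(tr(reference), tr(est$point)))) {
    stop("reference equals the point estimate: every other value is less compatible",
         call. = FALSE)
  }
  mirror <- inv(2 * tr(est$point) - tr(reference))
  p_ref <- p_value(est, reference)
  new_interval("compatibility", 1 - p_ref,
               min(reference, mirror), max(reference, mirror), est)
}

#' @export
print.interval_estimate <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    if (x$kind[i] == "compatibility") {
      cat(sprintf("%g%% compatibility interval: (%.4g, %.4g)\n",
                  100 * x$level_or_cutoff[i], x$lower[i], x$upper[i]))
    } else {
      cat(sprintf("1/%.3g likelihood interval: (%.4g, %.4g)\n",
                  1 / x$level_or_cutoff[i], x$lower[i], x$upper[i]))
    }
  }
  invisible(x)
}
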