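#' Combine evidence across independent studies
#'
#' Sums the natural-log surprisals `-ln(p)` of K independent P-values for
#' the same test hypothesis, doubles the sum, and refers it to a
#' chi-squared distribution with 2K degrees of freedom (Fisher's
#' combination). Under the shared test hypothesis each `-ln(p)` has
#' expectation 1, so the undoubled sum has expectation K; binary S-values
#' must be converted to nats before summing, never mixed. The combination
#' is one-directional in evidence -- small P-values reinforce each other;
#' there is no two-sided variant.
#'
#' All input P-values must share the same sidedness convention for the
#' shared hypothesis; the caller declares it via `sided` and the
#' declaration is carried in the result. Mixing conventions silently
#' would invalidate the referral, and cannot be detected from the numbers
#' alone. (Likewise, the referral presumes valid -- uniform-under-the-model
#' -- P-values as inputs; quantities such as posterior predictive P-values
#' do not qualify, and no code can tell them apart from valid ones.)
#'
#' @param p_values Numeric vector of per-study P-values in (0, 1], one per
#'   independent study.
#' @param sided Declared convention of the inputs, `"two"` or `"one"`;
#'   recorded, not used in the arithmetic.
#' @return A list of class `study_combination`: `statistic`
#'   (`2 * sum(-log(p))`), `df` (`2K`), `p_combined` (upper chi-squared
#'   tail), `K`, `s_nats_sum`, and `sided`.
#' @examples
#' combine_studies(c(0.05, 0.05))   # two borderline studies reinforce
#' combine_studies(1)$p_combined    # K = 1 returns the input unchanged
#' @export
combine_studies <- function(p_values, sided = c("two", "one")) {
  sided <- match.arg(sided)
  check_p(p_values)
  k <- length(p_values)
  s_nats <- -log(p_values)
  stat <- 2 * sum(s_nats)
  df <- 2L * k
  structure(
    list(statistic = stat,
         df = df,
         p_combined = stats::pchisq(stat, df = df, lower.tail = FALSE),
         K = k,
         s_nats_sum = sum(s_nats),
         sided = sided),
    class = "study_combination")
}

#' @export
print.study_combination <- function(x, ...) {
  cat(sprintf("Combined evidence over K = %d studies (%s-sided inputs)\n",
              x$K, x$sided))
  cat(sprintf("  2 * sum(-ln p) = %.4g on chi-squared(%d)\n", x$statistic, x$df))
  cat(sprintf("  combined P = %.4g  (S = %.3g bits)\n",
              x$p_combined, -log2(x$p_combined)))
  invisible(x)
}

#' Check P-value validity (uniformity) empirically
#'
#' A P-value is valid when, under the test hypothesis and all background
#' assumptions, it is uniform on (0, 1). Given a sample of P-values
#' produced under conditions where the tested hypothesis was true, this
#' compares their empirical distribution to uniform(0, 1) with a
#' Kolmogorov-Smirnov test. A small `ks_p` with mass piled near 0
#' indicates the tested hypothesis (or some background assumption) does
#' not hold in the generating process.
#'
#' @param p_values At least 10 P-values in \[0, 1\].
#' @return A list with `ks_distance` (the KS statistic), `ks_p` (its tail
#'   probability), and `n`.
#' @examples
#' set.seed(1)
#' check_uniformity(runif(1000))  # valid by construction
#' @export
check_uniformity <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) < 10) {
    stop("at least 10 P-values are needed to assess uniformity", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  # ties are expected in discrete/rounded inputs; the asymptotic test is fine
  ks <- suppressWarnings(
    stats::ks.test(p_values, "punif", 0, 1, exact = FALSE))
  list(ks_distance = unname(ks$statistic),
       ks_p = ks$p.value,
       n = length(p_values))
}

#' Simulate a set of study estimates under the Wald model
#'
#' Draws `n_studies` analysis-scale point estimates from a normal
#' distribution with mean `true_effect` and standard deviation
#' `se_per_study` -- the regime in which all background assumptions of the
#' Wald machinery hold exactly, so P-values tested at the true effect are
#' uniform and level-L intervals cover at rate L. Used for validity and
#' coverage checks; it emulates sampling error only, not bias,
#' heterogeneity, or model misspecification.
#'
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-for-bit reproducible and no global random state is touched.
#' @param n_studies Number of studies to draw.
#' @param true_effect True parameter value on the analysis scale (e.g. a
#'   log hazard ratio).
#' @param se_per_study Common standard error on the analysis scale.
#' @param scale Scale on which the estimates are to be reported
#'   (`"log"` exponentiates back to the ratio scale).
#' @return A list of class `simulated_study_set`: the generation
#'   parameters plus `estimates`, a tibble with one row per study
#'   (`study`, `point` on the natural scale, `se`).
#' @examples
#' sim <- simulate_studies(seed = 1, n_studies = 5,
#'                         true_effect = log(1.61), se_per_study = 0.24)
#' sim$estimates
#' @export
simulate_studies <- function(seed, n_studies, true_effect, se_per_study,
                             scale = c("log", "identity")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(n_studies) || n_studies < 1) {
    stop("`n_studies` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(se_per_study) || se_per_study <= 0) {
    stop("`se_per_study` must be positive", call. = FALSE)
  }
  draws <- withr::with_seed(as.integer(seed),
                            stats::rnorm(n_studies, mean = true_effect,
                                         sd = se_per_study))
  inv <- if (scale == "log") exp else identity
  structure(
    list(seed = as.integer(seed),
         n_studies = as.integer(n_studies),
         true_effect = true_effect,
         se_per_study = se_per_study,
         scale = scale,
         estimates = tibble::tibble(study = seq_len(n_studies),
                                    point = inv(draws),
                                    se = se_per_study)),
    class = "simulated_study_set")
}

#' Materialize one simulated study as an effect estimate
#'
#' @param sim A [simulate_studies()] result.
#' @param i Study index.
#' @return An [effect_estimate()] with the stated standard error.
#' @export
study_estimate <- function(sim, i) {
  stopifnot(inherits(sim, "simulated_study_set"))
  row <- sim$estimates[i, ]
  effect_estimate(point = row$point, se = row$se, scale = sim$scale,
                  label = sprintf("simulated study %d (seed %d)", i, sim$seed))
}

#' Per-study P-values for a shared test hypothesis
#'
#' Vectorized over the whole study set: the two-sided Wald P-value of each
#' simulated estimate against `value` (natural scale).
#'
#' @inheritParams study_estimate
#' @param value Hypothesis value on the natural scale.
#' @return Numeric vector of P-values, one per study.
#' @export
study_p_values <- function(sim, value) {
  stopifnot(inherits(sim, "simulated_study_set"))
  tr <- if (sim$scale == "log") log else identity
  z <- (tr(value) - tr(sim$estimates$point)) / sim$estimates$se
  pmin(2 * stats::pnorm(abs(z), lower.tail = FALSE), 1)
}

#' Interval coverage across a simulated study set
#'
#' Fraction of level-`level` compatibility intervals that contain the true
#' effect; equals the nominal level up to Monte-Carlo error when the
#' background assumptions hold.
#'
#' @inheritParams study_estimate
#' @param level Interval level in (0, 1).
#' @return A proportion.
#' @export
interval_coverage <- function(sim, level = 0.95) {
  stopifnot(inherits(sim, "simulated_study_set"),
            is.numeric(level), level > 0, level < 1)
  tr <- if (sim$scale == "log") log else identity
  q <- stats::qnorm((1 + level) / 2)
  center <- tr(sim$estimates$point)
  covered <- (center - q * sim$estimates$se <= sim$true_effect) &
             (sim$true_effect <= center + q * sim$estimates$se)
  mean(covered)
}
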