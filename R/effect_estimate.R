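#' Represent a reported summary effect estimate
#'
#' An `effect_estimate` holds a published point estimate together with the
#' information needed to apply the Wald normal approximation on its analysis
#' scale: either the reported interval limits (from which the standard error
#' is back-calculated) or the standard error itself. Ratio measures (hazard,
#' odds, risk ratios) are analyzed on the natural-log scale; difference
#' measures on the identity scale. The scale must be stated explicitly --
#' silent misdetection of the scale is the worst failure mode for this kind
#' of reanalysis, so there is no automatic guess.
#'
#' @param point Reported point estimate on the natural (reported) scale.
#'   Must be positive when `scale = "log"`.
#' @param lower,upper Reported interval limits on the natural scale.
#'   Optional when `se` is supplied.
#' @param level Percentile level of the reported interval, in (0, 1).
#'   Defaults to 0.95, the near-universal reporting convention.
#' @param scale Analysis scale: `"log"` for ratio measures, `"identity"`
#'   for differences. No default -- the caller must say.
#' @param se Standard error on the analysis scale. Optional; derived from
#'   the limits when absent. If both `se` and limits are supplied they must
#'   agree to 1% relative tolerance, otherwise an error is raised rather
#'   than silently preferring one source.
#' @param label Free-text label carried through reports.
#'
#' @return An object of class `effect_estimate`: a list with elements
#'   `point`, `lower`, `upper`, `level`, `scale`, `se` (always populated,
#'   on the analysis scale) and `label`.
#'
#' @examples
#' # The canonical worked example: an adjusted hazard ratio of 1.61 with
#' # 95% limits 0.997 and 2.59
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log",
#'                        label = "HDPS-adjusted HR")
#' est$se  # back-calculated log-scale standard error, ~0.2435
#' @seealso [se_from_limits()], [z_score()], [p_value()], [test_panel()]
#' @export
effect_estimate <- function(point, lower = NULL, upper = NULL, level = 0.95,
                            scale = c("log", "identity"), se = NULL,
                            label = "") {
  scale <- match.arg(scale)
  stopifnot(is.numeric(point), length(point) == 1L, is.finite(point))
  has_limits <- !is.null(lower) && !is.null(upper)
  if (!has_limits && is.null(se)) {
    stop("supply either both interval limits or a standard error", call. = FALSE)
  }
  if (has_limits) {
    stopifnot(is.numeric(lower), is.numeric(upper),
              length(lower) == 1L, length(upper) == 1L)
    if (!(lower < point && point < upper)) {
      stop("interval limits must bracket the point estimate: lower < point < upper",
           call. = FALSE)
    }
    if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
      stop("`level` must be a proportion strictly inside (0, 1)", call. = FALSE)
    }
  }
  if (scale == "log") {
    vals <- c(point, if (has_limits) c(lower, upper))
    if (any(vals <= 0)) {
      stop("point and limits must be positive on the log (ratio) scale",
           call. = FALSE)
    }
  }
  if (!is.null(se)) {
    stopifnot(is.numeric(se), length(se) == 1L)
    if (!is.finite(se) || se <= 0) {
      stop("`se` must be a positive finite number", call. = FALSE)
    }
  }
  est <- structure(
    list(point = point,
         lower = if (has_limits) lower else NA_real_,
         upper = if (has_limits) upper else NA_real_,
         level = if (has_limits) level else NA_real_,
         scale = scale,
         se = se,
         label = as.character(label)),
    class = "effect_estimate")
  if (has_limits) {
    derived <- se_from_limits(est)
    if (!is.null(se)) {
      if (abs(se - derived) / derived > 0.01) {
        stop(sprintf(paste0("supplied standard error (%.5g) disagrees with the ",
                            "value back-calculated from the limits (%.5g) by ",
                            "more than 1%%"), se, derived), call. = FALSE)
      }
    } else {
      est$se <- derived
    }
  }
  est
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" <", x$label, ">") else ""
  cat(sprintf("Effect estimate%s (%s scale)\n", lab, x$scale))
  cat(sprintf("  point: %g", x$point))
  if (is.finite(x$lower)) {
    cat(sprintf("   %g%% limits: (%g, %g)", 100 * x$level, x$lower, x$upper))
  }
  cat(sprintf("\n  analysis-scale SE: %.5g\n", x$se))
  invisible(x)
}

# scale transform and its inverse on the analysis scale
trans_fun <- function(est) {
  if (est$scale == "log") log else identity
}
trans_inv <- function(est) {
  if (est$scale == "log") exp else identity
}

#' Back-calculate the standard error from reported interval limits
#'
#' Under the Wald approximation a level-`L` interval has endpoints
#' `T(point) +/- q * SE` on the analysis scale, with
#' `q = qnorm((1 + L) / 2)`. Inverting gives
#' `SE = (T(upper) - T(lower)) / (2 * q)`, where `T` is the natural log for
#' ratio measures and the identity for differences. Exact normal quantiles
#' are used throughout, never the rounded 1.96.
#'
#' @param est An [effect_estimate()] with interval limits present.
#' @return The standard error on the analysis scale (a positive scalar).
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' se_from_limits(est)  # ~0.2435 on the log-HR scale
#' @export
se_from_limits <- function(est) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.finite(est$lower) || !is.finite(est$upper) || !is.finite(est$level)) {
    stop("interval limits and level are required to back-calculate the SE",
         call. = FALSE)
  }
  tr <- trans_fun(est)
  q <- stats::qnorm((1 + est$level) / 2)
  se <- (tr(est$upper) - tr(est$lower)) / (2 * q)
  if (!is.finite(se) || se <= 0) {
    stop("back-calculated standard error is not a positive finite number",
         call. = FALSE)
  }
  se
}

#' Wald Z statistic for a test hypothesis
#'
#' The signed standardized distance from the point estimate to a
#' hypothesized parameter value on the analysis scale:
#' `z = (T(value) - T(point)) / SE`. Negative when the hypothesis lies
#' below the point estimate.
#'
#' @param est An [effect_estimate()].
#' @param value Hypothesized parameter value(s) on the natural scale; may
#'   be a named vector (names are treated as hypothesis labels downstream).
#'   Must be positive when the estimate is on the log scale.
#' @return Numeric vector of Z statistics, one per hypothesis.
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' z_score(est, c(null = 1, doubling = 2))
#' @export
z_score <- function(est, value) {
  stopifnot(inherits(est, "effect_estimate"), is.numeric(value))
  if (is.null(est$se) || !is.finite(est$se) || est$se <= 0) {
    stop("estimate has no usable standard error", call. = FALSE)
  }
  if (est$scale == "log" && any(value <= 0)) {
    stop("hypothesis values must be positive on the log (ratio) scale",
         call. = FALSE)
  }
  tr <- trans_fun(est)
  (tr(value) - tr(est$point)) / est$se
}

# log of the tail probability for a Wald z; keeps extreme hypotheses from
# underflowing to log(0)
log_p_from_z <- function(z, sided = c("two", "lower", "upper")) {
  sided <- match.arg(sided)
  switch(sided,
    two   = pmin(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE), 0),
    lower = stats::pnorm(z, lower.tail = TRUE,  log.p = TRUE),
    upper = stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

#' Compatibility (P-) value for a test hypothesis
#'
#' The probability, under the test hypothesis together with all background
#' assumptions of the Wald model, of a test statistic at least as extreme
#' as the one implied by the reported estimate. Two-sided by default:
#' `2 * (1 - pnorm(|z|))`, capped at 1. One-sided tails follow the
#' convention that `"upper"` is the tail toward values above the
#' hypothesis (i.e. the probability that the estimate falls at or above
#' its observed position when the true value is the hypothesis).
#'
#' Tails are computed in log space, so the returned value is positive for
#' any finite `z` rather than underflowing to zero; extreme hypotheses
#' therefore still yield finite S-values. Where even the linear scale
#' cannot represent the tail, the smallest positive double is returned.
#'
#' @inheritParams z_score
#' @param sided `"two"` (default), `"lower"`, or `"upper"`.
#' @param log.p Return the natural log of the P-value instead.
#' @return Numeric vector of P-values in (0, 1] (or their logs).
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' p_value(est, 1)     # ~0.0505: the "null" is borderline-compatible
#' p_value(est, 2)     # ~0.373: doubling is clearly compatible
#' p_value(est, 1.61)  # 1 at the point estimate
#' @export
p_value <- function(est, value, sided = c("two", "lower", "upper"),
                    log.p = FALSE) {
  sided <- match.arg(sided)
  z <- z_score(est, value)
  lp <- log_p_from_z(z, sided)
  if (log.p) return(lp)
  p <- exp(lp)
  # smallest positive subnormal double: keeps the p > 0 contract when exp()
  # underflows (|z| beyond ~38.6)
  p[p == 0 & is.finite(lp)] <- 2^-1074
  p
}

#' Read effect estimates from a CSV file
#'
#' One estimate per row; columns `label`, `point`, `lower`, `upper`,
#' `level`, `scale`, `se`. Any of `lower`/`upper`/`level` or `se` may be
#' empty (but not both groups). A header row is required.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A named list of [effect_estimate()] objects (names from the
#'   `label` column).
#' @export
read_estimates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          label = readr::col_character(),
                          point = readr::col_double(),
                          lower = readr::col_double(),
                          upper = readr::col_double(),
                          level = readr::col_double(),
                          scale = readr::col_character(),
                          se    = readr::col_double()))
  required <- c("label", "point", "scale")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("input CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ests <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    ests[[i]] <- tryCatch(
      effect_estimate(
        point = row$point,
        lower = if (!is.null(row$lower) && is.finite(row$lower)) row$lower,
        upper = if (!is.null(row$upper) && is.finite(row$upper)) row$upper,
        level = if (!is.null(row$level) && is.finite(row$level)) row$level else 0.95,
        scale = row$scale,
        se    = if (!is.null(row$se) && is.finite(row$se)) row$se,
        label = row$label),
      error = function(e) {
        stop(sprintf("row %d (%s): %s", i, row$label, conditionMessage(e)),
             call. = FALSE)
      })
  }
  names(ests) <- vapply(ests, `[[`, character(1), "label")
  ests
}
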