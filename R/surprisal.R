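#' S-value (Shannon surprisal) of a P-value
#'
#' `s = -log2(p)` measures the information against the test hypothesis
#' (given the background assumptions) supplied by a P-value, in bits: the
#' number of consecutive heads on fair coin tosses that would be as
#' surprising. `p = 1` carries no information (`s = 0`); halving `p` adds
#' one bit. Natural-log surprisals ("nats") are used where additivity
#' against a chi-squared referral matters, as in [combine_studies()].
#'
#' @param p P-value(s) in (0, 1].
#' @param base `"bits"` (log base 2, default) or `"nats"` (natural log).
#' @return Non-negative surprisal(s), same length as `p`.
#' @examples
#' s_value(0.05)          # ~4.32 bits
#' s_value(0.0001)        # ~13.3 bits
#' s_value(c(1, 0.5))     # 0 and 1 bit
#' @export
s_value <- function(p, base = c("bits", "nats")) {
  base <- match.arg(base)
  check_p(p)
  if (base == "bits") -log2(p) else -log(p)
}

#' Invert an S-value back to a P-value
#'
#' @param s Non-negative surprisal(s).
#' @inheritParams s_value
#' @return `2^(-s)` for bits, `exp(-s)` for nats; the exact inverse of
#'   [s_value()].
#' @examples
#' p_from_s(10)  # ~0.001: ten heads in a row
#' @export
p_from_s <- function(s, base = c("bits", "nats")) {
  base <- match.arg(base)
  stopifnot(is.numeric(s))
  if (any(s < 0)) stop("S-values must be non-negative", call. = FALSE)
  if (base == "bits") 2^(-s) else exp(-s)
}

#' Maximum-likelihood ratio corresponding to a two-sided P-value
#'
#' For a simple hypothesis about one parameter under the Wald model, the
#' ratio of the maximized likelihood to the likelihood at the test
#' hypothesis is `exp(z^2 / 2)` with `z = qnorm(1 - p/2)`. The two-sided
#' inversion is applied uniformly -- including to quoted one-tail cutoffs
#' such as the 5-sigma and genome-wide thresholds, whose tail probability
#' is treated as `p` and re-inverted two-sidedly.
#'
#' @inheritParams s_value
#' @return MLR(s) `>= 1`.
#' @examples
#' mlr_from_p(0.05)  # ~6.83
#' mlr_from_p(0.01)  # ~27.6
#' @export
mlr_from_p <- function(p) {
  check_p(p)
  exp(z_from_p(p)^2 / 2)
}

#' Deviance (likelihood-ratio) statistic corresponding to a P-value
#'
#' `2 * ln(MLR) = z^2` with `z = qnorm(1 - p/2)`: the one-degree-of-freedom
#' chi-squared statistic whose two-sided normal tail is `p`.
#'
#' @inheritParams s_value
#' @return Non-negative deviance statistic(s).
#' @examples
#' deviance_from_p(0.05)  # ~3.84
#' @export
deviance_from_p <- function(p) {
  check_p(p)
  z_from_p(p)^2
}

check_p <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

# two-sided z inversion; lower.tail=FALSE keeps precision for tiny p
z_from_p <- function(p) {
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Evidential panel for several test hypotheses against one estimate
#'
#' Evaluates one reported estimate against a set of hypothesized parameter
#' values, returning the full panel of evidence translations for each:
#' Wald `z`, two-sided P-value, S-value in bits, maximum-likelihood ratio,
#' and deviance statistic. This is the table a reanalysis reports in place
#' of a lone null P-value: the same data carry very different amounts of
#' information against different hypotheses, and the panel shows the
#' gradation.
#'
#' MLR and deviance are defined here only through the two-sided Wald `z`
#' for a simple one-parameter hypothesis; there is deliberately no
#' one-sided variant, which would silently change the likelihood
#' convention.
#'
#' @param est An [effect_estimate()].
#' @param hypotheses Numeric vector of hypothesis values on the natural
#'   scale; names, if present, become the `label` column.
#' @return A tibble of class `surprisal_panel` with columns `label`,
#'   `hypothesis`, `z`, `p`, `s_bits`, `mlr`, `deviance`, one row per
#'   hypothesis, input order preserved. S-values are computed from the
#'   log-scale tail so extreme hypotheses do not saturate.
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' test_panel(est, c("no association" = 1, "doubling" = 2))
#' @export
test_panel <- function(est, hypotheses) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.numeric(hypotheses) || length(hypotheses) == 0L) {
    stop("`hypotheses` must be a non-empty numeric vector", call. = FALSE)
  }
  labels <- names(hypotheses)
  if (is.null(labels)) labels <- rep("", length(hypotheses))
  z <- z_score(est, unname(hypotheses))
  lp <- log_p_from_z(z, "two")
  p <- exp(lp)
  p[p == 0 & is.finite(lp)] <- 2^-1074
  out <- tibble::tibble(
    label = labels,
    hypothesis = unname(hypotheses),
    z = z,
    p = p,
    s_bits = abs(lp) / log(2),  # lp <= 0; abs() avoids IEEE negative zero
    mlr = exp(z^2 / 2),
    deviance = z^2)
  class(out) <- c("surprisal_panel", class(out))
  attr(out, "estimate") <- est
  out
}

#' Display-round an S-value
#'
#' S-values below about 10 bits (P-values down to ~0.001) are shown with
#' two decimals; larger ones are rounded to the nearest integer, since
#' decimal places on tens of bits convey spurious precision. Display-only:
#' stored values keep full precision.
#'
#' @param s Non-negative S-value(s).
#' @return Character vector.
#' @examples
#' format_s_value(c(4.31, 19.27, 10))
#' @export
format_s_value <- function(s) {
  stopifnot(is.numeric(s))
  if (any(s < 0, na.rm = TRUE)) stop("S-values must be non-negative", call. = FALSE)
  ifelse(s <= 10, sprintf("%.2f", s), sprintf("%d", as.integer(round(s))))
}

#' Render a panel as an aligned plain-text table
#'
#' Columns mirror the reporting convention: hypothesis label and value,
#' P-value, S-value in bits (display-rounded per [format_s_value()]),
#' maximum-likelihood ratio, and deviance statistic.
#'
#' @param panel A `surprisal_panel` from [test_panel()].
#' @param digits Significant digits for P, MLR and deviance columns.
#' @return Character vector of lines, invisibly also printed by
#'   `print.surprisal_panel`.
#' @export
format_panel <- function(panel, digits = 3) {
  stopifnot(inherits(panel, "surprisal_panel"))
  body <- data.frame(
    hypothesis = panel$label,
    value = formatC(panel$hypothesis, format = "g", digits = digits),
    P = formatC(panel$p, format = "g", digits = digits),
    `S (bits)` = format_s_value(panel$s_bits),
    MLR = formatC(panel$mlr, format = "g", digits = digits),
    deviance = formatC(panel$deviance, format = "g", digits = digits),
    check.names = FALSE)
  widths <- pmax(nchar(names(body)),
                 vapply(body, function(col) max(nchar(col)), integer(1)))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste(mapply(pad, names(body), widths), collapse = "  ")
  rows <- apply(mapply(pad, body, widths), 1, paste, collapse = "  ")
  c(header, strrep("-", nchar(header)), rows)
}

#' @export
print.surprisal_panel <- function(x, ...) {
  est <- attr(x, "estimate")
  if (!is.null(est) && nzchar(est$label)) {
    cat("Evidential panel for:", est$label, "\n")
  }
  cat(format_panel(x), sep = "\n")
  invisible(x)
}
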