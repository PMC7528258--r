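#' Plot a compatibility, surprisal, likelihood, or deviance curve
#'
#' Four views of the same function of the hypothesis value: the P-value
#' (compatibility) curve, the S-value (surprisal) curve, the relative
#' likelihood `exp(-z^2/2)`, and the deviance `z^2`. The x axis is spaced
#' on the analysis scale (log spacing for ratio measures) but labeled on
#' the natural scale. The P-value plot carries a secondary right-hand axis
#' giving the compatibility-interval percentile `1 - p`, so the default
#' 75/95/99% intervals can be read off where the curve crosses p = 0.25,
#' 0.05, 0.01. A vertical reference line (e.g. at the null) is drawn only
#' on request, since privileging one hypothesis on the graph is exactly
#' the habit the curve is meant to break.
#'
#' @param curve A [compatibility_curve()].
#' @param type One of `"p"`, `"s"`, `"likelihood"`, `"deviance"`.
#' @param levels Interval levels marked with horizontal guides on the
#'   P-value plot (default 0.75, 0.95, 0.99); `NULL` for none.
#' @param reference Optional hypothesis value for a vertical reference
#'   line.
#' @return A ggplot object.
#' @examples
#' est <- effect_estimate(1.61, 0.997, 2.59, scale = "log")
#' plot_curve(compatibility_curve(est), "p", reference = 1)
#' @export
plot_curve <- function(curve, type = c("p", "s", "likelihood", "deviance"),
                       levels = c(0.75, 0.95, 0.99), reference = NULL) {
  stopifnot(inherits(curve, "compatibility_curve"))
  type <- match.arg(type)
  est <- attr(curve, "estimate")
  view <- switch(type,
    p          = list(y = "p", lab = "P-value (compatibility)"),
    s          = list(y = "s_bits", lab = "S-value (bits of information)"),
    likelihood = list(y = "rel_likelihood", lab = "Relative likelihood"),
    deviance   = list(y = "deviance", lab = "Deviance statistic"))
  gg <- ggplot2::ggplot(curve,
          ggplot2::aes(x = .data$hypothesis, y = .data[[view$y]])) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = est$point, linetype = "dotted") +
    ggplot2::labs(x = if (est$scale == "log") "Hypothesized ratio" else
                      "Hypothesized difference",
                  y = view$lab,
                  title = if (nzchar(est$label)) est$label else NULL) +
    ggplot2::theme_minimal()
  if (est$scale == "log") {
    gg <- gg + ggplot2::scale_x_continuous(
      trans = "log",
      breaks = scales::log_breaks(n = 7),
      labels = scales::label_number(accuracy = 0.01))
  }
  if (type == "p") {
    gg <- gg + ggplot2::scale_y_continuous(
      limits = c(0, 1),
      sec.axis = ggplot2::sec_axis(~ 100 * (1 - .),
                                   name = "Compatibility interval (%)"))
    if (!is.null(levels)) {
      gg <- gg + ggplot2::geom_hline(yintercept = 1 - levels,
                                     linetype = "dashed", colour = "grey50")
    }
  }
  if (!is.null(reference)) {
    gg <- gg + ggplot2::geom_vline(xintercept = reference,
                                   linetype = "longdash", colour = "grey30")
  }
  gg
}

#' @importFrom rlang .data
NULL
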