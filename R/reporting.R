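#' The built-in worked-example estimate
#'
#' The canonical fixture used throughout the documentation: an adjusted
#' hazard ratio of 1.61 with 95% limits 0.997 and 2.59, from a published
#' high-dimensional-propensity-score (HDPS) reanalysis of antidepressant
#' use in pregnancy and autism spectrum disorder in offspring. An
#' estimate whose conventional summary ("no association, p > 0.05")
#' collapses under the evidential panel: the data carry barely more
#' information against a doubled hazard than against the null.
#'
#' @return An [effect_estimate()] on the log scale.
#' @examples
#' test_panel(brown_hdps(), c(null = 1, doubling = 2))
#' @export
brown_hdps <- function() {
  effect_estimate(point = 1.61, lower = 0.997, upper = 2.59, level = 0.95,
                  scale = "log", label = "HDPS-adjusted hazard ratio")
}

#' Default hypothesis list for a panel
#'
#' For ratio-scale estimates: halving, the null, the point estimate, and
#' doubling/tripling/quintupling of the effect -- the spread used in the
#' worked example. For difference scales: the null (0), the point
#' estimate, and its negation and doubling.
#'
#' @param est An [effect_estimate()].
#' @return Named numeric vector of hypothesis values.
#' @export
default_hypotheses <- function(est) {
  stopifnot(inherits(est, "effect_estimate"))
  if (est$scale == "log") {
    c("Halving of effect (0.5)" = 0.5,
      "No association (null, 1)" = 1,
      "Point estimate" = est$point,
      "Doubling (2)" = 2,
      "Tripling (3)" = 3,
      "Quintupling (5)" = 5)
  } else {
    c("Sign reversal" = -est$point,
      "No difference (null, 0)" = 0,
      "Point estimate" = est$point,
      "Doubling" = 2 * est$point)
  }
}

#' Run evidential panels for every estimate in a CSV file
#'
#' Reads estimates with [read_estimates()], computes a [test_panel()] for
#' each over `hypotheses` (defaulting per estimate via
#' [default_hypotheses()]), writes one full-precision CSV per estimate
#' into `out_dir`, and returns the panels. The plain-text rendering
#' (display-rounded per [format_s_value()]) goes to `message()` unless
#' `quiet = TRUE`; numeric output is never display-rounded in the CSVs.
#'
#' @param input_csv Path to an estimates CSV (see [read_estimates()]).
#' @param hypotheses Optional named numeric vector applied to every
#'   estimate; `NULL` for per-estimate defaults.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress the text tables.
#' @return Named list of `surprisal_panel` tibbles, invisibly.
#' @export
run_panel <- function(input_csv, hypotheses = NULL, out_dir = ".",
                      quiet = FALSE) {
  if (!is.null(hypotheses) &&
      (!is.numeric(hypotheses) || length(hypotheses) == 0L)) {
    stop("`hypotheses` must be NULL or a non-empty numeric vector",
         call. = FALSE)
  }
  ests <- read_estimates(input_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panels <- lapply(ests, function(est) {
    hyps <- if (is.null(hypotheses)) default_hypotheses(est) else hypotheses
    panel <- test_panel(est, hyps)
    path <- file.path(out_dir, paste0(slug(est$label), "_panel.csv"))
    write_csv_full(panel, path)
    if (!quiet) {
      message(est$label)
      message(paste(format_panel(panel), collapse = "\n"))
    }
    panel
  })
  invisible(panels)
}

#' Write curves and the four standard plots for every estimate in a CSV
#'
#' For each estimate: a curve CSV (columns `hypothesis`, `z`, `p`,
#' `s_bits`, `mlr`, `deviance`, `rel_likelihood`) and the P-value,
#' S-value, relative-likelihood, and deviance plots in the requested
#' device formats.
#'
#' @inheritParams run_panel
#' @param span_level,n_points Grid construction, see
#'   [compatibility_curve()].
#' @param levels Interval guides on the P-value plot.
#' @param reference Optional vertical reference value (e.g. the null);
#'   off by default.
#' @param formats Plot file formats, any of `"png"`, `"svg"`
#'   (svg requires the svglite package), `"pdf"`.
#' @return Named list of `compatibility_curve` tibbles, invisibly.
#' @export
run_curves <- function(input_csv, out_dir = ".", span_level = 0.999,
                       n_points = 400L, levels = c(0.75, 0.95, 0.99),
                       reference = NULL, formats = "png") {
  ests <- read_estimates(input_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- lapply(ests, function(est) {
    curve <- compatibility_curve(est, span_level = span_level,
                                 n_points = n_points)
    base <- file.path(out_dir, slug(est$label))
    write_csv_full(curve, paste0(base, "_curve.csv"))
    for (type in c("p", "s", "likelihood", "deviance")) {
      gg <- plot_curve(curve, type, levels = levels, reference = reference)
      for (fmt in formats) {
        ggplot2::ggsave(paste0(base, "_", type, "_curve.", fmt), gg,
                        width = 6, height = 4, dpi = 150)
      }
    }
    curve
  })
  invisible(curves)
}

#' JSON report of combination and uniformity checks
#'
#' Combines per-study P-values and assesses their uniformity, writing a
#' reproducible JSON report (inputs, declared convention, statistic,
#' degrees of freedom, combined P, KS distance and tail probability).
#'
#' @param p_values Per-study P-values.
#' @param path Output JSON path; `NULL` to skip writing.
#' @param sided Declared sidedness of the inputs (see
#'   [combine_studies()]).
#' @return The report as a list, invisibly when written.
#' @export
combination_report <- function(p_values, path = NULL, sided = c("two", "one")) {
  sided <- match.arg(sided)
  comb <- combine_studies(p_values, sided = sided)
  report <- list(
    K = comb$K,
    sided = comb$sided,
    p_values = p_values,
    statistic = comb$statistic,
    df = comb$df,
    p_combined = comb$p_combined,
    s_combined_bits = -log2(comb$p_combined))
  if (length(p_values) >= 10) {
    unif <- check_uniformity(p_values)
    report$ks_distance <- unif$ks_distance
    report$ks_p <- unif$ks_p
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

# 17 significant digits round-trip a double exactly; readr's default caps
# at 15, which is lossy in the last bits
write_csv_full <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
}

slug <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  x <- gsub("^_+|_+$", "", x)
  if (!nzchar(x)) "estimate" else x
}
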