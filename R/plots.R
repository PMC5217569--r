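#' Plot per-cycle base composition
#'
#' Line plot of base fraction against sequencing cycle, the diagnostic in
#' which a depressed G line reveals the G-undercall artifact.
#'
#' @param profile Output of [base_composition()].
#' @param bases Bases to show (default the four called bases).
#' @return A ggplot object.
#' @export
plot_composition <- function(profile, bases = c("A", "C", "G", "T")) {
  df <- profile[profile$base %in% bases, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cycle, y = .data$fraction, colour = .data$base
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "base fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot quality-score classes
#'
#' Stacked bar of the four Phred classes for one base identity.
#'
#' @param classes Output of [quality_classes()] (rows from one or more
#'   calls may be combined with `bind_rows` and an id column).
#' @return A ggplot object.
#' @export
plot_quality_classes <- function(classes) {
  ggplot2::ggplot(classes, ggplot2::aes(
    x = .data$base, y = .data$fraction, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of calls", fill = "Phred class") +
    ggplot2::theme_minimal()
}

#' Plot a mixture calibration series
#'
#' Observed-minus-predetermined differences against the predetermined
#' level, one line per mate — the plot in which a mate-specific artifact
#' shows as a diverging R1 line while R2 stays near zero.
#'
#' @param calibration Output of [calibrate_mixtures()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  df <- tidyr::pivot_longer(
    calibration[, c("predetermined", "diff_r1", "diff_r2")],
    cols = c("diff_r1", "diff_r2"),
    names_to = "mate", values_to = "diff"
  )
  df$mate <- toupper(sub("diff_", "", df$mate))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predetermined, y = .data$diff, colour = .data$mate
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "predetermined CpG level (%)",
      y = "observed - predetermined (points)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a run comparison
#'
#' Window-level scatter of run A against run B with the fitted OLS line.
#'
#' @param object A `run_comparison` from [compare_runs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot run_comparison
#' @export
autoplot.run_comparison <- function(object, ...) {
  ggplot2::ggplot(object$windows, ggplot2::aes(
    x = .data$level_b, y = .data$level_a
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60", linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "red", se = FALSE) +
    ggplot2::labs(x = "run B level (%)", y = "run A level (%)") +
    ggplot2::theme_minimal()
}

#' Plot windowed methylation levels
#'
#' Box plot of window levels, optionally grouped (e.g. by run or density
#' class via the `group` column).
#'
#' @param stats Window statistics ([window_levels()]), optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_window_levels <- function(stats) {
  df <- stats[!is.na(stats$level), ]
  if (!"group" %in% names(df)) df$group <- "run"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$level)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "CpG methylation level (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
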