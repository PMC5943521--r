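#' Plot a calibration fit
#'
#' Scatterplot of the paired SUVR values with the fitted regression line,
#' in the fitted direction (response on the vertical axis), plus the
#' identity line for reference.
#'
#' @param object An `suvr_fit` from [fit_ols()] or [fit_deming()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot suvr_fit
#' @export
autoplot.suvr_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$transform$slope,
                         intercept = object$transform$intercept,
                         colour = "#2166AC") +
    ggplot2::labs(x = paste0(object$x_name, " (SUVR)"),
                  y = paste0(object$y_name, " (SUVR)"),
                  title = sprintf("%s regression: %s ~ %s", object$method,
                                  object$y_name, object$x_name),
                  subtitle = format(object$transform)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration report
#'
#' Bar chart of group-mean percent differences from the standard for every
#' variant, with the tolerance band marked.
#'
#' @param object A [calibration_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_report
#' @export
autoplot.calibration_report <- function(object, ...) {
  tol <- attr(object, "tol")
  d <- tibble::as_tibble(object)
  d <- d[-(1:2), , drop = FALSE]  # drop the reference rows (identically 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant,
                                  y = .data$mean_pct_diff,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * tol$max_mean_percent_diff,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "Group-mean % difference from standard",
                  fill = "Group",
                  title = "Level-2 calibration variants vs standard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}

#' Plot the regression lines of several pathway variants
#'
#' Scatterplot of the non-standard method against the standard with one
#' calibration line per fitted variant, drawn in the conversion direction
#' (standard on the vertical axis).
#'
#' @param table Long SUVR table.
#' @param variants Variant names passed to [pathway_spec()].
#' @param lambda Deming error-variance ratio.
#' @param standard Standard method label.
#' @return A ggplot object.
#' @export
plot_pathway_lines <- function(table,
                               variants = c("1step-linear", "1step-deming",
                                            "2step-linear"),
                               lambda = 1, standard = "S") {
  fits <- purrr::map(variants, function(v) run_pathway(table, v, lambda))
  src <- fits[[1]]$transform$input_label
  wide <- suvr_wider(table, methods = c(src, standard))
  lines <- dplyr::bind_rows(purrr::map(fits, function(f) {
    tibble::tibble(variant = f$variant, slope = f$transform$slope,
                   intercept = f$transform$intercept)
  }))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[src]],
                                     y = .data[[standard]])) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$group), alpha = 0.6) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$variant)) +
    ggplot2::labs(x = paste0(src, " (SUVR)"),
                  y = paste0(standard, " (SUVR)"),
                  colour = "Variant", shape = "Group",
                  title = "Level-2 calibration lines") +
    ggplot2::theme_minimal()
}
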