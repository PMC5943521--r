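#' Linear transform between SUVR scales
#'
#' The currency of level-2 calibration: an affine map
#' `output = slope * input + intercept` between two SUVR scales, labelled by
#' the method it maps from and to. A zero slope cannot be inverted and is
#' rejected at construction for calibration use.
#'
#' @param slope,intercept Transform coefficients.
#' @param input_label,output_label Method labels for the input and output
#'   scales.
#' @param fit_method How the transform arose: `"ols"`, `"deming"`,
#'   `"composed"`, `"inverted"` or `"manual"`.
#' @param n Number of paired observations behind a fitted transform.
#' @return An object of class `linear_transform`.
#' @examples
#' t <- linear_transform(2, 1, "MM40", "S")
#' apply_transform(t, c(1, 2))
#' @export
linear_transform <- function(slope, intercept, input_label = "x",
                             output_label = "y", fit_method = "manual",
                             n = NA_integer_) {
  if (!is.finite(slope) || !is.finite(intercept)) {
    stop("linear_transform: slope and intercept must be finite",
         call. = FALSE)
  }
  if (slope == 0) {
    stop("linear_transform: zero slope is not invertible and cannot be used",
         " for calibration", call. = FALSE)
  }
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 input_label = input_label, output_label = output_label,
                 fit_method = fit_method, n = as.integer(n)),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, digits = 6, ...) {
  cat(sprintf("<linear_transform> %s -> %s  [%s]\n  %s = %s * %s + %s\n",
              x$input_label, x$output_label, x$fit_method,
              x$output_label, format(x$slope, digits = digits),
              x$input_label, format(x$intercept, digits = digits)))
  invisible(x)
}

#' @export
format.linear_transform <- function(x, digits = 6, ...) {
  sprintf("%s = %.*g * %s + %.*g", x$output_label, digits, x$slope,
          x$input_label, digits, x$intercept)
}

parse_fit_formula <- function(formula, data) {
  if (!inherits(formula, "formula") || length(formula) != 3) {
    stop("supply a two-sided formula: response ~ predictor", call. = FALSE)
  }
  lhs <- rlang::f_lhs(formula)
  rhs <- rlang::f_rhs(formula)
  if (!rlang::is_symbol(lhs) || !rlang::is_symbol(rhs)) {
    stop("formula must be of the form response ~ predictor (single terms)",
         call. = FALSE)
  }
  y_name <- rlang::as_name(lhs)
  x_name <- rlang::as_name(rhs)
  for (nm in c(y_name, x_name)) {
    if (!nm %in% names(data)) {
      stop(sprintf("column '%s' not found in data", nm), call. = FALSE)
    }
  }
  d <- tibble::tibble(x = as.numeric(data[[x_name]]),
                      y = as.numeric(data[[y_name]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) {
    stop("regression needs at least 3 complete paired observations",
         call. = FALSE)
  }
  list(x = d$x, y = d$y, x_name = x_name, y_name = y_name)
}

new_suvr_fit <- function(transform, method, x, y, x_name, y_name,
                         lambda = NA_real_) {
  n <- length(x)
  fitted <- transform$slope * x + transform$intercept
  resid <- y - fitted
  p <- 2L
  sigma <- sqrt(sum(resid^2) / max(n - p, 1L))
  r2 <- if (stats::var(y) > 0) {
    stats::cor(x, y)^2
  } else {
    NA_real_
  }
  structure(list(
    transform = transform,
    method = method,
    lambda = lambda,
    diagnostics = tibble::tibble(r.squared = r2, sigma = sigma, n = n),
    data = tibble::tibble(x = x, y = y),
    x_name = x_name, y_name = y_name
  ), class = "suvr_fit")
}

#' Ordinary least squares calibration fit
#'
#' Fits `response = slope * predictor + intercept` by least squares
#' (vertical residuals), following the `lm(response ~ predictor)`
#' convention in which the method nearer the standard scale is the
#' predictor. Backed by [stats::lm()].
#'
#' @param data Data frame with one column per method (see [suvr_wider()]).
#' @param formula Two-sided formula `response ~ predictor`, single terms.
#' @return An object of class `suvr_fit` holding the fitted
#'   [linear_transform()] (`$transform`, mapping predictor scale to response
#'   scale) and diagnostics; see [tidy.suvr_fit()] and [glance.suvr_fit()].
#' @examples
#' d <- data.frame(S = 1:5, MM40 = 2 * (1:5) + 1)
#' fit_ols(d, MM40 ~ S)$transform
#' @export
fit_ols <- function(data, formula) {
  p <- parse_fit_formula(formula, data)
  if (stats::var(p$x) == 0) {
    stop("fit_ols: predictor has zero variance", call. = FALSE)
  }
  co <- stats::coef(stats::lm(y ~ x, data = data.frame(x = p$x, y = p$y)))
  slope <- unname(co[["x"]])
  intercept <- unname(co[["(Intercept)"]])
  if (stats::var(p$y) == 0) {
    slope <- 0
    intercept <- p$y[1]
  }
  tr <- if (slope == 0) {
    warning("fit_ols: zero slope; transform is non-invertible and unusable",
            " for calibration", call. = FALSE)
    structure(list(slope = 0, intercept = intercept,
                   input_label = p$x_name, output_label = p$y_name,
                   fit_method = "ols", n = length(p$x)),
              class = "linear_transform")
  } else {
    linear_transform(slope, intercept, input_label = p$x_name,
                     output_label = p$y_name, fit_method = "ols",
                     n = length(p$x))
  }
  new_suvr_fit(tr, "ols", p$x, p$y, p$x_name, p$y_name)
}

deming_slope <- function(x, y, lambda) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2) / n
  syy <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  if (sxy == 0) {
    if (isTRUE(all.equal(syy, lambda * sxx))) {
      stop("fit_deming: zero covariance with equal (scaled) variances;",
           " line orientation is undefined", call. = FALSE)
    }
    stop("fit_deming: zero covariance between predictor and response",
         call. = FALSE)
  }
  ((syy - lambda * sxx) +
     sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
}

#' Deming errors-in-variables calibration fit
#'
#' Fits a straight line assuming measurement error on both axes, with error
#' variance ratio `lambda = var(error in response) / var(error in
#' predictor)`. The closed-form moment solution is used; the line always
#' passes through the sample centroid. Unlike least squares, the Deming fit
#' is symmetric: swapping the roles of the variables (and replacing
#' `lambda` by `1/lambda`) yields the exact inverse transform, so the fitted
#' calibration does not depend on which method is called the predictor.
#' `lambda = 1` (the default) is orthogonal regression, appropriate when the
#' two methods are about equally noisy.
#'
#' @inheritParams fit_ols
#' @param lambda Error-variance ratio (response over predictor), positive.
#' @return An object of class `suvr_fit`; see [fit_ols()].
#' @examples
#' d <- data.frame(S = 1:5, MM40 = 2 * (1:5) + 1)
#' fit_deming(d, MM40 ~ S)$transform
#' @export
fit_deming <- function(data, formula, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0) {
    stop("fit_deming: lambda must be a positive scalar", call. = FALSE)
  }
  p <- parse_fit_formula(formula, data)
  slope <- deming_slope(p$x, p$y, lambda)
  intercept <- mean(p$y) - slope * mean(p$x)
  tr <- linear_transform(slope, intercept, input_label = p$x_name,
                         output_label = p$y_name, fit_method = "deming",
                         n = length(p$x))
  new_suvr_fit(tr, "deming", p$x, p$y, p$x_name, p$y_name, lambda = lambda)
}

#' Invert a linear transform
#'
#' `(slope, intercept)` becomes `(1/slope, -intercept/slope)` and the
#' direction labels swap; inverting twice returns the original transform.
#'
#' @param t A [linear_transform()] with nonzero slope.
#' @return The inverse [linear_transform()].
#' @examples
#' invert_transform(linear_transform(2, 1))
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "linear_transform"))
  if (t$slope == 0) {
    stop("invert_transform: zero slope is not invertible", call. = FALSE)
  }
  linear_transform(1 / t$slope, -t$intercept / t$slope,
                   input_label = t$output_label, output_label = t$input_label,
                   fit_method = "inverted", n = t$n)
}

#' Compose two linear transforms
#'
#' Chains `first` then `second` into the single transform applying them in
#' sequence, as used to collapse a two-step calibration pathway into one
#' equation. The output label of `first` must equal the input label of
#' `second`.
#'
#' @param first,second [linear_transform()] objects.
#' @return A composed [linear_transform()] mapping `first$input_label` to
#'   `second$output_label`.
#' @examples
#' a <- linear_transform(2, 1, "MM40", "MM50")
#' b <- linear_transform(3, -1, "MM50", "S")
#' compose_transforms(a, b)
#' @export
compose_transforms <- function(first, second) {
  stopifnot(inherits(first, "linear_transform"),
            inherits(second, "linear_transform"))
  if (!identical(first$output_label, second$input_label)) {
    stop(sprintf(
      "compose_transforms: label mismatch ('%s' -> '%s' then '%s' -> '%s')",
      first$input_label, first$output_label,
      second$input_label, second$output_label), call. = FALSE)
  }
  linear_transform(second$slope * first$slope,
                   second$slope * first$intercept + second$intercept,
                   input_label = first$input_label,
                   output_label = second$output_label,
                   fit_method = "composed",
                   n = min(first$n, second$n, na.rm = FALSE))
}

#' Apply a linear transform to SUVR values
#'
#' @param t A [linear_transform()].
#' @param values Numeric vector of SUVR values on the transform's input
#'   scale.
#' @return Numeric vector `slope * values + intercept`.
#' @export
apply_transform <- function(t, values) {
  stopifnot(inherits(t, "linear_transform"))
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("apply_transform: values must be finite numerics", call. = FALSE)
  }
  t$slope * values + t$intercept
}

#' Transform one method's records onto another scale
#'
#' Applies a calibration transform to the rows of a long SUVR table carrying
#' the transform's input label, appending the converted values under a new
#' method label (the transformed, "calculated standard" values).
#'
#' @param table Long SUVR table.
#' @param t A [linear_transform()].
#' @param new_label Method label for the transformed records; defaults to
#'   `"Shat_<input_label>"`.
#' @return The table with the transformed records appended.
#' @export
transform_suvr_table <- function(table, t,
                                 new_label = paste0("Shat_", t$input_label)) {
  table <- validate_suvr_table(table)
  src <- dplyr::filter(table, .data$method_label == t$input_label)
  if (nrow(src) == 0) {
    stop(sprintf("transform_suvr_table: no records with label '%s'",
                 t$input_label), call. = FALSE)
  }
  out <- dplyr::mutate(src, method_label = new_label,
                       suvr = apply_transform(t, .data$suvr))
  dplyr::bind_rows(table, out)
}

#' @export
print.suvr_fit <- function(x, ...) {
  cat(sprintf("<suvr_fit> %s regression, n = %d\n", x$method,
              x$diagnostics$n))
  print(x$transform)
  cat(sprintf("  R^2 = %.4f, residual SD = %.4g\n",
              x$diagnostics$r.squared, x$diagnostics$sigma))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x An `suvr_fit` from [fit_ols()] or [fit_deming()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`),
#'   broom-style.
#' @method tidy suvr_fit
#' @export
tidy.suvr_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$x_name),
                 estimate = c(x$transform$intercept, x$transform$slope))
}

#' One-row summary of a calibration fit
#'
#' @param x An `suvr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `lambda`, `r.squared`, `sigma`
#'   (residual SD), `n`.
#' @method glance suvr_fit
#' @export
glance.suvr_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(method = x$method, lambda = x$lambda),
                   x$diagnostics)
}

#' @method tidy linear_transform
#' @export
tidy.linear_transform <- function(x, ...) {
  tibble::tibble(input_label = x$input_label, output_label = x$output_label,
                 slope = x$slope, intercept = x$intercept,
                 fit_method = x$fit_method, n = x$n)
}
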