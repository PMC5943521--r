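#' Specify a level-2 calibration pathway
#'
#' A pathway names the sequence of regressions converting a non-standard
#' SUVR method onto the standard scale. Each step fits
#' `response ~ predictor` with the method nearer the standard as predictor;
#' the fitted map is then inverted to point toward the standard and the
#' steps are composed. Three variants are built in:
#'
#' * `"1step-linear"`: one least-squares regression of the non-standard
#'   method on the standard (`MM40 ~ S`).
#' * `"1step-deming"`: the same single step with Deming regression.
#' * `"2step-linear"`: separate least-squares corrections for acquisition
#'   (`MM40 ~ MM50`) and processing (`MM50 ~ S`), composed.
#'
#' @param variant One of the built-in variant names above, or a custom name
#'   when `steps` is supplied.
#' @param steps Optional data frame with columns `response`, `predictor`,
#'   `method` (`"ols"` or `"deming"`), one row per step in chain order from
#'   the non-standard label toward the standard.
#' @param standard Label of the standard scale the chain must reach.
#' @return An object of class `pathway_spec`.
#' @examples
#' pathway_spec("2step-linear")
#' @export
pathway_spec <- function(variant, steps = NULL, standard = "S") {
  if (is.null(steps)) {
    steps <- switch(variant,
      "1step-linear" = tibble::tibble(response = "MM40", predictor = "S",
                                      method = "ols"),
      "1step-deming" = tibble::tibble(response = "MM40", predictor = "S",
                                      method = "deming"),
      "2step-linear" = tibble::tibble(response = c("MM40", "MM50"),
                                      predictor = c("MM50", "S"),
                                      method = "ols"),
      stop(sprintf("unknown pathway variant '%s'; supply steps=", variant),
           call. = FALSE)
    )
  }
  steps <- tibble::as_tibble(steps)
  stopifnot(all(c("response", "predictor", "method") %in% names(steps)),
            nrow(steps) >= 1)
  if (!all(steps$method %in% c("ols", "deming"))) {
    stop("pathway steps must use method 'ols' or 'deming'", call. = FALSE)
  }
  # after inversion each step maps response -> predictor, so the chain is
  # response[1] -> predictor[1] = response[2] -> ... -> standard
  if (nrow(steps) > 1 &&
      !all(steps$predictor[-nrow(steps)] == steps$response[-1])) {
    stop("pathway steps do not chain: predictor of each step must be the",
         " response of the next", call. = FALSE)
  }
  if (steps$predictor[nrow(steps)] != standard) {
    stop(sprintf("pathway must end at the standard label '%s'", standard),
         call. = FALSE)
  }
  structure(list(variant = variant, steps = steps, standard = standard,
                 source = steps$response[1]),
            class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf("<pathway_spec> %s: %s -> %s\n", x$variant, x$source,
              x$standard))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  step %d: %s(%s ~ %s)\n", i,
                ifelse(x$steps$method[i] == "ols", "lm", "deming"),
                x$steps$response[i], x$steps$predictor[i]))
  }
  invisible(x)
}

#' Fit a calibration pathway on paired SUVR data
#'
#' Runs every regression step of a [pathway_spec()] on a long SUVR table,
#' inverts each fitted map so that it points toward the standard scale, and
#' composes the chain into a single transform from the non-standard method
#' to the standard.
#'
#' @param table Long SUVR table (see [validate_suvr_table()]) containing
#'   paired values for every label the pathway references.
#' @param spec A [pathway_spec()] or the name of a built-in variant.
#' @param lambda Deming error-variance ratio used for `"deming"` steps.
#' @return An object of class `pathway_fit`: list with `$transform` (the
#'   composed [linear_transform()] mapping the source label to the
#'   standard), `$step_fits` (the per-step `suvr_fit`s, in fitted
#'   direction), `$variant`.
#' @examples
#' tab <- generate_suvr_dataset(cohort_spec(seed = 1))$table
#' run_pathway(tab, "1step-deming")$transform
#' @export
run_pathway <- function(table, spec, lambda = 1) {
  if (is.character(spec)) spec <- pathway_spec(spec)
  stopifnot(inherits(spec, "pathway_spec"))
  labels <- unique(c(spec$steps$response, spec$steps$predictor))
  wide <- suvr_wider(table, methods = labels)
  miss <- setdiff(labels, names(wide))
  if (length(miss)) {
    stop("run_pathway: table lacks paired values for label(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(wide) < 3) {
    stop("run_pathway: fewer than 3 fully paired subjects", call. = FALSE)
  }
  step_fits <- purrr::pmap(spec$steps, function(response, predictor, method) {
    f <- stats::as.formula(paste(response, "~", predictor))
    if (method == "ols") fit_ols(wide, f) else fit_deming(wide, f, lambda)
  })
  toward_standard <- purrr::map(step_fits, function(fit) {
    if (fit$transform$slope == 0) {
      stop("run_pathway: a step fit has zero slope and cannot be inverted",
           call. = FALSE)
    }
    invert_transform(fit$transform)
  })
  composed <- purrr::reduce(toward_standard, compose_transforms)
  composed$fit_method <- if (nrow(spec$steps) == 1) {
    paste0(spec$steps$method[1], "-inverted")
  } else {
    "composed"
  }
  structure(list(variant = spec$variant, transform = composed,
                 step_fits = step_fits, spec = spec),
            class = "pathway_fit")
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat(sprintf("<pathway_fit> variant %s\n", x$variant))
  print(x$transform)
  invisible(x)
}

#' @method tidy pathway_fit
#' @export
tidy.pathway_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$step_fits, function(f) {
    dplyr::mutate(tidy.linear_transform(f$transform),
                  variant = x$variant, .before = 1)
  }))
}

#' @method glance pathway_fit
#' @export
glance.pathway_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, slope = x$transform$slope,
                 intercept = x$transform$intercept,
                 n_steps = nrow(x$spec$steps), n = x$transform$n)
}

#' Centiloid anchor pair
#'
#' The Centiloid scale maps the young-control (YC) reference group mean SUVR
#' to 0 CL and the Alzheimer's-disease (AD) group mean to 100 CL.
#'
#' @param yc_mean,ad_mean Anchor group mean SUVRs; `ad_mean > yc_mean`.
#' @return An object of class `centiloid_anchors`.
#' @examples
#' centiloid_anchors(1.0095, 2.0761)
#' @export
centiloid_anchors <- function(yc_mean, ad_mean) {
  if (!is.finite(yc_mean) || !is.finite(ad_mean) || ad_mean <= yc_mean) {
    stop("centiloid_anchors: need finite anchors with ad_mean > yc_mean",
         call. = FALSE)
  }
  structure(list(yc_mean = as.numeric(yc_mean),
                 ad_mean = as.numeric(ad_mean)),
            class = "centiloid_anchors")
}

#' @export
print.centiloid_anchors <- function(x, ...) {
  cat(sprintf("<centiloid_anchors> YC-0 at %.4f SUVR, AD-100 at %.4f SUVR\n",
              x$yc_mean, x$ad_mean))
  invisible(x)
}

#' Derive Centiloid anchors from a reference SUVR table
#'
#' Anchors are the YC and AD group means of the standard-method records, so
#' the reference rows of a report land at exactly 0 and 100 CL.
#'
#' @param table Long SUVR table containing the standard method with both
#'   groups.
#' @param method Standard method label.
#' @return A [centiloid_anchors()].
#' @export
anchors_from_table <- function(table, method = "S") {
  table <- validate_suvr_table(table)
  ref <- dplyr::filter(table, .data$method_label == method)
  gm <- dplyr::summarise(dplyr::group_by(ref, .data$group),
                         m = mean(.data$suvr), .groups = "drop")
  if (!all(c("YC", "AD") %in% gm$group)) {
    stop(sprintf("anchors_from_table: method '%s' lacks a YC or AD group",
                 method), call. = FALSE)
  }
  centiloid_anchors(gm$m[gm$group == "YC"], gm$m[gm$group == "AD"])
}

#' Convert standard-scale SUVR to Centiloid units
#'
#' Linear anchored conversion `100 * (value - yc_mean) / (ad_mean -
#' yc_mean)`: the YC anchor maps to 0 CL and the AD anchor to 100 CL.
#'
#' @param values Numeric SUVR value(s) on the standard scale.
#' @param anchors A [centiloid_anchors()].
#' @return Centiloid value(s).
#' @examples
#' a <- centiloid_anchors(1.0095, 2.0761)
#' suvr_to_centiloid(c(1.0095, 2.0761), a)
#' @export
suvr_to_centiloid <- function(values, anchors) {
  stopifnot(inherits(anchors, "centiloid_anchors"))
  100 * (values - anchors$yc_mean) / (anchors$ad_mean - anchors$yc_mean)
}

#' Percent difference relative to a reference mean
#'
#' @param diff Difference in SUVR units.
#' @param reference_mean Positive reference mean SUVR.
#' @return `100 * diff / reference_mean`, in percent. Full precision is
#'   returned; tabular display rounds to 2 decimals.
#' @examples
#' percent_difference(-0.00579, 2.0761)
#' @export
percent_difference <- function(diff, reference_mean) {
  if (any(!is.finite(reference_mean)) || any(reference_mean <= 0)) {
    stop("percent_difference: reference mean must be positive",
         call. = FALSE)
  }
  100 * diff / reference_mean
}

#' Acceptance tolerances for calibration reports
#'
#' Default thresholds follow the calibration-acceptability convention for
#' level-2 transforms: group-mean transformed values must agree with the
#' reference within 2 percent and within 1 Centiloid.
#'
#' @param max_mean_percent_diff Maximum allowed absolute group-mean percent
#'   difference from the standard (default 2).
#' @param max_mean_cl_diff Maximum allowed absolute group-mean Centiloid
#'   difference (default 1).
#' @return An object of class `tolerance_config`.
#' @export
tolerance_config <- function(max_mean_percent_diff = 2,
                             max_mean_cl_diff = 1) {
  if (max_mean_percent_diff <= 0 || max_mean_cl_diff <= 0) {
    stop("tolerance_config: tolerances must be positive", call. = FALSE)
  }
  structure(list(max_mean_percent_diff = max_mean_percent_diff,
                 max_mean_cl_diff = max_mean_cl_diff),
            class = "tolerance_config")
}

report_rows <- function(wide, shat, variant, anchors, tol, standard) {
  span <- anchors$ad_mean - anchors$yc_mean
  d <- tibble::tibble(group = wide$group, s = wide[[standard]], shat = shat)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$group),
    mean_suvr = mean(.data$shat),
    mean_diff_suvr = mean(.data$shat - .data$s),
    .groups = "drop"
  )
  ref_mean <- dplyr::summarise(dplyr::group_by(d, .data$group),
                               rm = mean(.data$s), .groups = "drop")
  out <- dplyr::left_join(out, ref_mean, by = "group")
  out <- dplyr::mutate(
    out,
    variant = variant,
    mean_pct_diff = percent_difference(.data$mean_diff_suvr, .data$rm),
    mean_cl = suvr_to_centiloid(.data$mean_suvr, anchors),
    mean_cl_diff = .data$mean_diff_suvr * 100 / span,
    pass = abs(.data$mean_pct_diff) <= tol$max_mean_percent_diff &
      abs(.data$mean_cl_diff) <= tol$max_mean_cl_diff
  )
  out$group <- factor(out$group, levels = c("YC", "AD"))
  out <- dplyr::arrange(out, .data$group)
  out$group <- as.character(out$group)
  dplyr::select(out, "variant", "group", "mean_suvr", "mean_diff_suvr",
                "mean_pct_diff", "mean_cl", "mean_cl_diff", "pass")
}

#' Evaluate a calibration transform against the standard
#'
#' Applies a fitted transform to the non-standard records of a paired SUVR
#' table and compares group means with the standard-method values: mean
#' transformed SUVR, mean difference, mean percent difference, Centiloid
#' conversions, and pass/fail against the tolerances. Centiloid difference
#' columns are the group-mean SUVR difference scaled by the anchor span
#' (`100 / (ad_mean - yc_mean)`).
#'
#' @param table Long SUVR table containing the transform's input label and
#'   the standard method for the same subjects, each tagged YC or AD.
#' @param transform A [linear_transform()] whose output scale is the
#'   standard.
#' @param anchors A [centiloid_anchors()]; by default derived from the
#'   standard method's group means via [anchors_from_table()].
#' @param tol A [tolerance_config()].
#' @param standard Standard method label.
#' @return A tibble with one row per group: `variant`, `group`,
#'   `mean_suvr`, `mean_diff_suvr`, `mean_pct_diff`, `mean_cl`,
#'   `mean_cl_diff`, `pass`.
#' @export
evaluate_transform <- function(table, transform, anchors = NULL,
                               tol = tolerance_config(), standard = "S") {
  stopifnot(inherits(transform, "linear_transform"),
            inherits(tol, "tolerance_config"))
  wide <- suvr_wider(table, methods = c(transform$input_label, standard))
  if (!all(c("YC", "AD") %in% wide$group)) {
    stop("evaluate_transform: both YC and AD groups are required",
         call. = FALSE)
  }
  if (is.null(anchors)) anchors <- anchors_from_table(table, standard)
  shat <- apply_transform(transform, wide[[transform$input_label]])
  report_rows(wide, shat, transform$input_label, anchors, tol, standard)
}

#' Full calibration report across pathway variants
#'
#' Fits every requested pathway variant on the table, evaluates each against
#' the standard, and assembles the report: a reference row per group
#' (identically zero differences, 0 and 100 CL by construction of the
#' anchors) followed by per-variant group rows. The best variant is the one
#' with the smallest maximum absolute group-mean percent difference (ties
#' broken by the YC value).
#'
#' @param table Long SUVR table with all labels the variants need.
#' @param variants Character vector of [pathway_spec()] variant names, or a
#'   list of `pathway_spec` objects.
#' @param lambda Deming error-variance ratio for Deming steps.
#' @param anchors Optional [centiloid_anchors()]; default derives them from
#'   the standard method's group means.
#' @param tol A [tolerance_config()].
#' @param standard Standard method label.
#' @return A tibble of class `calibration_report` with the columns of
#'   [evaluate_transform()]; attributes `anchors`, `tol`, `best_variant`,
#'   `fits` (the underlying `pathway_fit`s).
#' @examples
#' tab <- generate_suvr_dataset(cohort_spec(seed = 1))$table
#' calibration_report(tab)
#' @export
calibration_report <- function(table,
                               variants = c("1step-linear", "1step-deming",
                                            "2step-linear"),
                               lambda = 1, anchors = NULL,
                               tol = tolerance_config(), standard = "S") {
  table <- validate_suvr_table(table)
  if (is.null(anchors)) anchors <- anchors_from_table(table, standard)
  specs <- purrr::map(variants, function(v) {
    if (inherits(v, "pathway_spec")) v else pathway_spec(v, standard = standard)
  })
  fits <- purrr::map(specs, function(sp) run_pathway(table, sp, lambda))
  names(fits) <- purrr::map_chr(fits, "variant")
  rows <- purrr::map(fits, function(f) {
    r <- evaluate_transform(table, f$transform, anchors = anchors, tol = tol,
                            standard = standard)
    r$variant <- f$variant
    r
  })
  ref_wide <- suvr_wider(table, methods = standard)
  ref <- report_rows(ref_wide, ref_wide[[standard]], standard, anchors, tol,
                     standard)
  report <- dplyr::bind_rows(c(list(ref), rows))
  worst <- purrr::map_dbl(rows, function(r) max(abs(r$mean_pct_diff)))
  yc_val <- purrr::map_dbl(rows, function(r) {
    abs(r$mean_pct_diff[r$group == "YC"])
  })
  best <- names(fits)[order(worst, yc_val)][1]
  structure(report,
            class = c("calibration_report", class(report)),
            anchors = anchors, tol = tol, best_variant = best, fits = fits)
}

#' @export
print.calibration_report <- function(x, ...) {
  disp <- dplyr::mutate(tibble::as_tibble(x),
                        mean_suvr = round(.data$mean_suvr, 4),
                        mean_diff_suvr = round(.data$mean_diff_suvr, 5),
                        mean_pct_diff = round(.data$mean_pct_diff, 2),
                        mean_cl = round(.data$mean_cl, 3),
                        mean_cl_diff = round(.data$mean_cl_diff, 3))
  a <- attr(x, "anchors")
  cat(sprintf("Calibration report (anchors: YC-0 %.4f, AD-100 %.4f SUVR)\n",
              a$yc_mean, a$ad_mean))
  print(disp, n = nrow(disp))
  cat(sprintf("Best variant: %s\n", attr(x, "best_variant")))
  invisible(x)
}

#' Check a standard-method reimplementation against reference values
#'
#' The level-1 replication step of a level-2 calibration: regress the
#' reimplemented standard-method SUVRs on the published reference values and
#' check slope, intercept and R-squared against user-supplied thresholds
#' (the authoritative thresholds live in the external calibration standard,
#' so no numeric defaults are asserted here).
#'
#' @param reference,reimplementation Long SUVR tables (or data frames with
#'   `subject_id` and `suvr`) covering the same subjects.
#' @param slope_tol Allowed absolute deviation of the slope from 1.
#' @param intercept_tol Allowed absolute intercept.
#' @param min_r2 Minimum R-squared.
#' @return A list with `pass` (logical) and `fit`, a one-row tibble with
#'   `slope`, `intercept`, `r.squared`, `n` and the per-threshold pass
#'   flags.
#' @export
level1_replication_check <- function(reference, reimplementation,
                                     slope_tol, intercept_tol, min_r2) {
  stopifnot(is.numeric(slope_tol), is.numeric(intercept_tol),
            is.numeric(min_r2))
  ref <- tibble::as_tibble(reference)[c("subject_id", "suvr")]
  rei <- tibble::as_tibble(reimplementation)[c("subject_id", "suvr")]
  if (!setequal(ref$subject_id, rei$subject_id)) {
    stop("level1_replication_check: subject sets differ between tables",
         call. = FALSE)
  }
  d <- dplyr::inner_join(ref, rei, by = "subject_id",
                         suffix = c("_ref", "_new"))
  fit <- fit_ols(d, suvr_new ~ suvr_ref)
  g <- glance.suvr_fit(fit)
  res <- tibble::tibble(
    slope = fit$transform$slope,
    intercept = fit$transform$intercept,
    r.squared = g$r.squared,
    n = g$n,
    slope_ok = abs(fit$transform$slope - 1) <= slope_tol,
    intercept_ok = abs(fit$transform$intercept) <= intercept_tol,
    r2_ok = g$r.squared >= min_r2
  )
  list(pass = all(res$slope_ok, res$intercept_ok, res$r2_ok), fit = res)
}
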