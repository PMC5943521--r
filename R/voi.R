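#' VOI statistic of a static image
#'
#' Computes the mean or median of image intensity over the voxels of a
#' volume-of-interest mask, optionally restricted to a tissue mask (e.g. a
#' grey+white-matter segmentation). Mean over a cortical VOI normalised by a
#' whole-cerebellum VOI is the Centiloid-standard convention; median over
#' tissue-masked VOIs is the convention of median-based pipelines.
#'
#' NaN voxels inside the effective mask are excluded (their count is
#' reported via a message); an effective mask that is empty or all-NaN is an
#' error naming the VOI.
#'
#' @param image 3D numeric array (or `static_image`).
#' @param voi 3D mask (logical, or numeric treated as nonzero = in-mask).
#' @param statistic `"mean"` or `"median"`. The median of an even number of
#'   voxels is the midpoint of the two central values.
#' @param tissue Optional 3D tissue mask intersected with `voi`.
#' @param voi_label Label used in error messages.
#' @return A single numeric value.
#' @examples
#' img <- array(c(1, 2, 3, 100), dim = c(4, 1, 1))
#' m <- array(TRUE, dim = c(4, 1, 1))
#' voi_statistic(img, m, "mean")    # 26.5
#' voi_statistic(img, m, "median")  # 2.5
#' @export
voi_statistic <- function(image, voi, statistic = c("mean", "median"),
                          tissue = NULL, voi_label = "VOI") {
  statistic <- match.arg(statistic)
  if (!identical(dim(image)[1:3], dim(voi)[1:3])) {
    stop(sprintf("voi_statistic: mask '%s' shape does not match image",
                 voi_label), call. = FALSE)
  }
  mask <- as.logical(voi != 0)
  if (!is.null(tissue)) {
    if (!identical(dim(image)[1:3], dim(tissue)[1:3])) {
      stop(sprintf("voi_statistic: tissue mask shape does not match image (VOI '%s')",
                   voi_label), call. = FALSE)
    }
    mask <- mask & as.logical(tissue != 0)
  }
  vals <- as.numeric(image)[mask]
  if (length(vals) == 0L) {
    stop(sprintf("voi_statistic: effective mask for VOI '%s' is empty",
                 voi_label), call. = FALSE)
  }
  n_nan <- sum(is.na(vals))
  if (n_nan > 0L) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      stop(sprintf("voi_statistic: all in-mask voxels of VOI '%s' are NaN",
                   voi_label), call. = FALSE)
    }
    message(sprintf("voi_statistic: excluded %d NaN voxel(s) in VOI '%s'",
                    n_nan, voi_label))
  }
  switch(statistic, mean = mean(vals), median = stats::median(vals))
}

#' SUVR from target and reference VOI values
#'
#' The standardized uptake value ratio is the target-VOI uptake statistic
#' divided by the reference-VOI uptake statistic.
#'
#' @param target_value,reference_value VOI statistics; `reference_value > 0`.
#' @return `target_value / reference_value` (dimensionless).
#' @examples
#' compute_suvr(2.0, 1.0)
#' @export
compute_suvr <- function(target_value, reference_value) {
  if (any(!is.finite(reference_value)) || any(reference_value <= 0)) {
    stop("compute_suvr: reference value must be positive", call. = FALSE)
  }
  target_value / reference_value
}

#' Define an SUVR quantification profile
#'
#' A method profile binds together everything that defines one SUVR
#' quantification convention: the uptake statistic, the names of the target
#' and reference VOIs, whether a tissue mask is applied, and the method label
#' attached to the resulting records.
#'
#' Two conventions are built in via [standard_profile()] (mean statistic,
#' cortical target over whole cerebellum, no tissue masking — the
#' Centiloid-standard convention) and [mayo_profile()] (median statistic over
#' tissue-masked VOIs, cortical composite over cerebellar crus).
#'
#' @param label Method label for output records (e.g. `"S"`, `"MM40"`).
#' @param statistic `"mean"` or `"median"`.
#' @param target,reference Names of the target and reference VOIs; these key
#'   into the `vois` list given to [quantify_method()].
#' @param use_tissue Whether a tissue mask is applied to both VOIs.
#' @return A list of class `method_profile`.
#' @export
method_profile <- function(label, statistic = c("mean", "median"),
                           target, reference, use_tissue = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(is.character(label), length(label) == 1,
            is.character(target), is.character(reference))
  structure(list(label = label, statistic = statistic, target = target,
                 reference = reference, use_tissue = isTRUE(use_tissue)),
            class = "method_profile")
}

#' @rdname method_profile
#' @export
standard_profile <- function(label = "S", reference = "whole-cerebellum") {
  method_profile(label, "mean", target = "CTX", reference = reference,
                 use_tissue = FALSE)
}

#' @rdname method_profile
#' @export
mayo_profile <- function(label = "MM40") {
  method_profile(label, "median", target = "GlobalPiB",
                 reference = "cerebellar-crus", use_tissue = TRUE)
}

#' Quantify a static image under a method profile
#'
#' Applies a [method_profile()] to a static image: extracts the target and
#' reference VOI statistics (masked by tissue if the profile says so), forms
#' the SUVR, and returns a one-row SUVR record.
#'
#' @param image 3D array or `static_image`.
#' @param profile A [method_profile()].
#' @param vois Named list of 3D masks; must contain the profile's target and
#'   reference names.
#' @param tissue Optional tissue mask, required when the profile uses one.
#' @param subject_id,group Identifiers attached to the record (`group` is
#'   `"YC"` or `"AD"`).
#' @return A one-row tibble with columns `subject_id`, `group`,
#'   `method_label`, `suvr`.
#' @export
quantify_method <- function(image, profile, vois, tissue = NULL,
                            subject_id = NA_character_,
                            group = NA_character_) {
  stopifnot(inherits(profile, "method_profile"))
  for (nm in c(profile$target, profile$reference)) {
    if (!nm %in% names(vois)) {
      stop(sprintf("quantify_method: VOI '%s' not supplied", nm),
           call. = FALSE)
    }
  }
  tis <- if (profile$use_tissue) {
    if (is.null(tissue)) {
      stop("quantify_method: profile requires a tissue mask", call. = FALSE)
    }
    tissue
  } else {
    NULL
  }
  tv <- voi_statistic(image, vois[[profile$target]], profile$statistic,
                      tissue = tis, voi_label = profile$target)
  rv <- voi_statistic(image, vois[[profile$reference]], profile$statistic,
                      tissue = tis, voi_label = profile$reference)
  tibble::tibble(subject_id = as.character(subject_id),
                 group = as.character(group),
                 method_label = profile$label,
                 suvr = compute_suvr(tv, rv))
}

#' Validate a long-format SUVR table
#'
#' An SUVR table holds one record per subject and quantification method:
#' columns `subject_id`, `group` (`"YC"`/`"AD"`), `method_label`, `suvr`.
#' Pairing across methods joins on `subject_id`.
#'
#' @param table Data frame to validate.
#' @return The table as a tibble, invisibly validated.
#' @export
validate_suvr_table <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("subject_id", "group", "method_label", "suvr")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("SUVR table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(table$group %in% c("YC", "AD"))) {
    stop("SUVR table: group labels must be 'YC' or 'AD'", call. = FALSE)
  }
  if (any(!is.finite(table$suvr)) || any(table$suvr <= 0)) {
    stop("SUVR table: suvr values must be finite and positive", call. = FALSE)
  }
  if (anyDuplicated(table[c("subject_id", "method_label")])) {
    stop("SUVR table: (subject_id, method_label) pairs must be unique",
         call. = FALSE)
  }
  table
}

#' Pivot an SUVR table to one column per method
#'
#' @param table A long SUVR table (see [validate_suvr_table()]).
#' @param methods Optional subset of method labels to keep; rows (subjects)
#'   with any missing method are dropped only if `drop_incomplete = TRUE`.
#' @param drop_incomplete Drop subjects lacking any requested method.
#' @return A wide tibble: `subject_id`, `group`, one numeric column per
#'   method label.
#' @export
suvr_wider <- function(table, methods = NULL, drop_incomplete = TRUE) {
  table <- validate_suvr_table(table)
  if (!is.null(methods)) {
    table <- dplyr::filter(table, .data$method_label %in% methods)
  }
  wide <- tidyr::pivot_wider(table, id_cols = c("subject_id", "group"),
                             names_from = "method_label",
                             values_from = "suvr")
  if (drop_incomplete) wide <- tidyr::drop_na(wide)
  wide
}
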