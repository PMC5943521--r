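#' Read and write PET volumes as NIfTI
#'
#' Thin wrappers around RNifti. `read_dynamic_series()` combines a 4D NIfTI
#' volume with its timing sidecar into a [dynamic_series()];
#' `read_static_image()` and `write_static_image()` handle 3D volumes (VOI
#' masks are read the same way).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param timing Path to a timing sidecar (CSV with columns `frame_index`,
#'   `start_min`, `duration_min`, or a JSON array of such records), or a
#'   data frame of timing records, or a ready [frame_schedule()].
#' @param ... Passed to [extract_frame_schedule()] (e.g. `time_unit`).
#' @return `read_dynamic_series()`: a [dynamic_series()];
#'   `read_static_image()`: a 3D array with NIfTI attributes.
#' @export
read_dynamic_series <- function(path, timing, ...) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) {
    stop("read_dynamic_series: expected a 4D NIfTI volume", call. = FALSE)
  }
  sched <- if (inherits(timing, "frame_schedule")) {
    timing
  } else {
    extract_frame_schedule(read_timing(timing), ...)
  }
  dims <- RNifti::pixdim(img)
  dynamic_series(arr, sched, voxel_dims = dims[seq_len(min(3, length(dims)))])
}

#' @rdname read_dynamic_series
#' @export
read_static_image <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3) {
    stop("read_static_image: expected a 3D NIfTI volume", call. = FALSE)
  }
  arr
}

#' @rdname read_dynamic_series
#' @param image 3D array (or `static_image`) to write.
#' @export
write_static_image <- function(image, path) {
  RNifti::writeNifti(RNifti::asNifti(unclass(array(as.numeric(image),
                                                   dim(image)[1:3]))), path)
  invisible(path)
}

read_timing <- function(timing) {
  if (is.data.frame(timing)) return(tibble::as_tibble(timing))
  stopifnot(is.character(timing), length(timing) == 1)
  if (grepl("\\.json$", timing, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(timing))
  } else {
    readr::read_csv(timing, show_col_types = FALSE)
  }
}

#' Read or write a long SUVR table as CSV
#'
#' Columns: `subject_id`, `group`, `method_label`, `suvr`. The table is
#' validated on read and on write.
#'
#' @param path CSV file path.
#' @param table Long SUVR table.
#' @return `read_suvr_table()`: a validated tibble. `write_suvr_table()`:
#'   the path, invisibly.
#' @export
read_suvr_table <- function(path) {
  validate_suvr_table(readr::read_csv(path, show_col_types = FALSE,
                                      col_types = readr::cols(
                                        subject_id = readr::col_character(),
                                        group = readr::col_character(),
                                        method_label = readr::col_character(),
                                        suvr = readr::col_double())))
}

#' @rdname read_suvr_table
#' @export
write_suvr_table <- function(table, path) {
  readr::write_csv(validate_suvr_table(table), path)
  invisible(path)
}

#' Serialize a linear transform to JSON
#'
#' Transforms round-trip through a small JSON object carrying
#' `input_label`, `output_label`, `slope`, `intercept`, `fit_method`, `n`.
#'
#' @param t A [linear_transform()].
#' @param path JSON file path.
#' @return `write_transform_json()`: the path, invisibly;
#'   `read_transform_json()`: a [linear_transform()].
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "linear_transform"))
  jsonlite::write_json(unclass(t), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  linear_transform(x$slope, x$intercept, input_label = x$input_label,
                   output_label = x$output_label, fit_method = x$fit_method,
                   n = if (is.null(x$n) || is.na(x$n)) NA_integer_ else x$n)
}
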