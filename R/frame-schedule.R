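#' Construct a dynamic-PET frame schedule
#'
#' A frame schedule describes the acquisition timing of every frame of a
#' dynamic PET series: for each frame, its start time and duration in minutes
#' post-injection. Frames must tile time without overlap; the schedule is
#' stored sorted by start time with 0-based `frame_index` preserved from the
#' acquisition order.
#'
#' @param start_min Numeric vector of frame start times, minutes post-injection.
#' @param duration_min Numeric vector of frame durations in minutes
#'   (strictly positive).
#' @param frame_index Optional integer vector of 0-based frame indices
#'   identifying each frame's position along the 4th axis of the series.
#'   Defaults to acquisition order `0:(n-1)` before sorting, so a shuffled
#'   timing table keeps its original frame identities.
#' @return A tibble of class `frame_schedule` with columns `frame_index`,
#'   `start_min`, `duration_min`, `end_min`, sorted by `start_min`.
#' @examples
#' frame_schedule(start_min = seq(35, 65, by = 5), duration_min = 5)
#' @export
frame_schedule <- function(start_min, duration_min, frame_index = NULL) {
  n <- length(start_min)
  duration_min <- rep_len(duration_min, n)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  if (n == 0L) {
    stop("a frame schedule needs at least one frame", call. = FALSE)
  }
  if (anyNA(start_min) || anyNA(duration_min)) {
    stop("frame schedule error: missing start time or duration", call. = FALSE)
  }
  if (any(duration_min <= 0)) {
    stop("frame schedule error: durations must be strictly positive",
         call. = FALSE)
  }
  if (anyDuplicated(frame_index)) {
    stop("frame schedule error: duplicated frame_index", call. = FALSE)
  }
  ord <- order(start_min)
  starts <- as.numeric(start_min[ord])
  durs <- as.numeric(duration_min[ord])
  sched <- tibble::tibble(
    frame_index = as.integer(frame_index[ord]),
    start_min = starts,
    duration_min = durs,
    end_min = starts + durs
  )
  # tolerate sub-millisecond numeric jitter from unit conversion
  if (n > 1 && any(sched$start_min[-1] < sched$end_min[-n] - 1e-9)) {
    stop("frame schedule error: overlapping frame intervals", call. = FALSE)
  }
  class(sched) <- c("frame_schedule", class(sched))
  sched
}

#' Build a frame schedule from per-frame timing records
#'
#' Converts a timing table (for example a CSV sidecar, or rows extracted from
#' the DICOM frame-timing header field) into a validated [frame_schedule()]
#' in minutes post-injection. Records may arrive in any order; the schedule
#' is sorted and validated. When `time_unit = "ms"` (the DICOM convention for
#' frame reference times) both times and durations are divided by 60000.
#'
#' @param records Data frame with one row per frame, containing a reference
#'   time column and a duration column, and optionally `frame_index`.
#' @param time_unit `"minutes"` or `"ms"`.
#' @param time_col,duration_col Column names holding the reference time and
#'   duration. Defaults match the sidecar convention
#'   (`start_min`, `duration_min`); a table using plain `time`/`duration`
#'   columns is also recognised.
#' @param reference How the reference time relates to the frame interval:
#'   `"start"` (default) treats it as the frame start; `"midpoint"` treats it
#'   as the frame centre, so the start is `time - duration / 2`.
#' @return A [frame_schedule()].
#' @examples
#' rec <- data.frame(frame_index = 0:2, start_min = c(40, 45, 50),
#'                   duration_min = 5)
#' extract_frame_schedule(rec)
#' @export
extract_frame_schedule <- function(records,
                                   time_unit = c("minutes", "ms"),
                                   time_col = NULL, duration_col = NULL,
                                   reference = c("start", "midpoint")) {
  time_unit <- match.arg(time_unit)
  reference <- match.arg(reference)
  records <- tibble::as_tibble(records)
  if (is.null(time_col)) {
    time_col <- intersect(c("start_min", "time", "start"), names(records))[1]
  }
  if (is.null(duration_col)) {
    duration_col <- intersect(c("duration_min", "duration"), names(records))[1]
  }
  if (is.na(time_col) || is.null(time_col) || !time_col %in% names(records)) {
    stop("frame schedule error: no reference-time column found", call. = FALSE)
  }
  if (is.na(duration_col) || is.null(duration_col) ||
      !duration_col %in% names(records)) {
    stop("frame schedule error: missing duration column", call. = FALSE)
  }
  tt <- records[[time_col]]
  dd <- records[[duration_col]]
  if (anyNA(dd)) stop("frame schedule error: missing duration", call. = FALSE)
  scale <- if (time_unit == "ms") 1 / 60000 else 1
  tt <- tt * scale
  dd <- dd * scale
  if (reference == "midpoint") tt <- tt - dd / 2
  fi <- if ("frame_index" %in% names(records)) records$frame_index else NULL
  frame_schedule(start_min = tt, duration_min = dd, frame_index = fi)
}

#' Define a post-injection time window
#'
#' @param start,end Window bounds in minutes post-injection; `start < end`.
#' @return A named numeric vector of class `time_window`.
#' @examples
#' time_window(40, 60)
#' @export
time_window <- function(start, end) {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1 ||
      length(end) != 1 || is.na(start) || is.na(end) || start >= end) {
    stop("time window error: need scalar start < end", call. = FALSE)
  }
  structure(c(start = as.numeric(start), end = as.numeric(end)),
            class = "time_window")
}

as_time_window <- function(window) {
  if (inherits(window, "time_window")) return(window)
  if (is.numeric(window) && length(window) == 2) {
    return(time_window(window[[1]], window[[2]]))
  }
  stop("time window error: supply time_window() or c(start, end)",
       call. = FALSE)
}

#' Select dynamic frames falling within a time window
#'
#' Identifies the frames of a schedule that belong to a requested
#' post-injection window, e.g. the 40-60 and 50-70 minute late-uptake windows
#' used for PiB SUVR imaging. Under the default full-containment rule a frame
#' is selected when its whole interval lies inside the window, with a small
#' edge tolerance absorbing timing jitter; under the midpoint rule a frame is
#' selected when its centre falls inside the window.
#'
#' @param schedule A [frame_schedule()].
#' @param window A [time_window()] or `c(start, end)` in minutes.
#' @param rule `"full"` (interval containment, default) or `"midpoint"`.
#' @param edge_tol Edge tolerance in minutes for the full-containment rule
#'   (default 1 second).
#' @return Sorted integer vector of 0-based frame indices.
#' @examples
#' sched <- frame_schedule(seq(35, 65, by = 5), 5)
#' select_frames(sched, c(40, 60))
#' @export
select_frames <- function(schedule, window, rule = c("full", "midpoint"),
                          edge_tol = 1 / 60) {
  stopifnot(inherits(schedule, "frame_schedule"))
  rule <- match.arg(rule)
  window <- as_time_window(window)
  keep <- switch(rule,
    full = schedule$start_min >= window[["start"]] - edge_tol &
           schedule$end_min <= window[["end"]] + edge_tol,
    midpoint = {
      mid <- schedule$start_min + schedule$duration_min / 2
      mid >= window[["start"]] & mid < window[["end"]]
    }
  )
  idx <- sort(schedule$frame_index[keep])
  if (length(idx) == 0L) {
    stop(sprintf("no frames fall within window [%g, %g] min under rule '%s'",
                 window[["start"]], window[["end"]], rule), call. = FALSE)
  }
  idx
}

#' Construct a dynamic PET series
#'
#' Bundles a 4D voxel array (x, y, z, frame) with its [frame_schedule()].
#' The 4th-axis position of each frame must match the schedule's
#' `frame_index` (0-based: frame_index `i` lives at array slot `i + 1`).
#'
#' @param voxels 4D numeric array of activity values.
#' @param schedule A [frame_schedule()] with one row per frame.
#' @param voxel_dims Voxel dimensions in mm (length 3).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(voxels, schedule, voxel_dims = c(1, 1, 1)) {
  if (length(dim(voxels)) != 4) {
    stop("dynamic series error: voxels must be a 4D array", call. = FALSE)
  }
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4] != nrow(schedule)) {
    stop("dynamic series error: frame count does not match schedule",
         call. = FALSE)
  }
  if (!all(sort(schedule$frame_index) == seq_len(nrow(schedule)) - 1L)) {
    stop("dynamic series error: schedule frame_index must cover 0:(n-1)",
         call. = FALSE)
  }
  structure(list(voxels = voxels, schedule = schedule,
                 voxel_dims = as.numeric(voxel_dims)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_series> %d x %d x %d voxels, %d frames, %g-%g min\n",
              d[1], d[2], d[3], d[4],
              min(x$schedule$start_min), max(x$schedule$end_min)))
  invisible(x)
}

new_static_image <- function(voxels, provenance = list()) {
  structure(voxels, class = c("static_image", class(voxels)),
            provenance = provenance)
}

#' Voxel-wise average of selected dynamic frames
#'
#' Averages the selected frames of a dynamic series into a single static
#' image, as done when collapsing a dynamic late-uptake acquisition into a
#' summed static image. The default is an unweighted voxel-wise mean;
#' duration weighting is available for schedules with unequal frame lengths.
#'
#' @param series A [dynamic_series()].
#' @param indices 0-based frame indices to average (non-empty).
#' @param weighting `"uniform"` (default) or `"duration"`.
#' @return A `static_image`: a 3D array carrying a `provenance` attribute
#'   with the frame indices (and window, when produced by
#'   [window_average()]).
#' @export
average_frames <- function(series, indices,
                           weighting = c("uniform", "duration")) {
  stopifnot(inherits(series, "dynamic_series"))
  weighting <- match.arg(weighting)
  if (length(indices) == 0L) {
    stop("average_frames: empty frame index list", call. = FALSE)
  }
  nfr <- dim(series$voxels)[4]
  if (any(indices < 0L | indices >= nfr)) {
    stop("average_frames: frame index out of range", call. = FALSE)
  }
  w <- if (weighting == "duration") {
    durs <- series$schedule$duration_min[match(indices,
                                               series$schedule$frame_index)]
    durs / sum(durs)
  } else {
    rep(1 / length(indices), length(indices))
  }
  d <- dim(series$voxels)
  out <- array(0, dim = d[1:3])
  for (k in seq_along(indices)) {
    out <- out + w[k] * series$voxels[, , , indices[k] + 1L, drop = TRUE]
  }
  new_static_image(out, provenance = list(frames = sort(as.integer(indices)),
                                          weighting = weighting))
}

#' Window and average a dynamic series in one call
#'
#' Convenience wrapper: [select_frames()] then [average_frames()], recording
#' the window in the output provenance.
#'
#' @inheritParams select_frames
#' @inheritParams average_frames
#' @return A `static_image`.
#' @examples
#' sched <- frame_schedule(seq(35, 65, by = 5), 5)
#' arr <- array(1, dim = c(2, 2, 2, nrow(sched)))
#' ds <- dynamic_series(arr, sched)
#' img <- window_average(ds, c(40, 60))
#' attr(img, "provenance")
#' @export
window_average <- function(series, window, rule = c("full", "midpoint"),
                           edge_tol = 1 / 60,
                           weighting = c("uniform", "duration")) {
  window <- as_time_window(window)
  idx <- select_frames(series$schedule, window, rule = rule,
                       edge_tol = edge_tol)
  img <- average_frames(series, idx, weighting = weighting)
  prov <- attr(img, "provenance")
  prov$window <- unclass(window)
  attr(img, "provenance") <- prov
  img
}
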