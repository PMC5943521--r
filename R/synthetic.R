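#' Specify a synthetic two-group amyloid cohort
#'
#' Describes the latent SUVR distribution of a young-control (YC, amyloid
#' negative) and an Alzheimer's-disease (AD, amyloid positive) group on the
#' standard scale. Defaults emulate the reference cohort anchoring the
#' Centiloid scale: group means 1.0095 and 2.0761 SUVR with 34 YC and 45 AD
#' subjects, giving the wide dynamic range and group separation on which
#' level-2 calibration relies. Within-group spreads default to 0.06 (YC)
#' and 0.35 (AD) SUVR.
#'
#' @param n_yc,n_ad Subjects per group (at least 2 each).
#' @param yc_mean,ad_mean Latent group mean SUVRs; `ad_mean > yc_mean`.
#' @param yc_sd,ad_sd Latent within-group SDs (non-negative).
#' @param distribution Latent distribution: `"gaussian"` (default) or
#'   `"uniform"` (matched mean and SD, stressing dynamic-range sensitivity).
#' @param seed Optional RNG seed for reproducible generation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_yc = 34, n_ad = 45,
                        yc_mean = 1.0095, ad_mean = 2.0761,
                        yc_sd = 0.06, ad_sd = 0.35,
                        distribution = c("gaussian", "uniform"),
                        seed = NULL) {
  distribution <- match.arg(distribution)
  if (n_yc < 2 || n_ad < 2) {
    stop("cohort_spec: at least 2 subjects per group", call. = FALSE)
  }
  if (yc_sd < 0 || ad_sd < 0) {
    stop("cohort_spec: SDs must be non-negative", call. = FALSE)
  }
  if (ad_mean <= yc_mean) {
    stop("cohort_spec: ad_mean must exceed yc_mean", call. = FALSE)
  }
  structure(list(n_yc = as.integer(n_yc), n_ad = as.integer(n_ad),
                 yc_mean = yc_mean, ad_mean = ad_mean,
                 yc_sd = yc_sd, ad_sd = ad_sd,
                 distribution = distribution, seed = seed),
            class = "cohort_spec")
}

#' Specify a synthetic SUVR measurement method
#'
#' A method observes each subject's latent standard-scale value through a
#' linear map plus independent measurement noise:
#' `observed = slope * true + intercept + noise`. Giving every method its
#' own noise puts error on both axes of any paired regression, the
#' errors-in-variables structure that motivates Deming regression.
#'
#' @param label Method label (e.g. `"S"`, `"MM50"`, `"MM40"`).
#' @param slope,intercept Latent linear map from the true scale
#'   (`slope > 0`).
#' @param noise_sd Measurement noise SD (non-negative).
#' @param noise `"homoscedastic"` (default) or `"proportional"`, where the
#'   noise SD scales with the latent signal (`noise_sd` per unit SUVR).
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(label, slope = 1, intercept = 0, noise_sd = 0.05,
                        noise = c("homoscedastic", "proportional")) {
  noise <- match.arg(noise)
  if (slope <= 0) stop("method_spec: slope must be positive", call. = FALSE)
  if (noise_sd < 0) {
    stop("method_spec: noise_sd must be non-negative", call. = FALSE)
  }
  structure(list(label = label, slope = slope, intercept = intercept,
                 noise_sd = noise_sd, noise = noise),
            class = "method_spec")
}

#' @rdname method_spec
#' @details `default_method_specs()` returns the three-method family used
#'   throughout the package's examples and tests: the standard method `S`
#'   (identity map), a same-window nonstandard processing method `MM50`
#'   producing larger values than the standard, and an earlier-window
#'   variant `MM40` slightly below `MM50`, each with 0.05 SUVR measurement
#'   noise.
#' @export
default_method_specs <- function() {
  list(method_spec("S", 1, 0, 0.05),
       method_spec("MM50", 1.25, 0.10, 0.05),
       method_spec("MM40", 1.18, 0.07, 0.05))
}

#' Generate a paired multi-method SUVR dataset
#'
#' Draws a latent true standard-scale value per subject from its group
#' distribution, then observes it through every method's linear map with
#' independent noise. The exact latent maps are returned so recovery can be
#' tested: a calibration pathway for method `m` should recover the inverse
#' of `m`'s latent map.
#'
#' @param cohort A [cohort_spec()].
#' @param methods List of [method_spec()]s (at least 2).
#' @param seed RNG seed; defaults to the cohort's seed. Generation is fully
#'   reproducible for a given seed.
#' @return A list with `table` (long SUVR table: `subject_id`, `group`,
#'   `method_label`, `suvr`) and `truth` (list with `latent`, a tibble of
#'   per-subject true values, and `maps`, a tibble of the latent method
#'   maps).
#' @examples
#' d <- generate_suvr_dataset(cohort_spec(seed = 1))
#' dplyr::count(d$table, group, method_label)
#' @export
generate_suvr_dataset <- function(cohort = cohort_spec(),
                                  methods = default_method_specs(),
                                  seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (length(methods) < 2) {
    stop("generate_suvr_dataset: at least 2 methods", call. = FALSE)
  }
  for (m in methods) stopifnot(inherits(m, "method_spec"))
  labels <- purrr::map_chr(methods, "label")
  if (anyDuplicated(labels)) {
    stop("generate_suvr_dataset: duplicated method labels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, mu, sd) {
    if (cohort$distribution == "uniform") {
      stats::runif(n, mu - sqrt(3) * sd, mu + sqrt(3) * sd)
    } else {
      stats::rnorm(n, mu, sd)
    }
  }
  latent <- tibble::tibble(
    subject_id = c(sprintf("YC%03d", seq_len(cohort$n_yc)),
                   sprintf("AD%03d", seq_len(cohort$n_ad))),
    group = rep(c("YC", "AD"), c(cohort$n_yc, cohort$n_ad)),
    true_suvr = c(draw(cohort$n_yc, cohort$yc_mean, cohort$yc_sd),
                  draw(cohort$n_ad, cohort$ad_mean, cohort$ad_sd))
  )
  table <- dplyr::bind_rows(purrr::map(methods, function(m) {
    signal <- m$slope * latent$true_suvr + m$intercept
    sd_vec <- if (m$noise == "proportional") {
      m$noise_sd * signal
    } else {
      rep(m$noise_sd, nrow(latent))
    }
    tibble::tibble(subject_id = latent$subject_id, group = latent$group,
                   method_label = m$label,
                   suvr = signal + stats::rnorm(nrow(latent), 0, sd_vec))
  }))
  maps <- tibble::tibble(label = labels,
                         slope = purrr::map_dbl(methods, "slope"),
                         intercept = purrr::map_dbl(methods, "intercept"),
                         noise_sd = purrr::map_dbl(methods, "noise_sd"))
  list(table = validate_suvr_table(table),
       truth = list(latent = latent, maps = maps))
}

#' Specify a dynamic PET phantom
#'
#' A rectangular phantom with a cortical (CTX) region and a reference
#' region, each carrying a piecewise-constant time-activity value defined by
#' time segments, sampled on a frame schedule. Windowed averages and SUVRs
#' of the phantom are therefore known in closed form.
#'
#' @param shape Spatial array dimensions (length 3).
#' @param segments Data frame with columns `start`, `end` (minutes), `ctx`,
#'   `ref` (positive activity values); segments must cover every frame.
#' @param schedule A [frame_schedule()].
#' @param background Activity value outside both regions.
#' @param noise_sd SD of voxel-wise Gaussian noise added to every frame
#'   (0 = noise-free).
#' @param seed Optional RNG seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(8, 8, 4),
                         segments = tibble::tibble(start = 0, end = 90,
                                                   ctx = 2, ref = 1),
                         schedule = frame_schedule(seq(35, 65, by = 5), 5),
                         background = 0.5, noise_sd = 0, seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 2),
            inherits(schedule, "frame_schedule"))
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("start", "end", "ctx", "ref") %in% names(segments)))
  if (any(segments$end <= segments$start) ||
      any(segments$ctx <= 0) || any(segments$ref <= 0)) {
    stop("phantom_spec: segments need start < end and positive values",
         call. = FALSE)
  }
  structure(list(shape = as.integer(shape), segments = segments,
                 schedule = schedule, background = background,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# time-weighted mean of the piecewise-constant activity over [t0, t1]
segment_mean <- function(segments, col, t0, t1) {
  overlap <- pmax(0, pmin(segments$end, t1) - pmax(segments$start, t0))
  if (abs(sum(overlap) - (t1 - t0)) > 1e-9) {
    stop("phantom segments do not cover a frame interval", call. = FALSE)
  }
  sum(overlap * segments[[col]]) / (t1 - t0)
}

#' Generate a dynamic PET phantom
#'
#' Realises a [phantom_spec()] as a [dynamic_series()] plus its region
#' masks. The CTX region occupies the lower half of the x-axis and the
#' reference region the upper half; each frame holds the region's
#' time-averaged activity over the frame interval (plus optional noise).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `series` (a [dynamic_series()]), `masks` (named list
#'   with `CTX` and `reference` 3D logical arrays), and `frame_values`
#'   (tibble of the closed-form per-frame region values).
#' @examples
#' ph <- generate_dynamic_phantom(phantom_spec())
#' img <- window_average(ph$series, c(40, 60))
#' voi_statistic(img, ph$masks$CTX, "mean")
#' @export
generate_dynamic_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sched <- spec$schedule
  nfr <- nrow(sched)
  ctx_mask <- array(FALSE, spec$shape)
  ref_mask <- array(FALSE, spec$shape)
  half <- floor(spec$shape[1] / 2)
  ctx_mask[seq_len(half), , ] <- TRUE
  ref_mask[(half + 1):spec$shape[1], , ] <- TRUE
  fv <- tibble::tibble(
    frame_index = sched$frame_index,
    ctx = purrr::map2_dbl(sched$start_min, sched$end_min,
                          ~segment_mean(spec$segments, "ctx", .x, .y)),
    ref = purrr::map2_dbl(sched$start_min, sched$end_min,
                          ~segment_mean(spec$segments, "ref", .x, .y))
  )
  if (!is.null(spec$seed)) set.seed(spec$seed)
  vox <- array(spec$background, c(spec$shape, nfr))
  for (k in seq_len(nfr)) {
    fr <- array(spec$background, spec$shape)
    fr[ctx_mask] <- fv$ctx[fv$frame_index == sched$frame_index[k]]
    fr[ref_mask] <- fv$ref[fv$frame_index == sched$frame_index[k]]
    if (spec$noise_sd > 0) {
      fr <- fr + stats::rnorm(length(fr), 0, spec$noise_sd)
    }
    vox[, , , sched$frame_index[k] + 1L] <- fr
  }
  list(series = dynamic_series(vox, sched),
       masks = list(CTX = ctx_mask, reference = ref_mask),
       frame_values = fv)
}
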