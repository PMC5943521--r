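# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# normal-equation OLS via explicit sums
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- (sum(y) - b * sum(x)) / n
  c(intercept = a, slope = b)
}

# Deming fit by numerical minimization of the weighted orthogonal loss
# sum((y - a - b x)^2 / (lambda + b^2)). The intercept is profiled out
# (optimal a is mean(y - b x)); the slope is found by root-finding on the
# gradient of the profiled loss, bracketing around the OLS slope.
deming_oracle <- function(x, y, lambda = 1) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  grad_num <- function(b) {  # numerator of dL/db after profiling a
    r <- yc - b * xc
    -(lambda + b^2) * sum(r * xc) - b * sum(r^2)
  }
  b0 <- ols_oracle(x, y)[["slope"]]
  bracket <- sort(c(b0 / 10, b0 * 10))
  b <- stats::uniroot(grad_num, bracket, tol = 1e-14)$root
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# a 5-minute frame tiling of 35-70 minutes post-injection
tiling_schedule <- function() frame_schedule(seq(35, 65, by = 5), 5)

# small dynamic series with specified per-frame constant values
constant_series <- function(frame_values, shape = c(3, 3, 2),
                            schedule = tiling_schedule()) {
  stopifnot(length(frame_values) == nrow(schedule))
  vox <- array(0, c(shape, length(frame_values)))
  for (k in seq_along(frame_values)) vox[, , , k] <- frame_values[k]
  dynamic_series(vox, schedule)
}

# noise-free paired table where every method is an exact affine map of S
exact_chain_table <- function(s_values = c(seq(0.9, 1.2, length.out = 6),
                                           seq(1.7, 2.5, length.out = 6)),
                              mm50 = c(slope = 1.25, intercept = 0.10),
                              mm40_from_mm50 = c(slope = 0.95,
                                                 intercept = -0.02)) {
  groups <- rep(c("YC", "AD"), each = length(s_values) / 2)
  ids <- sprintf("P%02d", seq_along(s_values))
  mm50_v <- mm50[["slope"]] * s_values + mm50[["intercept"]]
  mm40_v <- mm40_from_mm50[["slope"]] * mm50_v +
    mm40_from_mm50[["intercept"]]
  dplyr::bind_rows(
    tibble::tibble(subject_id = ids, group = groups, method_label = "S",
                   suvr = s_values),
    tibble::tibble(subject_id = ids, group = groups, method_label = "MM50",
                   suvr = mm50_v),
    tibble::tibble(subject_id = ids, group = groups, method_label = "MM40",
                   suvr = mm40_v)
  )
}
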