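#' Add white Gaussian measurement noise at a prescribed SNR
#'
#' Noise variance is set per frame to `P_signal / 10^(snr_db/10)` where
#' `P_signal` is the mean square of the clean frame, matching the decibel
#' definition SNR_dB = 10 log10(P_signal / P_noise).  `snr_db = Inf` returns
#' the frame unchanged.
#'
#' @param v_clean a `voltage_frame` (or bare numeric vector).
#' @param snr_db signal-to-noise ratio in dB (the study uses Inf, 40, 30, 20,
#'   10; any finite value is accepted).
#' @param rng_seed integer seed.
#' @return an object of the same type with noise added.
#' @export
add_noise <- function(v_clean, snr_db, rng_seed) {
  vals <- if (inherits(v_clean, "voltage_frame")) v_clean$values else v_clean
  if (is.infinite(snr_db)) return(v_clean)
  p_sig <- mean(vals^2)
  if (p_sig <= 0) stop("zero-power clean signal with finite SNR", call. = FALSE)
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  noisy <- with_seed(rng_seed, vals + stats::rnorm(length(vals), sd = sd_n))
  if (inherits(v_clean, "voltage_frame")) {
    v_clean$values <- noisy
    v_clean
  } else noisy
}

#' Normalization statistics for voltage-difference vectors
#'
#' @param y_list list (or matrix with samples in columns) of raw
#'   reference-subtracted voltage vectors.
#' @return a `voltage_norm_stats` list with global `mean` and `sd`.
#' @export
voltage_norm_stats <- function(y_list) {
  y <- if (is.list(y_list)) unlist(y_list) else as.vector(y_list)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  structure(list(mean = mean(y), sd = s), class = "voltage_norm_stats")
}

#' Normalize a noisy frame against a reference frame
#'
#' Subtracts the homogeneous-background reference frame and applies the global
#' standardization `(y - mean) / sd` used for network conditioning.  The
#' transform is affine and exactly invertible via [denormalize_voltage()].
#'
#' @param v_noisy noisy current-state frame (`voltage_frame` or vector).
#' @param v_ref reference frame from the homogeneous background.
#' @param stats a `voltage_norm_stats`; `NULL` skips standardization.
#' @return numeric vector of normalized voltage differences.
#' @export
normalize_voltage <- function(v_noisy, v_ref, stats = NULL) {
  a <- if (inherits(v_noisy, "voltage_frame")) v_noisy$values else v_noisy
  b <- if (inherits(v_ref, "voltage_frame")) v_ref$values else v_ref
  if (length(a) != length(b)) stop("frame length mismatch", call. = FALSE)
  y <- a - b
  if (!is.null(stats)) y <- (y - stats$mean) / stats$sd
  y
}

#' Invert [normalize_voltage()] back to a raw voltage difference
#' @param y normalized vector.
#' @param stats the `voltage_norm_stats` used to normalize.
#' @return raw voltage difference vector (volts).
#' @export
denormalize_voltage <- function(y, stats) {
  y * stats$sd + stats$mean
}
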