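#' Detector-current time series
#'
#' A DiFC trace: photodetector current samples (nA) at a fixed rate
#' (2 kHz by default).
#'
#' @param samples numeric vector of currents, nA.
#' @param sample_rate sampling rate, Hz (> 0).
#' @return A `difc_trace` with fields `samples`, `sample_rate`,
#'   `duration` (s).
#' @export
difc_trace <- function(samples, sample_rate = 2000) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_invalid("samples must be a non-empty numeric vector")
  if (!is_scalar(sample_rate) || sample_rate <= 0)
    stop_invalid("sample_rate must be > 0")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = length(samples) / sample_rate),
            class = "difc_trace")
}

#' @export
print.difc_trace <- function(x, ...) {
  cat(sprintf("<difc_trace> %d samples at %g Hz (%.3g s), median %.4g nA\n",
              length(x$samples), x$sample_rate, x$duration,
              median(x$samples)))
  invisible(x)
}

#' @export
as.data.frame.difc_trace <- function(x, ...) {
  data.frame(time_s = (seq_along(x$samples) - 1) / x$sample_rate,
             current_nA = x$samples)
}

#' Read/write traces as two-column CSV
#'
#' Column layout: `time_s, current_nA` with a one-line header. The sample
#' rate is recovered from the median time step on read.
#'
#' @param trace a [difc_trace()].
#' @param path CSV file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "difc_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "current_nA") %in% names(df)))
    stop_invalid("trace CSV must have columns time_s, current_nA")
  dt <- median(diff(df$time_s))
  difc_trace(df$current_nA, sample_rate = 1 / dt)
}

# --- moving-window statistics ------------------------------------------------

# Centered moving mean and sd with windows truncated at the trace ends,
# ignoring NA (outlier-masked) samples. O(n) via cumulative sums.
roll_stats <- function(x, width) {
  n <- length(x)
  ok <- !is.na(x)
  xv <- ifelse(ok, x, 0)
  cs <- cumsum(xv)
  cs2 <- cumsum(xv^2)
  ck <- cumsum(as.numeric(ok))
  hw <- floor(width / 2)
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  sum_x <- cs[hi] - c(0, cs)[lo]
  sum_x2 <- cs2[hi] - c(0, cs2)[lo]
  m <- ck[hi] - c(0, ck)[lo]
  mean_w <- ifelse(m > 0, sum_x / m, NA_real_)
  var_w <- ifelse(m > 1, pmax(0, (sum_x2 - sum_x^2 / m) / (m - 1)), NA_real_)
  list(mean = mean_w, sd = sqrt(var_w), count = m)
}

# Mask samples more than mad_k scaled median absolute deviations from the
# trace median (scaled-MAD rule, consistency constant 1.4826).
mask_outliers <- function(x, mad_k) {
  med <- median(x)
  s <- mad(x)           # 1.4826 * MAD
  if (s == 0) return(x) # constant (or half-constant) trace: nothing to mask
  ifelse(abs(x - med) > mad_k * s, NA_real_, x)
}

#' Robust background level of a trace
#'
#' Masks outliers (samples more than `mad_k` scaled median absolute
#' deviations from the trace median), computes the centered moving mean
#' over a `window_s` window (truncated at the trace ends), and returns the
#' median of the moving-mean values. Transient fluorescence peaks are
#' rejected both by the outlier mask and by the final median.
#'
#' @param trace a [difc_trace()], at least one window long.
#' @param window_s moving-window length, s.
#' @param mad_k outlier threshold in scaled-MAD units.
#' @return Background level, nA.
#' @export
estimate_background <- function(trace, window_s = 1, mad_k = 3) {
  stopifnot(inherits(trace, "difc_trace"))
  width <- round(window_s * trace$sample_rate)
  if (length(trace$samples) < width)
    stop_invalid("trace (%g s) is shorter than the window (%g s)",
                 trace$duration, window_s)
  x <- mask_outliers(trace$samples, mad_k)
  median(roll_stats(x, width)$mean, na.rm = TRUE)
}

#' Robust noise level of a trace
#'
#' As [estimate_background()] but reducing the moving standard deviation:
#' outlier masking, centered moving sd over `window_s`, then the median of
#' moving-sd values.
#'
#' @inheritParams estimate_background
#' @return Noise level (standard deviation), nA.
#' @export
estimate_noise <- function(trace, window_s = 1, mad_k = 3) {
  stopifnot(inherits(trace, "difc_trace"))
  width <- round(window_s * trace$sample_rate)
  if (length(trace$samples) < width)
    stop_invalid("trace (%g s) is shorter than the window (%g s)",
                 trace$duration, window_s)
  x <- mask_outliers(trace$samples, mad_k)
  median(roll_stats(x, width)$sd, na.rm = TRUE)
}

#' Moving-median background subtraction for peak display
#'
#' The display-oriented alternative to the calibration background: a
#' running-median baseline (5 s window by default) subtracted from the
#' raw trace.
#'
#' @inheritParams estimate_background
#' @return A `difc_trace` of background-subtracted currents.
#' @export
subtract_moving_median <- function(trace, window_s = 5) {
  stopifnot(inherits(trace, "difc_trace"))
  width <- round(window_s * trace$sample_rate)
  width <- min(width, length(trace$samples))
  if (width %% 2 == 0) width <- width - 1L
  base <- stats::runmed(trace$samples, k = max(width, 1L), endrule = "median")
  difc_trace(trace$samples - base, trace$sample_rate)
}

#' Detect transient fluorescence peaks in a trace
#'
#' Local maxima of the background-subtracted trace with amplitude at least
#' `k_noise` times the noise level and pairwise separation at least
#' `min_sep_s`; when two candidates fall closer than the minimum
#' separation, the larger is kept. Amplitudes are reported
#' background-subtracted.
#'
#' @param trace a [difc_trace()].
#' @param background background level, nA (e.g. [estimate_background()]).
#' @param noise noise level, nA (> 0; e.g. [estimate_noise()]).
#' @param k_noise amplitude threshold in noise units.
#' @param min_sep_s minimum separation between reported peaks, s.
#' @return Data frame with `time_s` and `amplitude_nA`, ordered by time.
#' @export
detect_peaks <- function(trace, background, noise, k_noise = 5,
                         min_sep_s = 1) {
  stopifnot(inherits(trace, "difc_trace"))
  if (!is_scalar(noise) || noise <= 0)
    stop_invalid("noise must be > 0")
  y <- trace$samples - background
  min_sep <- max(1L, round(min_sep_s * trace$sample_rate))
  pk <- pracma::findpeaks(y, minpeakheight = k_noise * noise,
                          minpeakdistance = min_sep)
  if (is.null(pk))
    return(data.frame(time_s = numeric(0), amplitude_nA = numeric(0)))
  ord <- order(pk[, 2])
  data.frame(time_s = (pk[ord, 2] - 1) / trace$sample_rate,
             amplitude_nA = pk[ord, 1])
}

# --- unit conversion ---------------------------------------------------------

#' Detector current to reflectance conversion constant
#'
#' @param factor reflectance per unit current, W mm^-2 nA^-1. The default
#'   271e-15 corresponds to a detector gain of 1e4, detector area of
#'   0.565 mm^2, and a wavelength of 810 nm; it cancels in every unitless
#'   quantity (SNR, sigma_rel) and only anchors absolute reflectances.
#' @param gain,detector_area_mm2,wavelength_nm the ingredients, recorded
#'   for provenance.
#' @return A `conversion_constant` object.
#' @export
conversion_constant <- function(factor = 271e-15, gain = 1e4,
                                detector_area_mm2 = 0.565,
                                wavelength_nm = 810) {
  if (!is_scalar(factor) || factor <= 0) stop_invalid("factor must be > 0")
  structure(list(factor = factor, gain = gain,
                 detector_area_mm2 = detector_area_mm2,
                 wavelength_nm = wavelength_nm),
            class = "conversion_constant")
}

#' Convert detector current to reflectance
#'
#' @param i_nA current(s), nA.
#' @param conv a [conversion_constant()].
#' @return Reflectance, W mm^-2 (multiply by 1e12 for pW mm^-2).
#' @export
current_to_reflectance <- function(i_nA, conv = conversion_constant()) {
  stopifnot(inherits(conv, "conversion_constant"))
  i_nA * conv$factor
}

# --- coefficient fitting (exact inverses of the forward model) ---------------

#' Fit the surface-weighted AF prefactor from a background reflectance
#'
#' Inverts the background forward model for the exponentially-halving
#' depth profile: `prefactor = R0 / (P_src * sum W * 2^(-z/half_depth))`.
#' [background_reflectance()] of the fitted model reproduces `r0` exactly.
#'
#' @param r0 background reflectance, mW mm^-2.
#' @param p_src source power, mW.
#' @param W a [sensitivity_map()] grid.
#' @param half_depth halving depth of the AF profile, mm.
#' @return Prefactor `mu_a,AF * eta_AF` at the surface, mm^-1.
#' @export
fit_af_het <- function(r0, p_src, W, half_depth = 0.1) {
  stopifnot(inherits(W, "sensitivity_grid"))
  z <- voxel_centers(W$medium)$z
  wsum <- sum(apply(W$values, 3, sum) * 2^(-z / half_depth))
  if (wsum <= 0) stop_invalid("weighted sensitivity sum is zero (degenerate geometry)")
  r0 / (p_src * wsum)
}

#' Fit the homogeneous AF coefficient from a background reflectance
#'
#' `coefficient = R0 / (P_src * sum W)`; the exact inverse of
#' [background_reflectance()] with a homogeneous AF model.
#'
#' @inheritParams fit_af_het
#' @return Coefficient `mu_a,AF * eta_AF`, mm^-1.
#' @export
fit_af_hom <- function(r0, p_src, W) {
  stopifnot(inherits(W, "sensitivity_grid"))
  wsum <- sum(W$values)
  if (wsum <= 0) stop_invalid("sensitivity sum is zero (degenerate geometry)")
  r0 / (p_src * wsum)
}

#' Fit the target coefficient from a peak reflectance
#'
#' Assumes the peak maximum occurred with the target at the
#' highest-sensitivity voxel:
#' `coefficient = (R_peak - R0) / (P_src * max W)`.
#'
#' @param r_peak_minus_r0 background-subtracted peak reflectance, mW mm^-2.
#' @inheritParams fit_af_het
#' @return Coefficient `mu_a,target * eta_target`, mm^-1.
#' @export
fit_target <- function(r_peak_minus_r0, p_src, W) {
  stopifnot(inherits(W, "sensitivity_grid"))
  wmax <- max(W$values)
  if (wmax <= 0) stop_invalid("sensitivity grid is all zero (degenerate geometry)")
  r_peak_minus_r0 / (p_src * wmax)
}

#' Full calibration chain on a trace
#'
#' Runs the robust background and noise estimates, detects peaks, converts
#' currents to reflectance, and — when a sensitivity grid is supplied —
#' fits the AF prefactors (both depth profiles) and the target coefficient
#' from the mean peak amplitude.
#'
#' @param trace a [difc_trace()].
#' @param W optional [sensitivity_map()] grid for coefficient fitting.
#' @param p_src source power, mW.
#' @param conv a [conversion_constant()].
#' @param window_s,mad_k,k_noise,min_sep_s estimator settings, see
#'   [estimate_background()] and [detect_peaks()].
#' @param half_depth AF halving depth for the surface-weighted fit, mm.
#' @return A `calibration_result` list: `background_nA`,
#'   `background_mW_mm2`, `noise_nA`, `noise_mW_mm2`, `sigma_rel`,
#'   `peaks` (data frame), `peak_mean_nA`, and (with `W`)
#'   `af_coefficient_het`, `af_coefficient_hom`, `target_coefficient`
#'   (mm^-1).
#' @export
calibrate_trace <- function(trace, W = NULL, p_src = 75,
                            conv = conversion_constant(),
                            window_s = 1, mad_k = 3,
                            k_noise = 5, min_sep_s = 1,
                            half_depth = 0.1) {
  bg <- estimate_background(trace, window_s, mad_k)
  nz <- estimate_noise(trace, window_s, mad_k)
  peaks <- if (nz > 0) detect_peaks(trace, bg, nz, k_noise, min_sep_s)
           else data.frame(time_s = numeric(0), amplitude_nA = numeric(0))
  to_mw <- function(i_nA) current_to_reflectance(i_nA, conv) * 1e3  # W -> mW
  res <- list(
    background_nA = bg,
    background_mW_mm2 = to_mw(bg),
    noise_nA = nz,
    noise_mW_mm2 = to_mw(nz),
    sigma_rel = nz / bg,
    peaks = peaks,
    peak_mean_nA = if (nrow(peaks)) mean(peaks$amplitude_nA) else NA_real_,
    p_src = p_src
  )
  if (!is.null(W)) {
    res$af_coefficient_het <- fit_af_het(res$background_mW_mm2, p_src, W,
                                         half_depth)
    res$af_coefficient_hom <- fit_af_hom(res$background_mW_mm2, p_src, W)
    res$target_coefficient <- if (nrow(peaks))
      fit_target(to_mw(res$peak_mean_nA), p_src, W) else NA_real_
  }
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result>\n  background %.4g nA (%.4g pW mm^-2)\n",
              x$background_nA, x$background_mW_mm2 * 1e9))
  cat(sprintf("  noise      %.4g nA (%.4g pW mm^-2), sigma_rel %.4g\n",
              x$noise_nA, x$noise_mW_mm2 * 1e9, x$sigma_rel))
  cat(sprintf("  peaks      %d detected, mean amplitude %.4g nA\n",
              nrow(x$peaks), x$peak_mean_nA))
  if (!is.null(x$af_coefficient_hom))
    cat(sprintf("  coefficients: AF het %.4g, AF hom %.4g, target %.4g mm^-1\n",
                x$af_coefficient_het, x$af_coefficient_hom,
                x$target_coefficient))
  invisible(x)
}
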