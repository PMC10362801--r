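#' Schedule of transient fluorescence peaks
#'
#' @param times_s event times, s.
#' @param amplitudes_nA peak amplitudes above background, nA.
#' @param widths_ms full width at half maximum of each peak, ms (> 0).
#'   Default 10 ms, a typical in-vivo transit width.
#' @param shape `"gaussian"`, or `"waveform"` with a custom normalized
#'   waveform (see `waveform`).
#' @param waveform for `shape = "waveform"`: a data frame with
#'   `offset_s` (time relative to the event) and `relative` (unit-peak
#'   signal), e.g. a transit profile rendered by [flow_trace()] via
#'   [flow_trace_waveform()]. Linearly interpolated, zero outside its
#'   support.
#' @return A `peak_schedule` object.
#' @export
peak_schedule <- function(times_s = numeric(0), amplitudes_nA = numeric(0),
                          widths_ms = 10, shape = c("gaussian", "waveform"),
                          waveform = NULL) {
  shape <- match.arg(shape)
  n <- length(times_s)
  if (length(amplitudes_nA) != n)
    stop_invalid("times and amplitudes must have equal length")
  widths_ms <- rep_len(widths_ms, n)
  if (n && any(widths_ms <= 0)) stop_invalid("widths must be > 0")
  if (shape == "waveform" && is.null(waveform))
    stop_invalid("shape = 'waveform' requires a waveform data frame")
  structure(list(times_s = as.numeric(times_s),
                 amplitudes_nA = as.numeric(amplitudes_nA),
                 widths_ms = as.numeric(widths_ms),
                 shape = shape, waveform = waveform),
            class = "peak_schedule")
}

#' Synthesize a DiFC trace with known ground truth
#'
#' Baseline current with multiplicative relative Gaussian noise —
#' `background * (1 + N(0, sigma_rel))` per sample, matching the
#' constant-relative-noise model `sigma_I = sigma_rel * R` — plus the
#' scheduled transient peaks. Note the noise is relative (multiplicative),
#' not additive-absolute; both conventions exist for photodetector traces
#' and this generator deliberately uses the former.
#'
#' @param background baseline current, nA (>= 0).
#' @param sigma_rel relative noise level (>= 0).
#' @param schedule a [peak_schedule()]; events must fall inside the trace.
#' @param duration_s trace length, s (> 0).
#' @param sample_rate Hz.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical and the caller's RNG stream is preserved.
#' @return A [difc_trace()] whose `ground_truth` attribute records every
#'   generator parameter.
#' @export
make_trace <- function(background = 170, sigma_rel = 0.031,
                       schedule = peak_schedule(), duration_s = 60,
                       sample_rate = 2000, seed = NULL) {
  if (!is_scalar(background) || background < 0)
    stop_invalid("background must be >= 0")
  if (!is_scalar(sigma_rel) || sigma_rel < 0)
    stop_invalid("sigma_rel must be >= 0")
  if (!is_scalar(duration_s) || duration_s <= 0)
    stop_invalid("duration must be > 0")
  stopifnot(inherits(schedule, "peak_schedule"))
  if (length(schedule$times_s) &&
      (any(schedule$times_s < 0) || any(schedule$times_s > duration_s)))
    stop_invalid("peak times must lie within the trace duration")
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- local_seed(seed, background * (1 + rnorm(n, 0, sigma_rel)))
  if (length(schedule$times_s)) {
    for (i in seq_along(schedule$times_s)) {
      t0 <- schedule$times_s[i]
      a <- schedule$amplitudes_nA[i]
      if (schedule$shape == "gaussian") {
        sig <- schedule$widths_ms[i] / 1000 / (2 * sqrt(2 * log(2)))  # FWHM -> sd
        sel <- abs(t - t0) < 6 * sig
        x[sel] <- x[sel] + a * exp(-(t[sel] - t0)^2 / (2 * sig^2))
      } else {
        wf <- schedule$waveform
        sel <- t - t0 >= min(wf$offset_s) & t - t0 <= max(wf$offset_s)
        x[sel] <- x[sel] + a * approx(wf$offset_s, wf$relative,
                                      xout = t[sel] - t0, rule = 2)$y
      }
    }
  }
  tr <- difc_trace(x, sample_rate)
  attr(tr, "ground_truth") <- list(
    background_nA = background, sigma_rel = sigma_rel,
    peak_times_s = schedule$times_s,
    peak_amplitudes_nA = schedule$amplitudes_nA,
    peak_widths_ms = schedule$widths_ms,
    shape = schedule$shape,
    duration_s = duration_s, sample_rate = sample_rate, seed = seed)
  tr
}

#' Toy grids with closed-form sensitivity
#'
#' Small fluence-grid pairs whose Jacobian `W` is hand-checkable: oracle
#' fixtures for the fluorescence and calibration algebra. Patterns:
#' `uniform` (constant fluences `a` and `b`, so `W = a * b * V`
#' everywhere), `point` (fluences supported on a single central voxel),
#' and `separable` (`Phi_src[i,j,k] = i`, `Phi_det[i,j,k] = j * k`, so
#' `sum(W)` factors into a product of axis sums).
#'
#' @param shape integer 3-vector of voxel counts, each <= 32.
#' @param pattern `"uniform"`, `"point"`, or `"separable"`.
#' @param voxel voxel edge, mm.
#' @param a,b uniform fluence values for the `uniform` pattern.
#' @return List with `phi_src`, `phi_det` (fluence grids), `W`
#'   (sensitivity grid), `medium`, and a `ground_truth` list of the
#'   pattern parameters.
#' @export
make_toy_grids <- function(shape = c(3, 3, 3),
                           pattern = c("uniform", "point", "separable"),
                           voxel = 1, a = 2, b = 3) {
  pattern <- match.arg(pattern)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_invalid("shape must be three positive voxel counts")
  if (any(shape > 32L))
    stop_invalid("toy grids are capped at 32 voxels per axis")
  med <- optical_medium(extent = shape * voxel, voxel = voxel)
  dims <- med$n_vox
  mk <- function(vals, role) {
    structure(list(values = array(vals, dim = dims), tallies = NULL,
                   medium = med,
                   optode = optode(c(0, 0), role,
                                   beam = if (role == "source") "pencil" else "cone"),
                   n_photons = 0, seed = NA_integer_,
                   gates = list(n = 1, t_end_ns = Inf)),
              class = "fluence_grid")
  }
  if (pattern == "uniform") {
    src <- array(a, dim = dims); det <- array(b, dim = dims)
  } else if (pattern == "point") {
    src <- array(0, dim = dims); det <- array(0, dim = dims)
    ci <- (shape + 1L) %/% 2L
    src[ci[1], ci[2], ci[3]] <- a
    det[ci[1], ci[2], ci[3]] <- b
  } else {
    idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                       k = seq_len(dims[3]))
    src <- array(idx$i, dim = dims)
    det <- array(idx$j * idx$k, dim = dims)
  }
  phi_src <- mk(src, "source")
  phi_det <- mk(det, "detector")
  W <- sensitivity_map(phi_src, phi_det)
  list(phi_src = phi_src, phi_det = phi_det, W = W, medium = med,
       ground_truth = list(pattern = pattern, shape = shape, voxel = voxel,
                           a = a, b = b))
}
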