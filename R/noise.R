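#' Coupling-coefficient noise parameters
#'
#' Measured intensities are modeled as theoretical reflectances multiplied
#' by Gaussian coupling-coefficient random variables of mean one: one
#' factor per optode (variance `p_opt * sigma_rel^2`, shared by the two
#' pairs containing that optode) and one non-cancelable (NC) factor per
#' pair (variance `p_nc * sigma_rel^2`). The variance fractions satisfy
#' `2 * p_opt + p_nc = 1`, so the total relative intensity noise is
#' `sigma_rel` for every single-distance pair regardless of `p_nc`; only
#' the DR, which cancels the per-optode factors exactly, is sensitive to
#' `p_nc`.
#'
#' @param sigma_rel relative intensity noise `sigma_I / R` (>= 0). Default
#'   0.031, the phantom-calibrated value.
#' @param p_nc non-cancelable variance fraction in `[0, 1]`. Default 0.05.
#' @param p_opt per-optode variance fraction; derived as `(1 - p_nc) / 2`
#'   when omitted, and checked against the constraint when supplied.
#' @return A `noise_params` object with fields `sigma_rel`, `p_nc`, `p_opt`.
#' @export
noise_params <- function(sigma_rel = 0.031, p_nc = 0.05, p_opt = NULL) {
  if (!is_scalar(sigma_rel) || sigma_rel < 0)
    stop_invalid("sigma_rel must be >= 0")
  if (!is_scalar(p_nc) || p_nc < 0 || p_nc > 1)
    stop_invalid("p_nc must be in [0, 1]")
  derived <- (1 - p_nc) / 2
  if (is.null(p_opt)) p_opt <- derived
  else if (!is_scalar(p_opt) || abs(2 * p_opt + p_nc - 1) > 1e-9)
    stop_invalid("variance fractions must satisfy 2 * p_opt + p_nc = 1 (got 2*%g + %g = %g)",
                 p_opt, p_nc, 2 * p_opt + p_nc)
  structure(list(sigma_rel = sigma_rel, p_nc = p_nc, p_opt = p_opt),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> sigma_rel %g, p_nc %g, p_opt %g\n",
              x$sigma_rel, x$p_nc, x$p_opt))
  invisible(x)
}

#' Sample measured intensity quartets under coupling-coefficient noise
#'
#' Each draw generates four per-optode factors `C1, C2, CA, CB` (shared
#' within the draw by the two pairs containing that optode) and four
#' per-pair non-cancelable factors, all Gaussian with mean 1, and forms
#' `I_pair = C_source * C_detector * C_NC,pair * R_pair`. Factors are drawn
#' in the fixed order C1, C2, CA, CB, then the NC factors for A1, A2, B1,
#' B2, vectorized over draws, so results are reproducible for a fixed seed.
#'
#' @param r_quartet theoretical reflectance quartet: an
#'   [intensity_quartet()] or named vector with `A1, A2, B1, B2`, all > 0.
#' @param params a [noise_params()].
#' @param n_draws number of draws (>= 1).
#' @param seed integer seed; the caller's RNG stream is preserved.
#' @return `n_draws x 4` matrix of sampled intensities with columns
#'   `A1, A2, B1, B2`.
#' @export
sample_intensities <- function(r_quartet, params, n_draws = 1e4, seed = NULL) {
  stopifnot(inherits(params, "noise_params"))
  r <- as_quartet_matrix(r_quartet)[1, ]
  if (any(r <= 0)) stop_invalid("reflectances must be > 0")
  if (!is_count(n_draws)) stop_invalid("n_draws must be a positive count")
  s_opt <- sqrt(params$p_opt) * params$sigma_rel
  s_nc <- sqrt(params$p_nc) * params$sigma_rel
  local_seed(seed, {
    C1 <- rnorm(n_draws, 1, s_opt)
    C2 <- rnorm(n_draws, 1, s_opt)
    CA <- rnorm(n_draws, 1, s_opt)
    CB <- rnorm(n_draws, 1, s_opt)
    NC <- matrix(rnorm(4 * n_draws, 1, s_nc), ncol = 4,
                 dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
    cbind(
      A1 = C1 * CA * NC[, "A1"] * r[["A1"]],
      A2 = C2 * CA * NC[, "A2"] * r[["A2"]],
      B1 = C1 * CB * NC[, "B1"] * r[["B1"]],
      B2 = C2 * CB * NC[, "B2"] * r[["B2"]])
  })
}

#' Noise statistics of the sampled dual ratio
#'
#' Applies [dual_ratio()] to sampled intensity quartets and reports the
#' empirical mean and standard deviation, alongside the theoretical DR of
#' the noiseless reflectances and the first-order (delta-method) standard
#' deviation `sqrt(p_nc) * sigma_rel * DR_theo`.
#'
#' @inheritParams sample_intensities
#' @return List with `mean`, `sd`, `dr_theoretical`, `sd_delta_method`,
#'   `n_draws`.
#' @export
dr_noise_stats <- function(r_quartet, params, n_draws = 1e4, seed = NULL) {
  dr_theo <- dual_ratio(r_quartet)
  draws <- sample_intensities(r_quartet, params, n_draws, seed)
  drs <- dual_ratio(draws)
  list(mean = mean(drs), sd = sd(drs),
       dr_theoretical = unname(dr_theo),
       sd_delta_method = sqrt(params$p_nc) * params$sigma_rel * unname(dr_theo),
       n_draws = n_draws)
}

#' Signal-to-noise ratio of a background-subtracted measurement
#'
#' Signed SNR: the expected change of a data type from baseline divided by
#' the baseline-condition standard deviation of the same data type. The
#' sign is retained — a strongly negative DR change is as informative as a
#' positive one for detecting a transiting target.
#'
#' @param delta_signal background-subtracted signal change.
#' @param baseline_sd baseline standard deviation (> 0) in the same units.
#' @return `delta_signal / baseline_sd`, dimensionless, signed.
#' @export
snr <- function(delta_signal, baseline_sd) {
  if (any(!is.finite(baseline_sd)) || any(baseline_sd <= 0))
    stop_invalid("baseline_sd must be > 0 (SNR undefined otherwise)")
  delta_signal / baseline_sd
}

# baseline sd of a data type under noise_params, analytic where possible
baseline_sd_sd_pair <- function(r0, params) {
  if (params$sigma_rel > 0.2)
    stop_invalid("analytic baseline noise assumes sigma_rel << 1 (got %g)",
                 params$sigma_rel)
  params$sigma_rel * r0
}
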