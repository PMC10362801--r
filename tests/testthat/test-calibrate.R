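test_that("background estimation is robust to noise and transient peaks", {
  # constant trace
  expect_equal(estimate_background(difc_trace(rep(170, 4000))), 170)
  # Gaussian relative noise, known ground truth
  tr <- make_trace(170, 5.29 / 170, duration_s = 60, seed = 31)
  expect_equal(estimate_background(tr), 170, tolerance = 0.5 / 170)
  # ten large, short peaks must not shift the background
  sched <- peak_schedule(times_s = seq(4, 56, length.out = 10),
                         amplitudes_nA = rep(500, 10), widths_ms = 10)
  trp <- make_trace(170, 5.29 / 170, sched, duration_s = 60, seed = 31)
  expect_equal(estimate_background(trp), 170, tolerance = 0.5 / 170)
  # too-short trace
  expect_error(estimate_background(difc_trace(rep(1, 100))), "shorter")
})

test_that("noise estimation recovers the injected standard deviation", {
  expect_equal(estimate_noise(difc_trace(rep(170, 4000))), 0)
  tr <- make_trace(170, 5.29 / 170, duration_s = 60, seed = 37)
  nz <- estimate_noise(tr)
  expect_equal(nz, 5.29, tolerance = 0.05)
  # sparse large peaks barely perturb the estimate
  sched <- peak_schedule(times_s = seq(4, 56, length.out = 8),
                         amplitudes_nA = rep(400, 8), widths_ms = 10)
  trp <- make_trace(170, 5.29 / 170, sched, duration_s = 60, seed = 37)
  expect_equal(estimate_noise(trp) / nz, 1, tolerance = 0.05)
})

test_that("peak detection applies the amplitude threshold and separation rule", {
  # flat trace: nothing to find
  flat <- difc_trace(rep(170, 8000))
  expect_equal(nrow(detect_peaks(flat, 170, 1)), 0)
  expect_error(detect_peaks(flat, 170, 0), "> 0")
  # three peaks of 10x noise, 2 s apart
  sched <- peak_schedule(times_s = c(2, 4, 6), amplitudes_nA = rep(52.9, 3),
                         widths_ms = 10)
  tr <- make_trace(170, 5.29 / 170, sched, duration_s = 8, seed = 41)
  bg <- estimate_background(tr); nz <- estimate_noise(tr)
  pk <- detect_peaks(tr, bg, nz)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$time_s, c(2, 4, 6), tolerance = 0.05)
  expect_equal(pk$amplitude_nA, rep(52.9, 3), tolerance = 0.15)
  # two peaks 0.5 s apart collapse to the larger one
  s2 <- peak_schedule(times_s = c(3, 3.5), amplitudes_nA = c(40, 60),
                      widths_ms = 10)
  tr2 <- make_trace(170, 0, s2, duration_s = 8, seed = 1)
  pk2 <- detect_peaks(tr2, 170, 5)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$time_s, 3.5, tolerance = 0.01)
})

test_that("current-to-reflectance conversion reproduces the calibration worked examples", {
  conv <- conversion_constant()   # 271e-15 W mm^-2 per nA
  to_pw <- function(i) current_to_reflectance(i, conv) * 1e12
  expect_equal(signif(to_pw(170), 3), 46.1)
  expect_equal(signif(to_pw(47.3), 3), 12.8)
  expect_equal(signif(to_pw(5.29), 3), 1.43)
  expect_equal(to_pw(0), 0)
})

test_that("coefficient fits are exact inverses of the forward reflectance model", {
  toy <- toy_separable()
  p_src <- 75
  # closed form on a uniform grid, checked by hand:
  # W = a*b*V everywhere, so hom fit = r0 / (p_src * N * a*b*V) and the
  # het fit divides by the z-profile-weighted sum instead
  uni <- toy_uniform()   # a = 2, b = 3, V = 1, 3x3x3 voxels
  zc <- c(0.5, 1.5, 2.5)
  r0 <- 4.2e-6
  expect_equal(fit_af_hom(r0, p_src, uni$W), r0 / (p_src * 27 * 6))
  want_het <- r0 / (p_src * 6 * 9 * sum(2^(-zc / 0.1)))
  expect_equal(fit_af_het(r0, p_src, uni$W), want_het)
  # round trips to machine precision
  co_h <- fit_af_hom(r0, p_src, toy$W)
  expect_equal(background_reflectance(toy$W, af_model("homogeneous", co_h),
                                      p_src), r0, tolerance = 1e-14)
  co_s <- fit_af_het(r0, p_src, toy$W)
  expect_equal(background_reflectance(toy$W,
                                      af_model("surface_weighted", co_s),
                                      p_src), r0, tolerance = 1e-14)
  # target fit: one-step arithmetic and exact round trip at the argmax voxel
  wmax <- max(toy$W$values)
  expect_equal(fit_target(1.3e-5, p_src, toy$W), 1.3e-5 / (p_src * wmax))
  co_t <- fit_target(1.3e-5, p_src, toy$W)
  amax <- which(toy$W$values == wmax, arr.ind = TRUE)[1, ]
  cc <- voxel_centers(toy$medium)
  pos <- c(cc$x[amax[1]], cc$y[amax[2]], cc$z[amax[3]])
  expect_equal(target_reflectance(toy$W, target_model(co_t, pos), p_src),
               1.3e-5, tolerance = 1e-14)
  # zero numerators and degenerate geometry
  expect_equal(fit_af_hom(0, p_src, toy$W), 0)
  expect_equal(fit_target(0, p_src, toy$W), 0)
  zero <- make_toy_grids(c(2, 2, 2), "uniform", a = 0, b = 0)
  expect_error(fit_af_hom(1, p_src, zero$W), "degenerate")
  expect_error(fit_target(1, p_src, zero$W), "degenerate")
})

test_that("the full calibration chain recovers generator ground truth", {
  tr <- reference_trace()   # 170 nA, sigma_rel 0.031, 20 peaks of 47.3 nA
  toy <- toy_separable()
  cal <- calibrate_trace(tr, toy$W)
  truth <- attr(tr, "ground_truth")
  expect_equal(cal$background_nA, truth$background_nA, tolerance = 0.005)
  expect_equal(cal$sigma_rel, truth$sigma_rel, tolerance = 0.1)
  expect_equal(nrow(cal$peaks), 20)
  # target coefficient round trip against the grid used for generation:
  # the injected amplitude corresponds to a known coefficient through W
  conv <- conversion_constant()
  coeff_true <- (47.3 * conv$factor * 1e3) / (75 * max(toy$W$values))
  expect_equal(cal$target_coefficient, coeff_true, tolerance = 0.15)
  # sigma_rel is invariant under trace rescaling
  tr2 <- difc_trace(tr$samples * 3.7, tr$sample_rate)
  cal2 <- calibrate_trace(tr2)
  expect_equal(cal2$sigma_rel, cal$sigma_rel, tolerance = 1e-10)
  # unit-chain consistency
  expect_equal(cal$background_mW_mm2,
               cal$background_nA * conv$factor * 1e3)
})

test_that("traces round-trip through CSV and the moving-median subtraction centers them", {
  tr <- make_trace(100, 0.02, duration_s = 2, sample_rate = 500, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-8)
  expect_equal(back$sample_rate, 500, tolerance = 1e-6)
  sub <- subtract_moving_median(tr, window_s = 1)
  expect_lt(abs(median(sub$samples)), 1)
  unlink(path)
})
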