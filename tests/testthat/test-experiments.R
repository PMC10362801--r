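# These tests share one desk-scale Monte-Carlo sensitivity set (reduced box
# and photon budget) built once in helper-fixtures.R.

test_that("SD SNR maps equal a brute-force per-position recomputation", {
  ws <- desk_w_set()
  af <- af_model("surface_weighted")
  np <- noise_params(0.031, 0.05)
  coeff <- 43.3e-6
  p_src <- 75
  m <- snr_map(ws, af, coeff, np, p_src, data_type = "sd", pair = "A1")
  # independent loop over a coarsened 10 x 10 sub-grid, re-deriving the
  # background sum, the target addition, and the SNR from first principles
  W <- ws$W$A1$values
  cc <- voxel_centers(ws$medium)
  iy <- length(cc$y) %/% 2L + 1L
  z <- cc$z
  prof <- af$coefficient * 2^(-z / af$half_depth)
  r0 <- 0
  for (k in seq_along(z)) r0 <- r0 + p_src * sum(W[, , k]) * prof[k]
  xi <- round(seq(1, length(cc$x), length.out = 10))
  zi <- round(seq(1, length(z), length.out = 10))
  for (ix in xi) for (iz in zi) {
    r_with <- r0 + p_src * coeff * W[ix, iy, iz]
    want <- (r_with - r0) / (0.031 * r0)
    expect_equal(m$values[ix, iz], want, tolerance = 1e-10)
  }
  # null target: flat zero map
  m0 <- snr_map(ws, af, 0, np, p_src, data_type = "sd", pair = "A1")
  expect_true(all(m0$values == 0))
})

test_that("parallel-flow SD transits show a doublet with the source-side peak higher", {
  ws <- desk_w_set()
  af <- af_model("surface_weighted")
  np <- noise_params(0.031, 0.05)
  tg <- target_model(position = c(0, 0, 1.5))
  ft <- flow_trace(ws, af, tg, np, data_type = "sd", pair = "A1")
  x <- ft$position_mm
  s <- ft$snr
  # restrict to the optode region; find the two dominant local maxima
  reg <- x > -5.5 & x < 1.5
  xr <- x[reg]; sr <- s[reg]
  loc <- which(diff(sign(diff(sr))) == -2) + 1
  loc <- loc[order(sr[loc], decreasing = TRUE)][1:2]
  x_src <- -0.5; x_det <- -3.5
  near_src <- loc[which.min(abs(xr[loc] - x_src))]
  near_det <- loc[which.min(abs(xr[loc] - x_det))]
  expect_false(near_src == near_det)       # genuinely two peaks
  expect_lt(abs(xr[near_src] - x_src), 1)  # one sits under the source
  expect_lt(abs(xr[near_det] - x_det), 1)  # one under the detector
  expect_gt(sr[near_src], sr[near_det])    # source-side peak is higher
  # kinematic scaling: doubling velocity halves the transit duration but
  # leaves the positional profile untouched
  tg2 <- target_model(position = c(0, 0, 1.5), velocity = 50)
  ft2 <- flow_trace(ws, af, tg2, np, data_type = "sd", pair = "A1")
  expect_equal(ft2$snr, ft$snr)
  expect_equal(ft2$time_s, ft$time_s / 2)
})

test_that("parallel-flow DR transits are triphasic: decrease, increase, decrease", {
  ws <- desk_w_set()
  af <- af_model("surface_weighted")
  np <- noise_params(0.031, 0.05)
  tg <- target_model(position = c(0, 0, 1.5))
  ft <- flow_trace(ws, af, tg, np, data_type = "dr", dr_sd_method = "delta")
  x <- ft$position_mm
  s <- ft$snr
  win <- function(a, b) s[x >= a & x <= b]
  # under detector A: below baseline; under the sources: above; under
  # detector B: below again
  expect_lt(min(win(-4.5, -2.5)), -1)
  expect_gt(max(win(-1, 1)), 1)
  expect_lt(min(win(2.5, 4.5)), -1)
  # map/trace consistency: the trace is a line scan of the map
  m <- snr_map(ws, af, tg$coefficient, np, data_type = "dr",
               dr_sd_method = "delta")
  iz <- drdifc:::voxel_index(ws$medium, c(0, 0, 1.5))[3]
  expect_equal(s, unname(m$values[, iz]), tolerance = 1e-12)
})

test_that("swapping the source and detector beam models flips the doublet asymmetry", {
  ws <- desk_w_set()
  med <- ws$medium
  # swapped roles: cone beam at the source position, pencil at the detector
  phi_src_cone <- run_photon_mc(med, optode(c(-0.5, 0), "detector", na = 0.5),
                                n_photons = 1e6, seed = 57)
  phi_det_pencil <- run_photon_mc(med, optode(c(-3.5, 0), "source"),
                                  n_photons = 1e6, seed = 58)
  W_swap <- sensitivity_map(phi_src_cone, phi_det_pencil)
  W_ref <- ws$W$A1
  cc <- voxel_centers(med)
  iy <- length(cc$y) %/% 2L + 1L
  iz <- which.min(abs(cc$z - 1.5))
  prof_ref <- W_ref$values[, iy, iz]
  prof_swap <- W_swap$values[, iy, iz]
  peak_near <- function(prof, x0) max(prof[abs(cc$x - x0) < 1])
  # reference: pencil at source (-0.5) gives the higher lobe there;
  # swapped beams move the higher lobe to the pencil at -3.5
  expect_gt(peak_near(prof_ref, -0.5), peak_near(prof_ref, -3.5))
  expect_gt(peak_near(prof_swap, -3.5), peak_near(prof_swap, -0.5))
})

test_that("depth interpolation matches the analytic crossing of an exponential profile", {
  ws <- analytic_w_set(w0 = 1e-4, half_depth = 1)
  af <- af_model("homogeneous", coefficient = 1e-6)
  np <- noise_params(0.031, 0.05)
  p_src <- 75
  coeff <- 43.3e-6
  ds <- depth_scan(ws, af, coeff, np, p_src, data_types = "A1")
  # closed form: SNR(z) = K 2^(-z/h) with K = coeff w0 / (sigma a sumW)
  sumW <- sum(ws$W$A1$values)
  K <- coeff * 1e-4 / (0.031 * 1e-6 * sumW)
  z_star <- log2(K) * 1
  expect_true(K > 1 && z_star < ws$medium$extent[3])
  expect_equal(ds$table$max_depth_mm, z_star,
               tolerance = 0.25 / z_star)   # within half a voxel
  # null target: no depth at all
  ds0 <- depth_scan(ws, af, 0, np, p_src, data_types = "A1")
  expect_true(is.na(ds0$table$max_depth_mm))
})

test_that("surface-weighted AF lets the DR see deeper than the long-distance SD", {
  ws <- desk_w_set()
  np <- noise_params(0.031, 0.05)
  ds <- depth_scan(ws, af_model("surface_weighted"), 43.3e-6, np,
                   dr_sd_method = "delta")
  tab <- setNames(ds$table$max_depth_mm, ds$table$data_type)
  expect_false(any(is.na(tab)))
  expect_gt(tab[["dr"]], tab[["A2"]])
  # centroid positions below the participating optodes
  cx <- setNames(ds$table$centroid_x_mm, ds$table$data_type)
  expect_equal(cx[["A1"]], -2)
  expect_equal(cx[["dr"]], 0)
})

test_that("replacing homogeneous AF by surface-weighted AF at equal total background raises deep DR SNR", {
  ws <- desk_w_set()
  np <- noise_params(0.031, 0.05)
  hom <- af_model("homogeneous")
  r0_hom <- background_reflectance(ws$W$A1, hom)
  co_sw <- fit_af_het(r0_hom, 75, ws$W$A1)
  sw <- af_model("surface_weighted", co_sw)
  # equal background on the calibrating pair by construction
  expect_equal(background_reflectance(ws$W$A1, sw), r0_hom)
  deep <- cbind(0, voxel_centers(ws$medium)$y[21], c(2.5, 3, 3.5))
  s_hom <- drdifc:::snr_at_positions(ws, hom, 43.3e-6, np, 75, "dr", NA,
                                     deep, "delta")
  s_sw <- drdifc:::snr_at_positions(ws, sw, 43.3e-6, np, 75, "dr", NA,
                                    deep, "delta")
  expect_true(all(abs(s_sw) > abs(s_hom)))
})

test_that("the pNC sweep leaves SD depths fixed and shrinks DR depth monotonically", {
  ws <- desk_w_set()
  af <- af_model("surface_weighted")
  sw <- pnc_sweep(ws, af, 43.3e-6, sigma_rel = 0.031,
                  pnc_grid = c(0.01, 0.05, 0.2, 0.5, 1),
                  dr_sd_method = "delta")
  d <- sw$depths
  expect_equal(diff(range(d$A1)), 0)
  expect_equal(diff(range(d$A2)), 0)
  expect_true(all(diff(d$dr) <= 1e-9))
  # at 5% NC noise the DR outperforms both SDs here, so the crossover
  # must be at least that large
  expect_gte(sw$crossover_p_nc, 0.05)
})
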