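#' Build the full sensitivity-grid set for a measurement geometry
#'
#' Runs one transport simulation per optode (two sources, two detectors)
#' and forms the four pair Jacobians `A1, A2, B1, B2` by the adjoint
#' method. Per-optode seeds are derived deterministically from `seed`.
#'
#' @param medium an [optical_medium()].
#' @param geometry a [measurement_geometry()].
#' @param n_photons photon budget per optode (Monte-Carlo engine).
#' @param seed base integer seed.
#' @param gates time-gate spec passed to [run_photon_mc()].
#' @param engine `"mc"` (the transport kernel; reference) or
#'   `"diffusion"` (closed-form grids; fast, pencil-only, no cone-beam
#'   near-field structure).
#' @return A `w_set`: lists `fluence` (per optode) and `W` (per pair),
#'   plus `medium`, `geometry`, `n_photons`, `seed`, `engine`.
#' @export
build_w_set <- function(medium, geometry = measurement_geometry(),
                        n_photons = 2e6, seed = 1L,
                        gates = list(n = 10, t_end_ns = 10),
                        engine = c("mc", "diffusion")) {
  engine <- match.arg(engine)
  stopifnot(inherits(medium, "difc_medium"),
            inherits(geometry, "measurement_geometry"))
  optodes <- c(geometry$sources, geometry$detectors)
  fl <- vector("list", length(optodes))
  names(fl) <- names(optodes)
  for (i in seq_along(optodes)) {
    fl[[i]] <- if (engine == "mc")
      run_photon_mc(medium, optodes[[i]], n_photons,
                    seed = seed + 101L * i, gates = gates)
    else diffusion_fluence_grid(medium, optodes[[i]])
  }
  prs <- geometry$pairs
  W <- vector("list", nrow(prs))
  names(W) <- prs$pair
  for (i in seq_len(nrow(prs)))
    W[[i]] <- sensitivity_map(fl[[prs$source[i]]], fl[[prs$detector[i]]])
  structure(list(fluence = fl, W = W, medium = medium, geometry = geometry,
                 n_photons = n_photons, seed = seed, engine = engine),
            class = "w_set")
}

#' @export
print.w_set <- function(x, ...) {
  cat(sprintf("<w_set> %s engine, %g photons/optode, pairs %s\n",
              x$engine, x$n_photons, paste(names(x$W), collapse = ", ")))
  invisible(x)
}

# vectorized nearest-voxel W lookup for an n x 3 position matrix
w_values_at <- function(W, positions) {
  m <- W$medium
  v <- m$voxel
  ext <- m$extent
  ix <- pmin(pmax(floor((positions[, 1] + ext[1] / 2) / v) + 1, 1), m$n_vox[1])
  iy <- pmin(pmax(floor((positions[, 2] + ext[2] / 2) / v) + 1, 1), m$n_vox[2])
  iz <- pmin(pmax(floor(positions[, 3] / v) + 1, 1), m$n_vox[3])
  W$values[cbind(ix, iy, iz)]
}

#' Baseline reflectance quartet of a sensitivity-grid set
#'
#' Background (target-absent) reflectance of each pair under an AF model.
#'
#' @param w_set a [build_w_set()] result.
#' @param af an [af_model()].
#' @param p_src source power, mW.
#' @return Named vector `A1, A2, B1, B2` of `R0`, mW mm^-2.
#' @export
reflectance_quartet <- function(w_set, af, p_src = 75) {
  vapply(w_set$W[c("A1", "A2", "B1", "B2")],
         background_reflectance, numeric(1), af = af, p_src = p_src)
}

# baseline DR noise sd for a quartet, by sampling or delta method
dr_baseline_sd <- function(r0, noise, method = c("sampling", "delta"),
                           n_draws = 1e4, seed = NULL) {
  method <- match.arg(method)
  if (noise$p_nc == 0 || noise$sigma_rel == 0) {
    # DR cancels all per-optode factors; no NC noise -> degenerate
    return(0)
  }
  if (method == "delta")
    sqrt(noise$p_nc) * noise$sigma_rel * unname(dual_ratio(r0))
  else dr_noise_stats(r0, noise, n_draws, seed)$sd
}

# core evaluator: signed SNR of a data type for targets at given positions
snr_at_positions <- function(w_set, af, target_coeff, noise, p_src,
                             data_type, pair, positions,
                             dr_sd_method = "sampling",
                             n_draws = 1e4, seed = NULL) {
  r0 <- reflectance_quartet(w_set, af, p_src)
  if (data_type == "sd") {
    delta <- p_src * target_coeff * w_values_at(w_set$W[[pair]], positions)
    sd0 <- baseline_sd_sd_pair(r0[[pair]], noise)
    if (sd0 == 0) stop_invalid("baseline noise is zero; SNR undefined")
    return(snr(delta, sd0))
  }
  # dual ratio
  lay <- validate_dr_layout(w_set$geometry)
  if (!isTRUE(lay$valid))
    stop_invalid("geometry is not a valid DR layout: %s", lay$diagnostic)
  rt <- sapply(c("A1", "A2", "B1", "B2"), function(p)
    r0[[p]] + p_src * target_coeff * w_values_at(w_set$W[[p]], positions))
  if (is.null(dim(rt))) rt <- matrix(rt, nrow = 1,
                                     dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  dr0 <- unname(dual_ratio(r0))
  delta <- dual_ratio(rt) - dr0
  sd0 <- dr_baseline_sd(r0, noise, dr_sd_method, n_draws, seed)
  if (sd0 == 0) stop_invalid("baseline DR noise is zero; SNR undefined")
  snr(delta, sd0)
}

#' Map of SNR over target position in the y = 0 plane
#'
#' For every candidate target voxel in the central `y` layer, computes the
#' change of the chosen data type from baseline (target absent) to target
#' present, divided by the baseline noise of that data type. The baseline
#' noise is position-independent and computed once: analytically
#' (`sigma_rel * R0`) for single-distance pairs, by coupling-draw sampling
#' (reference) or the delta-method closed form for the DR.
#'
#' @inheritParams reflectance_quartet
#' @param target_coeff target emission coefficient `mu_a * eta`, mm^-1.
#' @param noise a [noise_params()].
#' @param data_type `"sd"` (one pair) or `"dr"`.
#' @param pair which pair for `data_type = "sd"` (`"A1"`, `"A2"`, `"B1"`,
#'   `"B2"`).
#' @param dr_sd_method `"sampling"` or `"delta"` baseline DR noise.
#' @param n_draws,seed sampling settings for the DR baseline noise.
#' @return An `snr_map`: matrix `values` (x by z) of signed SNR plus axis
#'   coordinates and metadata.
#' @export
snr_map <- function(w_set, af, target_coeff, noise, p_src = 75,
                    data_type = c("dr", "sd"), pair = "A1",
                    dr_sd_method = c("sampling", "delta"),
                    n_draws = 1e4, seed = NULL) {
  data_type <- match.arg(data_type)
  dr_sd_method <- match.arg(dr_sd_method)
  if (!is_scalar(target_coeff) || target_coeff < 0)
    stop_invalid("target_coeff must be >= 0")
  cc <- voxel_centers(w_set$medium)
  iy <- length(cc$y) %/% 2L + 1L   # layer whose center is nearest y = 0+
  grid <- expand.grid(x = cc$x, z = cc$z)
  positions <- cbind(grid$x, cc$y[iy], grid$z)
  vals <- snr_at_positions(w_set, af, target_coeff, noise, p_src,
                           data_type, pair, positions,
                           dr_sd_method, n_draws, seed)
  structure(list(
    values = matrix(vals, nrow = length(cc$x)),
    x = cc$x, z = cc$z, y = cc$y[iy],
    data_type = data_type, pair = if (data_type == "sd") pair else NA,
    af_kind = af$kind, p_src = p_src, noise = noise,
    target_coeff = target_coeff
  ), class = "snr_map")
}

#' @export
print.snr_map <- function(x, ...) {
  cat(sprintf("<snr_map> %s%s, %s AF: %d x %d positions, SNR range [%.3g, %.3g]\n",
              toupper(x$data_type),
              if (!is.na(x$pair)) paste0(" ", x$pair) else "",
              x$af_kind, length(x$x), length(x$z),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Simulated transit trace of a flowing target
#'
#' Evaluates the SNR of a data type for a point target moving along a
#' straight line in the medium: `axis = "x"` flows parallel to the
#' source-detector line at depth `depth` (in the y = 0 plane), `axis =
#' "y"` flows perpendicular under a fixed `(x, z)`. The time axis is the
#' position divided by the target velocity.
#'
#' @inheritParams snr_map
#' @param target a [target_model()]; supplies the coefficient, depth (via
#'   its position) and velocity.
#' @param axis flow direction, `"x"` (parallel) or `"y"` (perpendicular).
#' @return Data frame with `position_mm`, `time_s`, `snr`; metadata in
#'   attributes.
#' @export
flow_trace <- function(w_set, af, target, noise, p_src = 75,
                       data_type = c("dr", "sd"), pair = "A1",
                       axis = c("x", "y"),
                       dr_sd_method = c("sampling", "delta"),
                       n_draws = 1e4, seed = NULL) {
  data_type <- match.arg(data_type)
  axis <- match.arg(axis)
  dr_sd_method <- match.arg(dr_sd_method)
  stopifnot(inherits(target, "target_model"))
  cc <- voxel_centers(w_set$medium)
  pos0 <- target$position
  if (pos0[3] <= 0 || pos0[3] >= w_set$medium$extent[3])
    stop_invalid("target depth %g mm is outside the medium", pos0[3])
  if (axis == "x") {
    iy <- length(cc$y) %/% 2L + 1L
    s <- cc$x
    positions <- cbind(s, cc$y[iy], pos0[3])
  } else {
    s <- cc$y
    positions <- cbind(pos0[1], s, pos0[3])
  }
  vals <- snr_at_positions(w_set, af, target$coefficient, noise, p_src,
                           data_type, pair, positions,
                           dr_sd_method, n_draws, seed)
  out <- data.frame(position_mm = s,
                    time_s = (s - s[1]) / target$velocity,
                    snr = vals)
  attr(out, "meta") <- list(data_type = data_type, pair = pair, axis = axis,
                            depth_mm = pos0[3], velocity_mm_s = target$velocity,
                            af_kind = af$kind)
  out
}

#' Normalized waveform from a flow trace
#'
#' Converts a [flow_trace()] into a unit-peak waveform usable as the
#' `waveform` of a [peak_schedule()], centered on its absolute maximum.
#'
#' @param ft a [flow_trace()] result.
#' @return Data frame with `offset_s` and `relative`.
#' @export
flow_trace_waveform <- function(ft) {
  imax <- which.max(abs(ft$snr))
  data.frame(offset_s = ft$time_s - ft$time_s[imax],
             relative = ft$snr / ft$snr[imax])
}

#' Maximum measurable depth per data type
#'
#' Scans the SNR of each data type for a target placed at increasing depth
#' below the centroid of the optodes participating in that data type, and
#' reports the deepest depth at which `|SNR| > 1`, located by linear
#' interpolation between the two grid depths bracketing the `|SNR| = 1`
#' crossing. If `|SNR| > 1` still holds at the deepest grid depth the scan
#' is censored at that depth (flagged); if `|SNR| <= 1` everywhere no
#' depth is reported (`NA`).
#'
#' @inheritParams snr_map
#' @param data_types character vector: pair names (`"A1"`, `"A2"`, ...)
#'   for single-distance scans and `"dr"` for the dual ratio.
#' @return A `depth_scan` result: per data type the SNR-vs-depth profile,
#'   the centroid x used, `max_depth_mm`, and a `censored` flag; plus a
#'   summary data frame `table`.
#' @export
depth_scan <- function(w_set, af, target_coeff, noise, p_src = 75,
                       data_types = c("A1", "A2", "dr"),
                       dr_sd_method = c("sampling", "delta"),
                       n_draws = 1e4, seed = NULL) {
  dr_sd_method <- match.arg(dr_sd_method)
  cc <- voxel_centers(w_set$medium)
  iy <- length(cc$y) %/% 2L + 1L
  geom <- w_set$geometry
  opt_x <- function(names_) {
    xs <- vapply(names_, function(nm) {
      o <- c(geom$sources, geom$detectors)[[nm]]
      o$position[1]
    }, numeric(1))
    mean(xs)
  }
  profiles <- list()
  for (dt in data_types) {
    if (dt == "dr") {
      x0 <- opt_x(names(c(geom$sources, geom$detectors)))
      vals <- snr_at_positions(w_set, af, target_coeff, noise, p_src,
                               "dr", NA, cbind(x0, cc$y[iy], cc$z),
                               dr_sd_method, n_draws, seed)
    } else {
      pr <- geom$pairs[geom$pairs$pair == dt, ]
      if (nrow(pr) != 1L) stop_invalid("unknown data type '%s'", dt)
      x0 <- opt_x(c(pr$detector, pr$source))
      vals <- snr_at_positions(w_set, af, target_coeff, noise, p_src,
                               "sd", dt, cbind(x0, cc$y[iy], cc$z),
                               dr_sd_method, n_draws, seed)
    }
    a <- abs(vals)
    above <- which(a > 1)
    if (length(above) == 0L) {
      md <- NA_real_; cens <- FALSE
    } else {
      i <- max(above)
      if (i == length(a)) {
        md <- cc$z[i]; cens <- TRUE
      } else {
        # linear interpolation of |SNR| between the bracketing depths
        md <- cc$z[i] + (a[i] - 1) / (a[i] - a[i + 1]) * (cc$z[i + 1] - cc$z[i])
        cens <- FALSE
      }
    }
    profiles[[dt]] <- list(z_mm = cc$z, snr = vals, centroid_x_mm = x0,
                           max_depth_mm = md, censored = cens)
  }
  tab <- data.frame(
    data_type = data_types,
    centroid_x_mm = vapply(profiles, `[[`, numeric(1), "centroid_x_mm"),
    max_depth_mm = vapply(profiles, `[[`, numeric(1), "max_depth_mm"),
    censored = vapply(profiles, `[[`, logical(1), "censored"),
    row.names = NULL)
  structure(list(profiles = profiles, table = tab, af_kind = af$kind,
                 noise = noise, p_src = p_src,
                 n_photons = w_set$n_photons, seed = w_set$seed),
            class = "depth_scan")
}

#' @export
print.depth_scan <- function(x, ...) {
  cat(sprintf("<depth_scan> %s AF, p_nc %g\n", x$af_kind, x$noise$p_nc))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Maximum depth versus non-cancelable noise fraction
#'
#' Repeats [depth_scan()] over a grid of `p_nc` values with common random
#' numbers (the same baseline-noise seed per value), and reports the
#' largest grid `p_nc` at which the DR maximum depth still exceeds the
#' deepest single-distance depth (the crossover). Single-distance depths
#' are insensitive to `p_nc` by construction (the total relative noise is
#' `sigma_rel` throughout).
#'
#' @inheritParams depth_scan
#' @param sigma_rel relative noise level.
#' @param pnc_grid vector of `p_nc` values in `[0, 1]`.
#' @return A `pnc_sweep` result: data frame `depths` (one row per `p_nc`,
#'   one column per data type) and `crossover_p_nc`.
#' @export
pnc_sweep <- function(w_set, af, target_coeff, sigma_rel = 0.031,
                      p_src = 75, pnc_grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5),
                      data_types = c("A1", "A2", "dr"),
                      dr_sd_method = c("delta", "sampling"),
                      n_draws = 1e4, seed = 1L) {
  dr_sd_method <- match.arg(dr_sd_method)
  if (any(pnc_grid < 0 | pnc_grid > 1))
    stop_invalid("pnc_grid values must lie in [0, 1]")
  rows <- lapply(pnc_grid, function(p) {
    np <- noise_params(sigma_rel = sigma_rel, p_nc = p)
    ds <- depth_scan(w_set, af, target_coeff, np, p_src, data_types,
                     dr_sd_method, n_draws, seed = seed)
    setNames(ds$table$max_depth_mm, ds$table$data_type)
  })
  depths <- cbind(data.frame(p_nc = pnc_grid),
                  as.data.frame(do.call(rbind, rows)))
  sd_cols <- setdiff(data_types, "dr")
  sd_best <- apply(depths[, sd_cols, drop = FALSE], 1, max, na.rm = TRUE)
  wins <- !is.na(depths$dr) & depths$dr > sd_best
  crossover <- if (any(wins)) max(depths$p_nc[wins]) else NA_real_
  structure(list(depths = depths, crossover_p_nc = crossover,
                 sigma_rel = sigma_rel, af_kind = af$kind),
            class = "pnc_sweep")
}

#' @export
print.pnc_sweep <- function(x, ...) {
  cat(sprintf("<pnc_sweep> %s AF, sigma_rel %g; DR advantage up to p_nc = %s\n",
              x$af_kind, x$sigma_rel, format(x$crossover_p_nc)))
  print(x$depths, row.names = FALSE)
  invisible(x)
}
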