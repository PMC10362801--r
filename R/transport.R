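#' Monte-Carlo photon transport Green's function on a voxel grid
#'
#' Launches photons from an optode on the `z = 0` surface of a homogeneous
#' voxelized slab and scores the continuous-wave fluence-rate Green's
#' function (fluence per unit source power, mm^-2) in every voxel.
#'
#' The kernel uses Henyey-Greenstein scattering with the medium's `g`,
#' Fresnel reflection/refraction at the `z = 0` index boundary
#' (`n_in` against `n_out`), and absorbing conditions on the other five
#' faces (escaping photons are terminated and tallied). Fluence is scored
#' with a collision estimator, equivalent to absorbed-weight deposition
#' divided by `mu_a` per voxel volume and well defined as `mu_a -> 0`.
#' Photon histories are time-resolved into `gates$n` gates ending at
#' `gates$t_end_ns`; gated values are stored per unit time, so the CW grid
#' is the gate-width-weighted sum (see [cw_integrate()]). Histories whose
#' optical time exceeds the last gate are censored (their remaining weight
#' is tallied, not scored). Low-weight photons undergo Russian roulette.
#'
#' @param medium an [optical_medium()].
#' @param optode an [optode()]; pencil beams enter at normal incidence,
#'   cone beams sample directions uniformly in solid angle within the
#'   exterior acceptance half-angle `asin(na / n_out)` and are refracted
#'   into the medium. Either way the launch weight is reduced by the
#'   Fresnel transmittance, so the Green's function is per unit power
#'   incident on the surface.
#' @param n_photons number of photon histories (>= 1).
#' @param seed integer seed for the kernel's own deterministic RNG; runs
#'   with equal seeds are bit-identical and the caller's R RNG stream is
#'   untouched.
#' @param gates list with `n` (gate count) and `t_end_ns` (end of the last
#'   gate, ns).
#' @param keep_gates if `TRUE`, the time-resolved 4-D array (per-unit-time
#'   fluence, `nx * ny * nz * n_gates`) is retained in the result.
#' @param roulette_w,roulette_m Russian-roulette trigger weight and
#'   survival boost.
#' @return A `fluence_grid`: list with the 3-D CW `values` array (mm^-2),
#'   conservation `tallies` (weights per launched photon), and the
#'   generating `medium`, `optode`, `n_photons`, `seed`, `gates`.
#' @seealso [diffusion_green()] for the semi-infinite closed form,
#'   [sensitivity_map()] for the fluorescence Jacobian.
#' @export
run_photon_mc <- function(medium, optode, n_photons = 1e7, seed = 1L,
                          gates = list(n = 10, t_end_ns = 10),
                          keep_gates = FALSE,
                          roulette_w = 1e-4, roulette_m = 10) {
  stopifnot(inherits(medium, "difc_medium"), inherits(optode, "difc_optode"))
  if (!is_count(n_photons)) stop_invalid("n_photons must be a positive count")
  if (!is_count(gates$n) || !is_scalar(gates$t_end_ns) || gates$t_end_ns <= 0)
    stop_invalid("gates must give a positive count and end time")
  check_optode_on_medium(medium, optode)

  res <- mc_fluence_cpp(
    medium$mu_a, medium$mu_s, medium$g, medium$n_in, medium$n_out,
    medium$extent, medium$voxel,
    optode$position[1:2],
    if (optode$beam == "pencil") 0L else 1L,
    if (is.na(optode$na)) 0 else optode$na,
    as.double(n_photons), as.integer(gates$n), gates$t_end_ns,
    as.double(seed), roulette_w, roulette_m)

  cw <- cw_integrate(res$gated, gates)
  out <- structure(list(
    values = cw,
    tallies = res$tallies,
    medium = medium, optode = optode,
    n_photons = n_photons, seed = seed, gates = gates
  ), class = "fluence_grid")
  if (keep_gates) out$gated <- res$gated
  out
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat(sprintf("<fluence_grid> %s beam at (%g, %g) mm, %g photons, seed %s\n",
              x$optode$beam, x$optode$position[1], x$optode$position[2],
              x$n_photons, format(x$seed)))
  cat(sprintf("  grid %d x %d x %d, CW fluence range [%.3g, %.3g] mm^-2\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integrate a time-gated fluence map to continuous wave
#'
#' Gated maps store per-unit-time fluence; the CW map is the
#' gate-width-weighted sum `sum_g value_g * dt` with `dt = t_end_ns / n`.
#'
#' @param gated 4-D array `(nx, ny, nz, n_gates)` of per-unit-time fluence.
#' @param gates list with `n` and `t_end_ns` consistent with `gated`.
#' @return 3-D CW fluence array.
#' @export
cw_integrate <- function(gated, gates) {
  d <- dim(gated)
  if (length(d) != 4L)
    stop_invalid("gated map must be a 4-D array (x, y, z, gate)")
  if (d[4] != gates$n)
    stop_invalid("gate count mismatch: map has %d gates, gate spec says %d",
                 d[4], gates$n)
  dt <- gates$t_end_ns / gates$n
  cw <- array(0, dim = d[1:3])
  for (g in seq_len(d[4])) cw <- cw + gated[, , , g]
  cw * dt
}

#' Semi-infinite diffusion-theory Green's function
#'
#' Closed-form CW fluence-rate Green's function (per unit power, mm^-2) for
#' a pencil beam on a semi-infinite homogeneous medium, in the
#' extrapolated-boundary approximation: the beam is represented as a buried
#' isotropic point source at one transport mean free path
#' `z0 = 1 / (mu_a + mu_s')` and mirrored in the extrapolated boundary at
#' `-2 zb - z0`, with `zb = 2 A D` and `A` from the internal-reflection
#' coefficient of the index mismatch (Groenhuis polynomial fit). Serves as
#' a fast fallback and as an independent oracle for the Monte-Carlo kernel
#' far from the source.
#'
#' @param medium an [optical_medium()]; `mu_s * (1 - g)` must be positive.
#' @param src_position pencil-beam entry point on the surface: `(x, y)` or
#'   `(x, y, 0)`, mm.
#' @param field_position one field point `(x, y, z)` or a matrix with one
#'   point per row; each must lie strictly inside the medium.
#' @return Fluence value(s), mm^-2.
#' @export
diffusion_green <- function(medium, src_position, field_position) {
  stopifnot(inherits(medium, "difc_medium"))
  mu_sp <- medium$mu_s * (1 - medium$g)
  if (mu_sp <= 0) stop_invalid("reduced scattering mu_s * (1 - g) must be > 0")
  src <- as.numeric(src_position)
  if (length(src) == 2L) src <- c(src, 0)
  fp <- field_position
  if (is.null(dim(fp))) fp <- matrix(as.numeric(fp), nrow = 1)
  if (ncol(fp) != 3L) stop_invalid("field_position must have 3 columns")
  ext <- medium$extent
  inside <- fp[, 1] > -ext[1] / 2 & fp[, 1] < ext[1] / 2 &
    fp[, 2] > -ext[2] / 2 & fp[, 2] < ext[2] / 2 &
    fp[, 3] > 0 & fp[, 3] < ext[3]
  if (!all(inside))
    stop_invalid("field position(s) outside the medium")

  mu_t <- medium$mu_a + mu_sp
  D <- 1 / (3 * mu_t)
  mu_eff <- sqrt(medium$mu_a / D)
  z0 <- 1 / mu_t
  n_rel <- medium$n_in / medium$n_out
  # effective internal reflection (Groenhuis et al. fit)
  r_eff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + r_eff) / (1 - r_eff)
  zb <- 2 * A * D

  rho2 <- (fp[, 1] - src[1])^2 + (fp[, 2] - src[2])^2
  r1 <- sqrt(rho2 + (fp[, 3] - z0)^2)
  r2 <- sqrt(rho2 + (fp[, 3] + z0 + 2 * zb)^2)
  phi <- (exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D)
  if (nrow(fp) == 1L) as.numeric(phi) else phi
}

#' Fill a fluence grid from the diffusion closed form
#'
#' Evaluates [diffusion_green()] at every voxel center for a pencil source
#' at an optode's position, returning an object interchangeable with
#' [run_photon_mc()] output. The cone-beam geometry is not represented;
#' cone optodes are treated as pencils. Intended for fast exploratory
#' work and for tests where the diffusive shape (not the exact near-field
#' beam structure) matters.
#'
#' @inheritParams run_photon_mc
#' @return A `fluence_grid` with `n_photons = 0` marking the analytic origin.
#' @export
diffusion_fluence_grid <- function(medium, optode) {
  stopifnot(inherits(medium, "difc_medium"), inherits(optode, "difc_optode"))
  check_optode_on_medium(medium, optode)
  cc <- voxel_centers(medium)
  pts <- as.matrix(expand.grid(x = cc$x, y = cc$y, z = cc$z))
  vals <- diffusion_green(medium, optode$position, pts)
  structure(list(
    values = array(vals, dim = medium$n_vox),
    tallies = NULL, medium = medium, optode = optode,
    n_photons = 0, seed = NA_integer_,
    gates = list(n = 1, t_end_ns = Inf)
  ), class = "fluence_grid")
}

#' Read/write fluence and sensitivity grids
#'
#' Grids are persisted as single-file R serializations carrying the full
#' object (values plus the medium, optode, photon count and seed they were
#' computed from), so a stored grid is self-describing.
#'
#' @param grid a `fluence_grid` or `sensitivity_grid`.
#' @param path file path (conventionally `.rds`).
#' @return `read_grid()` returns the stored object; `write_grid()` its path,
#'   invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, c("fluence_grid", "sensitivity_grid")))
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop_invalid("no grid file at '%s'", path)
  obj <- readRDS(path)
  if (!inherits(obj, c("fluence_grid", "sensitivity_grid")))
    stop_invalid("'%s' does not contain a stored grid", path)
  obj
}
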