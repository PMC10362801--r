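#' Homogeneous voxelized optical medium
#'
#' Defines a slab of optically turbid tissue-like material occupying
#' `x, y` in `[-extent/2, extent/2]` and `z` in `[0, extent_z]` (the `z = 0`
#' face is the measurement surface, `z` positive into the medium), divided
#' into cubic voxels. Defaults are the near-infrared (810 nm) tissue
#' properties used throughout the package's worked analyses.
#'
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s scattering coefficient, mm^-1.
#' @param g scattering anisotropy factor (mean cosine), in `[-1, 1]`.
#' @param n_in interior refractive index.
#' @param n_out exterior refractive index (air by default).
#' @param extent side lengths `(x, y, z)` of the slab, mm. A scalar is
#'   recycled to a cube. Each side must be an integer multiple of `voxel`.
#' @param voxel cubic voxel edge length, mm.
#' @return An object of class `difc_medium`.
#' @examples
#' med <- optical_medium(extent = 10, voxel = 0.5)
#' med$n_vox
#' @export
optical_medium <- function(mu_a = 0.002, mu_s = 7, g = 0.9,
                           n_in = 1.37, n_out = 1.0,
                           extent = c(30, 30, 30), voxel = 0.1) {
  if (!is_scalar(mu_a) || mu_a < 0) stop_invalid("mu_a must be >= 0")
  if (!is_scalar(mu_s) || mu_s <= 0) stop_invalid("mu_s must be > 0")
  if (!is_scalar(g) || g < -1 || g > 1) stop_invalid("g must be in [-1, 1]")
  if (!is_scalar(n_in) || n_in < 1) stop_invalid("n_in must be >= 1")
  if (!is_scalar(n_out) || n_out < 1) stop_invalid("n_out must be >= 1")
  if (!is_scalar(voxel) || voxel <= 0) stop_invalid("voxel must be > 0")
  if (length(extent) == 1L) extent <- rep(extent, 3L)
  if (length(extent) != 3L || !all(is.finite(extent)) || any(extent <= 0))
    stop_invalid("extent must be three positive side lengths")
  if (!divides_evenly(extent, voxel))
    stop_invalid("extent must be an integer multiple of voxel on each axis")
  structure(list(
    mu_a = mu_a, mu_s = mu_s, g = g, n_in = n_in, n_out = n_out,
    extent = as.numeric(extent), voxel = voxel,
    n_vox = as.integer(round(extent / voxel))
  ), class = "difc_medium")
}

#' @export
print.difc_medium <- function(x, ...) {
  cat(sprintf(
    "<difc_medium> mu_a=%g mu_s=%g g=%g n=%g/%g  %g x %g x %g mm @ %g mm (%d x %d x %d voxels)\n",
    x$mu_a, x$mu_s, x$g, x$n_in, x$n_out,
    x$extent[1], x$extent[2], x$extent[3], x$voxel,
    x$n_vox[1], x$n_vox[2], x$n_vox[3]))
  invisible(x)
}

#' Voxel-center coordinates of a medium
#'
#' @param medium a [optical_medium()].
#' @return A list with numeric vectors `x`, `y`, `z` of voxel-center
#'   coordinates (mm). `x` and `y` are centered on 0; `z` starts at
#'   `voxel/2` below the surface.
#' @export
voxel_centers <- function(medium) {
  stopifnot(inherits(medium, "difc_medium"))
  v <- medium$voxel
  ext <- medium$extent
  list(
    x = seq(-ext[1] / 2 + v / 2, ext[1] / 2 - v / 2, by = v),
    y = seq(-ext[2] / 2 + v / 2, ext[2] / 2 - v / 2, by = v),
    z = seq(v / 2, ext[3] - v / 2, by = v)
  )
}

# nearest-voxel index of a position (x, y, z), with bounds checking
voxel_index <- function(medium, position) {
  ext <- medium$extent
  v <- medium$voxel
  p <- as.numeric(position)
  if (length(p) != 3L) stop_invalid("position must be a 3-vector")
  inside <- p[1] >= -ext[1] / 2 && p[1] <= ext[1] / 2 &&
    p[2] >= -ext[2] / 2 && p[2] <= ext[2] / 2 &&
    p[3] >= 0 && p[3] <= ext[3]
  if (!inside) stop_invalid("position (%g, %g, %g) lies outside the medium",
                            p[1], p[2], p[3])
  idx <- c(
    floor((p[1] + ext[1] / 2) / v) + 1,
    floor((p[2] + ext[2] / 2) / v) + 1,
    floor(p[3] / v) + 1
  )
  pmin(pmax(as.integer(idx), 1L), medium$n_vox)
}

#' Source or detector optode on the measurement surface
#'
#' @param position position on the `z = 0` surface; a 2-vector `(x, y)` or a
#'   3-vector with `z = 0`, mm.
#' @param role `"source"` or `"detector"`.
#' @param beam `"pencil"` (normal incidence) or `"cone"` (direction sampled
#'   within the fiber acceptance cone). Defaults to the fiber convention:
#'   pencil for sources, 0.5-NA cone for detectors.
#' @param na numerical aperture of the cone beam, defined in the exterior
#'   medium (fiber convention). Must satisfy `0 < na < n_out`.
#' @param name optional label (e.g. `"A"`, `"1"`).
#' @return An object of class `difc_optode`.
#' @export
optode <- function(position, role = c("source", "detector"),
                   beam = NULL, na = 0.5, name = NULL) {
  role <- match.arg(role)
  p <- as.numeric(position)
  if (length(p) == 2L) p <- c(p, 0)
  if (length(p) != 3L || !all(is.finite(p)))
    stop_invalid("position must be a 2- or 3-vector")
  if (abs(p[3]) > 1e-9)
    stop_invalid("optode must sit on the z = 0 surface (got z = %g)", p[3])
  p[3] <- 0
  if (is.null(beam)) beam <- if (role == "source") "pencil" else "cone"
  beam <- match.arg(beam, c("pencil", "cone"))
  if (beam == "cone") {
    if (!is_scalar(na) || na <= 0)
      stop_invalid("cone beam requires 0 < na")
  }
  structure(list(position = p, role = role, beam = beam,
                 na = if (beam == "cone") na else NA_real_,
                 name = name),
            class = "difc_optode")
}

#' @export
print.difc_optode <- function(x, ...) {
  cat(sprintf("<difc_optode %s> %s at (%g, %g) mm, %s beam%s\n",
              if (is.null(x$name)) "" else x$name, x$role,
              x$position[1], x$position[2], x$beam,
              if (x$beam == "cone") sprintf(" (NA %g)", x$na) else ""))
  invisible(x)
}

check_optode_on_medium <- function(medium, opt) {
  ext <- medium$extent
  p <- opt$position
  if (abs(p[1]) > ext[1] / 2 || abs(p[2]) > ext[2] / 2)
    stop_invalid("optode at (%g, %g) lies outside the lateral extent",
                 p[1], p[2])
  if (opt$beam == "cone" && !(opt$na < medium$n_out))
    stop_invalid("numerical aperture %g is not physically admissible for n_out = %g",
                 opt$na, medium$n_out)
  invisible(TRUE)
}
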