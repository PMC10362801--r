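#' Autofluorescence background model
#'
#' Spatial distribution of the autofluorescence (AF) emission coefficient
#' `mu_a,AF * eta_AF` (mm^-1). Two shapes are supported: `homogeneous`
#' (the coefficient everywhere) and `surface_weighted`, an exponential
#' halving with depth, `coefficient * 2^(-z / half_depth)`, capturing
#' AF contributors concentrated in the skin.
#'
#' @param kind `"surface_weighted"` or `"homogeneous"`.
#' @param coefficient AF emission prefactor `mu_a,AF * eta_AF`, mm^-1
#'   (>= 0). Defaults are the calibrated phantom values for each shape.
#' @param half_depth depth at which the surface-weighted profile halves,
#'   mm (> 0).
#' @return An `af_model` object.
#' @export
af_model <- function(kind = c("surface_weighted", "homogeneous"),
                     coefficient = NULL, half_depth = 0.1) {
  kind <- match.arg(kind)
  if (is.null(coefficient))
    coefficient <- if (kind == "surface_weighted") 228e-9 else 6.81e-9
  if (!is_scalar(coefficient) || coefficient < 0)
    stop_invalid("coefficient must be >= 0")
  if (!is_scalar(half_depth) || half_depth <= 0)
    stop_invalid("half_depth must be > 0")
  structure(list(kind = kind, coefficient = coefficient,
                 half_depth = half_depth),
            class = "af_model")
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf("<af_model> %s, coefficient %.3g mm^-1%s\n", x$kind,
              x$coefficient,
              if (x$kind == "surface_weighted")
                sprintf(", half depth %g mm", x$half_depth) else ""))
  invisible(x)
}

#' AF depth profile values
#'
#' @param af an [af_model()].
#' @param z depth(s) below the surface, mm.
#' @return Per-depth emission coefficient, mm^-1.
#' @export
af_profile <- function(af, z) {
  stopifnot(inherits(af, "af_model"))
  if (af$kind == "homogeneous") rep(af$coefficient, length(z))
  else af$coefficient * 2^(-z / af$half_depth)
}

#' Point fluorescent target
#'
#' @param coefficient target emission coefficient `mu_a,target * eta_target`,
#'   mm^-1 (>= 0). Default is the phantom-calibrated microsphere value.
#' @param position 3-vector `(x, y, z)` inside the medium, mm.
#' @param velocity flow speed for simulated transits, mm/s.
#' @param direction unit 3-vector of travel.
#' @return A `target_model` object.
#' @export
target_model <- function(coefficient = 43.3e-6, position = c(0, 0, 1.5),
                         velocity = 25, direction = c(1, 0, 0)) {
  if (!is_scalar(coefficient) || coefficient < 0)
    stop_invalid("coefficient must be >= 0")
  position <- as.numeric(position)
  if (length(position) != 3L) stop_invalid("position must be a 3-vector")
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_invalid("direction must be nonzero")
  structure(list(coefficient = coefficient, position = position,
                 velocity = velocity, direction = direction / nrm),
            class = "target_model")
}

#' Fluorescence Jacobian (sensitivity) grid
#'
#' Per-voxel sensitivity of the detected fluorescence to a fluorophore's
#' position: the product of the source and detector (adjoint) fluence
#' Green's functions times the voxel volume,
#' `W = Phi_src * Phi_det * V` (mm^-1). Symmetric in its two arguments.
#'
#' @param phi_src,phi_det `fluence_grid`s on the same medium geometry, one
#'   computed from the source optode and one from the detector (adjoint)
#'   optode.
#' @return A `sensitivity_grid`: `values` (3-D W array, mm^-1),
#'   `voxel_volume` (mm^3), `medium`, and the `pair` of optodes.
#' @export
sensitivity_map <- function(phi_src, phi_det) {
  stopifnot(inherits(phi_src, "fluence_grid"), inherits(phi_det, "fluence_grid"))
  m <- phi_src$medium
  if (!identical(dim(phi_src$values), dim(phi_det$values)) ||
      !isTRUE(all.equal(m$extent, phi_det$medium$extent)) ||
      !isTRUE(all.equal(m$voxel, phi_det$medium$voxel)))
    stop_invalid("fluence grids do not share a medium geometry")
  V <- m$voxel^3
  structure(list(
    values = phi_src$values * phi_det$values * V,
    voxel_volume = V,
    medium = m,
    pair = list(src = phi_src$optode, det = phi_det$optode)
  ), class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  nm <- function(o) if (is.null(o$name)) sprintf("(%g,%g)", o$position[1],
                                                 o$position[2]) else o$name
  cat(sprintf("<sensitivity_grid> pair %s-%s, %d x %d x %d voxels, max W %.3g mm^-1\n",
              nm(x$pair$src), nm(x$pair$det),
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              max(x$values)))
  invisible(x)
}

# W value at a target position; nearest voxel by default, optional
# trilinear interpolation for smooth flow traces.
w_at <- function(W, position, interpolate = FALSE) {
  m <- W$medium
  if (!interpolate) {
    idx <- voxel_index(m, position)
    return(W$values[idx[1], idx[2], idx[3]])
  }
  cc <- voxel_centers(m)
  p <- as.numeric(position)
  tri <- function(grid_axis, p1) {
    i <- findInterval(p1, grid_axis)
    i <- min(max(i, 1L), length(grid_axis) - 1L)
    f <- (p1 - grid_axis[i]) / (grid_axis[i + 1] - grid_axis[i])
    list(i = i, f = min(max(f, 0), 1))
  }
  ax <- tri(cc$x, p[1]); ay <- tri(cc$y, p[2]); az <- tri(cc$z, p[3])
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) ax$f else 1 - ax$f) *
      (if (dy) ay$f else 1 - ay$f) *
      (if (dz) az$f else 1 - az$f)
    acc <- acc + wgt * W$values[ax$i + dx, ay$i + dy, az$i + dz]
  }
  acc
}

#' Fluorescent reflectance from a point target
#'
#' `R_target = P_src * W(r_target) * coefficient`: the source power times
#' the Jacobian at the target voxel times the target emission coefficient.
#'
#' @param W a [sensitivity_map()] grid.
#' @param target a [target_model()]; its position must lie inside the grid.
#' @param p_src source power, mW.
#' @param interpolate use trilinear interpolation of W instead of the
#'   nearest-voxel value.
#' @return Target reflectance contribution, mW mm^-2.
#' @export
target_reflectance <- function(W, target, p_src = 75, interpolate = FALSE) {
  stopifnot(inherits(W, "sensitivity_grid"), inherits(target, "target_model"))
  p_src * target$coefficient * w_at(W, target$position, interpolate)
}

#' Background reflectance from distributed autofluorescence
#'
#' `R0 = P_src * sum_voxels W * profile(z)`, the AF term of the measured
#' reflectance. For a homogeneous AF model this reduces to
#' `P_src * coefficient * sum(W)`.
#'
#' @inheritParams target_reflectance
#' @param af an [af_model()].
#' @return Background reflectance `R0`, mW mm^-2.
#' @export
background_reflectance <- function(W, af, p_src = 75) {
  stopifnot(inherits(W, "sensitivity_grid"), inherits(af, "af_model"))
  z <- voxel_centers(W$medium)$z
  prof <- af_profile(af, z)
  # sum over x,y per z-layer, then weight by the depth profile
  layer_sums <- apply(W$values, 3, sum)
  p_src * sum(layer_sums * prof)
}

#' Total fluorescent reflectance (background plus target)
#'
#' @inheritParams target_reflectance
#' @param af an [af_model()]; `target` may be `NULL` for baseline-only.
#' @return A `reflectance_value`: list with `value`, `background`, `target`
#'   components (mW mm^-2) and `p_src` (mW).
#' @export
total_reflectance <- function(W, af, target = NULL, p_src = 75,
                              interpolate = FALSE) {
  r0 <- background_reflectance(W, af, p_src)
  rt <- if (is.null(target)) 0 else
    target_reflectance(W, target, p_src, interpolate)
  structure(list(value = r0 + rt, background = r0, target = rt,
                 p_src = p_src),
            class = "reflectance_value")
}

#' @export
print.reflectance_value <- function(x, ...) {
  cat(sprintf("<reflectance> %.4g mW mm^-2 (background %.4g + target %.4g) at P_src %g mW\n",
              x$value, x$background, x$target, x$p_src))
  invisible(x)
}
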