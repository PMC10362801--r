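# Shared fixtures, built once per test run and memoized.
# All grids are generated in code at run time; seeds are fixed constants.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# Desk-scale sensitivity-grid set for the standard four-optode layout:
# a reduced box and photon budget that resolve the shallow (<= 5 mm)
# sensitivity structure the qualitative signatures live in.
desk_w_set <- function() {
  fixture("desk_w_set", function() {
    med <- optical_medium(extent = c(16, 10, 8), voxel = 0.25)
    build_w_set(med, measurement_geometry(), n_photons = 1e6, seed = 3L)
  })
}

# Toy grid bundles for algebraic oracles
toy_uniform <- function() fixture("toy_uniform", function()
  make_toy_grids(c(3, 3, 3), "uniform", voxel = 1, a = 2, b = 3))

toy_separable <- function() fixture("toy_separable", function()
  make_toy_grids(c(4, 3, 5), "separable", voxel = 0.5))

# Reference synthetic trace with the phantom-like parameters
reference_trace <- function() {
  fixture("reference_trace", function() {
    sched <- peak_schedule(times_s = seq(3, 57, length.out = 20),
                           amplitudes_nA = rep(47.3, 20), widths_ms = 10)
    make_trace(170, 0.031, sched, duration_s = 60, sample_rate = 2000,
               seed = 11L)
  })
}

# A hand-built w_set whose four Jacobians share one exact exponential
# depth profile, so single-distance SNR-vs-depth curves have a closed-form
# |SNR| = 1 crossing.
analytic_w_set <- function(w0 = 1e-4, half_depth = 1) {
  med <- optical_medium(extent = c(8, 4, 8), voxel = 0.5)
  z <- voxel_centers(med)$z
  prof <- w0 * 2^(-z / half_depth)
  vals <- aperm(array(prof, dim = med$n_vox[c(3, 1, 2)]), c(2, 3, 1))
  geom <- measurement_geometry()
  mk_fl <- function(opt) structure(
    list(values = sqrt(vals / med$voxel^3), tallies = NULL, medium = med,
         optode = opt, n_photons = 0, seed = NA_integer_,
         gates = list(n = 1, t_end_ns = Inf)),
    class = "fluence_grid")
  fl <- lapply(c(geom$sources, geom$detectors), mk_fl)
  W <- lapply(setNames(nm = c("A1", "A2", "B1", "B2")), function(p)
    sensitivity_map(fl[[substr(p, 2, 2)]], fl[[substr(p, 1, 1)]]))
  structure(list(fluence = fl, W = W, medium = med, geometry = geom,
                 n_photons = 0, seed = NA_integer_, engine = "analytic"),
            class = "w_set")
}
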