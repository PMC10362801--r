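#' Default run configuration
#'
#' The full configuration tree with the package's reference defaults:
#' 810 nm tissue optical properties, the symmetric four-optode layout
#' (detectors at -3.5 and +3.5 mm, sources at -0.5 and +0.5 mm along x),
#' surface-weighted AF, the phantom-calibrated target coefficient, 5%
#' non-cancelable noise at `sigma_rel = 0.031`, and a 75 mW source.
#' Physical quantities carry unit suffixes in their key names.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    medium = list(mu_a_mm1 = 0.002, mu_s_mm1 = 7, g = 0.9,
                  n_in = 1.37, n_out = 1.0,
                  extent_mm = c(30, 30, 30), voxel_mm = 0.1),
    optodes = list(
      source_1_x_mm = -0.5, source_2_x_mm = 0.5,
      detector_A_x_mm = -3.5, detector_B_x_mm = 3.5,
      detector_na = 0.5),
    transport = list(n_photons = 1e7, seed = 1,
                     gates_n = 10, gates_t_end_ns = 10,
                     engine = "mc"),
    af = list(kind = "surface_weighted", coefficient_mm1 = 228e-9,
              half_depth_mm = 0.1),
    target = list(coefficient_mm1 = 43.3e-6, depth_mm = 1.5,
                  velocity_mm_s = 25),
    noise = list(sigma_rel = 0.031, p_nc = 0.05, p_opt = 0.475),
    p_src_mW = 75,
    conversion = list(factor_W_mm2_nA = 271e-15, gain = 1e4,
                      detector_area_mm2 = 0.565, wavelength_nm = 810),
    trace = list(background_nA = 170, duration_s = 60, sample_rate_hz = 2000),
    paths = list(jacobian = NA_character_, trace_csv = NA_character_)
  ), class = "run_config")
}

check_keys <- function(cfg, ref, prefix = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop_invalid("unknown configuration key(s): %s",
                 paste0(prefix, bad, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      check_keys(cfg[[nm]], ref[[nm]], paste0(prefix, nm, "."))
  }
}

merge_config <- function(ref, cfg) {
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      ref[[nm]] <- merge_config(ref[[nm]], cfg[[nm]])
    else ref[[nm]] <- cfg[[nm]]
  }
  ref
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys with [default_config()]
#' values, rejects unknown keys, and validates cross-field constraints
#' (in particular `2 * p_opt + p_nc = 1` when both noise fractions are
#' given). An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no configuration file at '%s'", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  ref <- default_config()
  check_keys(cfg, ref)
  out <- merge_config(unclass(ref), cfg)
  if (is.null(cfg$noise$p_opt)) {
    out$noise$p_opt <- (1 - out$noise$p_nc) / 2
  } else if (abs(2 * cfg$noise$p_opt + out$noise$p_nc - 1) > 1e-9) {
    stop_invalid("noise fractions must satisfy 2 * p_opt + p_nc = 1 (got 2*%g + %g)",
                 cfg$noise$p_opt, out$noise$p_nc)
  }
  noise_params(out$noise$sigma_rel, out$noise$p_nc)  # validates ranges
  class(out) <- "run_config"
  out
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# object constructors from a config
config_medium <- function(cfg) {
  optical_medium(cfg$medium$mu_a_mm1, cfg$medium$mu_s_mm1, cfg$medium$g,
                 cfg$medium$n_in, cfg$medium$n_out,
                 cfg$medium$extent_mm, cfg$medium$voxel_mm)
}

config_geometry <- function(cfg) {
  o <- cfg$optodes
  measurement_geometry(
    sources = list(`1` = optode(c(o$source_1_x_mm, 0), "source", name = "1"),
                   `2` = optode(c(o$source_2_x_mm, 0), "source", name = "2")),
    detectors = list(
      A = optode(c(o$detector_A_x_mm, 0), "detector", na = o$detector_na,
                 name = "A"),
      B = optode(c(o$detector_B_x_mm, 0), "detector", na = o$detector_na,
                 name = "B")))
}

config_af <- function(cfg)
  af_model(cfg$af$kind, cfg$af$coefficient_mm1, cfg$af$half_depth_mm)

config_noise <- function(cfg)
  noise_params(cfg$noise$sigma_rel, cfg$noise$p_nc)

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run a named workflow from a configuration
#'
#' Chains the package modules into the standard workflows and writes their
#' outputs under `out_dir`. Every output file name is accompanied by a
#' JSON sidecar recording the configuration hash and seeds used.
#'
#' Workflows: `"fluence"` (one grid per optode), `"jacobian"` (fluence
#' then the four pair Jacobians, written as one `w_set`), `"snr-map"`,
#' `"trace"` (flow transit trace), `"depth-scan"`, `"pnc-sweep"` (these
#' four require `paths$jacobian` to point at a stored `w_set`),
#' `"simulate-trace"` (synthetic trace CSV plus ground-truth sidecar),
#' `"calibrate"` (requires `paths$trace_csv`, and uses `paths$jacobian`
#' when set for coefficient fits), and `"reference-defaults"` (the full
#' reference chain: jacobian then depth scans under both AF models,
#' emitting a maximum-depth table CSV).
#'
#' @param config a `run_config` (see [load_config()]).
#' @param workflow workflow name.
#' @param out_dir output directory (created if missing).
#' @return A list of the computed results (also written to `out_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config, workflow, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  workflows <- c("fluence", "jacobian", "snr-map", "trace", "depth-scan",
                 "pnc-sweep", "calibrate", "simulate-trace", "reference-defaults")
  if (!workflow %in% workflows)
    stop_invalid("unknown workflow '%s' (choose from %s)", workflow,
                 paste(workflows, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  sidecar <- function(name, extra = list()) {
    meta <- c(list(config_md5 = hash, seed = config$transport$seed,
                   n_photons = config$transport$n_photons), extra)
    jsonlite::write_json(meta, file.path(out_dir, paste0(name, ".meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  path_unset <- function(p)
    is.null(p) || length(p) != 1L || is.na(p) || !nzchar(p) || !file.exists(p)
  need_wset <- function() {
    p <- config$paths$jacobian
    if (path_unset(p))
      stop_invalid("workflow '%s' needs paths$jacobian pointing at a stored w_set (missing: %s)",
                   workflow, if (is.null(p)) "<unset>" else p)
    readRDS(p)
  }

  med <- config_medium(config)
  geom <- config_geometry(config)
  gates <- list(n = config$transport$gates_n,
                t_end_ns = config$transport$gates_t_end_ns)

  build <- function() build_w_set(med, geom, config$transport$n_photons,
                                  config$transport$seed, gates,
                                  engine = config$transport$engine)
  res <- switch(workflow,
    "fluence" = {
      ws <- build()
      for (nm in names(ws$fluence))
        write_grid(ws$fluence[[nm]], file.path(out_dir, paste0("fluence_", nm, ".rds")))
      sidecar("fluence")
      ws$fluence
    },
    "jacobian" = {
      ws <- build()
      saveRDS(ws, file.path(out_dir, "w_set.rds"))
      sidecar("w_set")
      ws
    },
    "snr-map" = {
      ws <- need_wset()
      m <- snr_map(ws, config_af(config), config$target$coefficient_mm1,
                   config_noise(config), config$p_src_mW,
                   seed = config$transport$seed)
      saveRDS(m, file.path(out_dir, "snr_map.rds"))
      sidecar("snr_map")
      m
    },
    "trace" = {
      ws <- need_wset()
      tg <- target_model(config$target$coefficient_mm1,
                         c(0, 0, config$target$depth_mm),
                         config$target$velocity_mm_s)
      ft <- flow_trace(ws, config_af(config), tg, config_noise(config),
                       config$p_src_mW, seed = config$transport$seed)
      write.csv(ft, file.path(out_dir, "flow_trace.csv"), row.names = FALSE)
      sidecar("flow_trace")
      ft
    },
    "depth-scan" = {
      ws <- need_wset()
      ds <- depth_scan(ws, config_af(config), config$target$coefficient_mm1,
                       config_noise(config), config$p_src_mW,
                       seed = config$transport$seed)
      write.csv(ds$table, file.path(out_dir, "depth_scan.csv"),
                row.names = FALSE)
      sidecar("depth_scan")
      ds
    },
    "pnc-sweep" = {
      ws <- need_wset()
      sw <- pnc_sweep(ws, config_af(config), config$target$coefficient_mm1,
                      config$noise$sigma_rel, config$p_src_mW,
                      seed = config$transport$seed)
      write.csv(sw$depths, file.path(out_dir, "pnc_sweep.csv"),
                row.names = FALSE)
      sidecar("pnc_sweep", list(crossover_p_nc = sw$crossover_p_nc))
      sw
    },
    "simulate-trace" = {
      sched <- peak_schedule(
        times_s = seq(2, config$trace$duration_s - 2, length.out = 10),
        amplitudes_nA = rep(47.3, 10))
      tr <- make_trace(config$trace$background_nA, config$noise$sigma_rel,
                       sched, config$trace$duration_s,
                       config$trace$sample_rate_hz,
                       seed = config$transport$seed)
      write_trace(tr, file.path(out_dir, "trace.csv"))
      jsonlite::write_json(attr(tr, "ground_truth"),
                           file.path(out_dir, "trace.truth.json"),
                           auto_unbox = TRUE, digits = NA)
      sidecar("trace")
      tr
    },
    "calibrate" = {
      p <- config$paths$trace_csv
      if (path_unset(p))
        stop_invalid("workflow 'calibrate' needs paths$trace_csv (missing: %s)",
                     if (is.null(p)) "<unset>" else p)
      tr <- read_trace(p)
      W <- if (!path_unset(config$paths$jacobian))
        readRDS(config$paths$jacobian)$W$A1 else NULL
      cal <- calibrate_trace(tr, W, config$p_src_mW,
                             conversion_constant(config$conversion$factor_W_mm2_nA))
      out <- unclass(cal)
      out$peaks <- NULL
      out$n_peaks <- nrow(cal$peaks)
      jsonlite::write_json(out, file.path(out_dir, "calibration.json"),
                           auto_unbox = TRUE, digits = NA)
      sidecar("calibration")
      cal
    },
    "reference-defaults" = {
      ws <- build()
      np <- config_noise(config)
      tabs <- lapply(c("surface_weighted", "homogeneous"), function(kind) {
        af <- af_model(kind,
                       if (kind == config$af$kind) config$af$coefficient_mm1
                       else NULL,
                       config$af$half_depth_mm)
        ds <- depth_scan(ws, af, config$target$coefficient_mm1, np,
                         config$p_src_mW, seed = config$transport$seed)
        cbind(af_kind = kind, ds$table)
      })
      tab <- do.call(rbind, tabs)
      write.csv(tab, file.path(out_dir, "max_depth_table.csv"),
                row.names = FALSE)
      sidecar("max_depth_table")
      tab
    })
  invisible(res)
}
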