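#' Read and validate an analysis configuration file
#'
#' Plain-text YAML configuration. Required keys: `coverslip_mass_kg`,
#' `coverslip_volume_m3`, `fluid_density_kg_m3`, `pixel_size_um`,
#' `frame_interval_s`, `strain_convention`. Optional keys (with defaults):
#' `gravity` (9.81), `poisson` (0.4), `min_area_px` (64),
#' `role_convention` (`"as_equation"`), `mode` (`"constant_stress"`),
#' `points_per_decade` (20), `extend_low_decades` (0).
#'
#' @param path YAML file path, or a named list already in memory.
#' @return Validated configuration list of class `spherorheo_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  required <- c("coverslip_mass_kg", "coverslip_volume_m3",
                "fluid_density_kg_m3", "pixel_size_um", "frame_interval_s",
                "strain_convention")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  defaults <- list(gravity = 9.81, poisson = 0.4, min_area_px = 64,
                   role_convention = "as_equation", mode = "constant_stress",
                   points_per_decade = 20, extend_low_decades = 0)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$strain_convention %in% c("engineering", "as_written"))
    stop("strain_convention must be 'engineering' or 'as_written'")
  structure(cfg, class = "spherorheo_config")
}

config_load_spec <- function(cfg) {
  load_spec(cfg$coverslip_mass_kg, cfg$coverslip_volume_m3,
            fluid_density = cfg$fluid_density_kg_m3, gravity = cfg$gravity)
}

manifest_add <- function(manifest, name, path) {
  manifest$outputs[[name]] <- path
  manifest
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  missing <- Filter(function(p) !file.exists(p), manifest$outputs)
  if (length(missing) > 0)
    stop("manifest lists missing outputs: ",
         paste(unlist(missing), collapse = ", "))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$manifest_path <- path
  structure(manifest, class = "run_manifest")
}

new_manifest <- function(stage, inputs, cfg, seed) {
  list(stage = stage,
       software = paste0("spherorheo ",
                         as.character(utils::packageVersion("spherorheo"))),
       seed = seed,
       inputs = as.list(inputs),
       config = unclass(cfg),
       warnings = list(),
       outputs = list())
}

#' Run the full analysis pipeline on one experiment
#'
#' End-to-end orchestration: read the input (an image stack, or a
#' pre-extracted stress/strain CSV), measure morphology, build stress and
#' strain histories, fit the Burgers model in the time domain, evaluate the
#' frequency-domain moduli both from the fitted model and model-free from
#' the sampled records, convert to shear, and write every stage's output
#' plus a run manifest into `out_dir`.
#'
#' Outputs written: `measurements.csv` (image input only),
#' `stress_strain.csv`, `burgers_fit.json`, `spectrum_burgers.csv`,
#' `spectrum_irheo.csv`, `spectrum_burgers_shear.csv`,
#' `spectrum_irheo_shear.csv`, `loss_tangent.csv`, `comparison.csv`
#' (plot-ready table of both routes), `manifest.json`.
#'
#' @param input path to a multi-page TIFF, a directory of PNG/TIFF frames,
#'   or a stress/strain CSV (see [read_stress_strain()]).
#' @param config configuration file path or list, see [read_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @return The run manifest (class `run_manifest`), invisibly.
#' @export
analyze_experiment <- function(input, config, out_dir, seed = 1L) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new_manifest("analyze", c(input = input), cfg, seed)
  spec <- config_load_spec(cfg)

  is_csv <- is.character(input) && grepl("\\.csv$", input, ignore.case = TRUE)
  if (is_csv) {
    series <- read_stress_strain(input)
  } else {
    images <- read_image_stack(input)
    frames <- measure_stack(images, pixel_size = cfg$pixel_size_um * 1e-6,
                            frame_interval = cfg$frame_interval_s,
                            min_area_px = cfg$min_area_px)
    mpath <- file.path(out_dir, "measurements.csv")
    utils::write.csv(as.data.frame(frames), mpath, row.names = FALSE)
    manifest <- manifest_add(manifest, "measurements", mpath)
    series <- stress_strain_series(frames, spec,
                                   convention = cfg$strain_convention)
  }
  spath <- file.path(out_dir, "stress_strain.csv")
  write_stress_strain(series, spath)
  manifest <- manifest_add(manifest, "stress_strain", spath)

  eng <- as_engineering(series)
  fit <- fit_burgers(eng, mode = cfg$mode,
                     role_convention = cfg$role_convention)
  fpath <- file.path(out_dir, "burgers_fit.json")
  jsonlite::write_json(
    list(params = unclass(fit$params), report = as.list(fit$report),
         role_convention = fit$role_convention,
         residual_norm = fit$residual_norm, se = as.list(fit$se),
         converged = fit$converged, n_points = fit$n_points,
         mode = fit$mode),
    fpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- manifest_add(manifest, "burgers_fit", fpath)

  omega <- default_frequency_grid(eng$time_s,
                                  points_per_decade = cfg$points_per_decade,
                                  extend_low_decades = cfg$extend_low_decades)
  spec_model <- burgers_moduli(fit$params, omega)
  spec_irheo <- complex_modulus(eng, omega = omega)
  bpath <- file.path(out_dir, "spectrum_burgers.csv")
  ipath <- file.path(out_dir, "spectrum_irheo.csv")
  write_spectrum(spec_model, bpath)
  write_spectrum(spec_irheo, ipath)
  manifest <- manifest_add(manifest, "spectrum_burgers", bpath)
  manifest <- manifest_add(manifest, "spectrum_irheo", ipath)

  gb <- compressional_to_shear(spec_model, nu = cfg$poisson)
  gi <- compressional_to_shear(spec_irheo, nu = cfg$poisson)
  gbpath <- file.path(out_dir, "spectrum_burgers_shear.csv")
  gipath <- file.path(out_dir, "spectrum_irheo_shear.csv")
  write_spectrum(gb, gbpath)
  write_spectrum(gi, gipath)
  manifest <- manifest_add(manifest, "spectrum_burgers_shear", gbpath)
  manifest <- manifest_add(manifest, "spectrum_irheo_shear", gipath)

  lt_model <- loss_tangent(spec_model)
  lt_irheo <- loss_tangent(spec_irheo)
  lt <- merge(lt_model, lt_irheo, by = "omega_rad_s",
              suffixes = c("_burgers", "_irheo"), all = TRUE)
  ltpath <- file.path(out_dir, "loss_tangent.csv")
  utils::write.csv(lt, ltpath, row.names = FALSE)
  manifest <- manifest_add(manifest, "loss_tangent", ltpath)

  comparison <- data.frame(
    omega_rad_s = spec_model$omega_rad_s,
    storage_burgers_Pa = spec_model$storage_Pa,
    loss_burgers_Pa = spec_model$loss_Pa,
    storage_irheo_Pa = spec_irheo$storage_Pa[
      match(spec_model$omega_rad_s, spec_irheo$omega_rad_s)],
    loss_irheo_Pa = spec_irheo$loss_Pa[
      match(spec_model$omega_rad_s, spec_irheo$omega_rad_s)])
  cpath <- file.path(out_dir, "comparison.csv")
  utils::write.csv(comparison, cpath, row.names = FALSE)
  manifest <- manifest_add(manifest, "comparison", cpath)

  invisible(write_manifest(manifest, out_dir))
}

#' Generate a synthetic experiment bundle on disk
#'
#' Runs [simulate_compression()] (and optionally [render_stack()]) and
#' writes the same formats the analysis side reads: `stress_strain.csv`,
#' `measurements.csv`, ground truth as `truth.json`, optionally
#' `frames.tiff`, plus a run manifest.
#'
#' @param config a [simulation_config()] (or `NULL` for the defaults).
#' @param out_dir output directory.
#' @param render also render and write a TIFF image stack (default FALSE).
#' @param pixel_size_m pixel calibration used when rendering (default
#'   4e-6 m/px so a 400-um spheroid fits a 160-px frame).
#' @return The run manifest, invisibly.
#' @export
simulate_experiment <- function(config = NULL, out_dir, render = FALSE,
                                pixel_size_m = 4e-6) {
  if (is.null(config)) config <- simulation_config()
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_compression(config)
  manifest <- new_manifest("simulate", character(0),
                           list(seed = config$seed,
                                noise_cv = config$noise_cv,
                                D0 = config$D0,
                                frame_interval = config$frame_interval,
                                duration = config$duration),
                           config$seed)
  spath <- file.path(out_dir, "stress_strain.csv")
  write_stress_strain(sim$series, spath)
  manifest <- manifest_add(manifest, "stress_strain", spath)
  mpath <- file.path(out_dir, "measurements.csv")
  utils::write.csv(as.data.frame(sim$frames), mpath, row.names = FALSE)
  manifest <- manifest_add(manifest, "measurements", mpath)
  tpath <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(params = unclass(sim$truth$params), net_force = sim$truth$net_force,
         strain = sim$truth$strain, stress = sim$truth$stress,
         diameters = sim$truth$diameters),
    tpath, auto_unbox = TRUE, digits = NA)
  manifest <- manifest_add(manifest, "truth", tpath)
  if (render) {
    stack <- render_stack(sim$truth$diameters, pixel_size = pixel_size_m,
                          seed = config$seed)
    rpath <- file.path(out_dir, "frames.tiff")
    tiff::writeTIFF(lapply(stack$frames, function(f) pmin(pmax(f, 0), 1)),
                    rpath)
    manifest <- manifest_add(manifest, "frames", rpath)
  }
  invisible(write_manifest(manifest, out_dir))
}
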