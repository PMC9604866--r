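#' Default run configuration
#'
#' Nested list describing a full SAR-guided imaging run: phantom, pulse,
#' forward model, SAR localization, aperture planning, acquisition and
#' imaging sections plus a global seed. Any field may be overridden in a
#' YAML/JSON config file ([read_run_config()]); unknown keys are rejected.
#' Fields set to `"auto"` are resolved at run time: the imaging medium
#' permittivity from the straight-ray path to the SAR estimate, the
#' imaging plane from the estimate's depth, and the sampling time offset
#' from the pulse time shift.
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    phantom = list(
      breast_radius_mm = 50, skin_thickness_mm = 2,
      skin = list(permittivity = 37, conductivity = 1.1, density = 1000),
      interior = list(permittivity = 9, conductivity = 0.4,
                      density = 1000),
      tumors = list(list(center_mm = c(20, -13, 14), radius_mm = 5,
                         permittivity = 50, conductivity = 1.2,
                         density = 1000))),
    pulse = list(center_frequency_hz = 5.8e9, impulse_width_s = "auto",
                 time_shift_s = "auto", amplitude = "normalized"),
    forward = list(attenuation_np_per_mm = list(skin = 0.1,
                                                interior = 0.02, air = 0),
                   spreading_exponent = 2, directivity_exponent = 4,
                   artifact_amplitude = 0.01, artifact_decay_s = 5e-10,
                   noise_sigma = 0),
    sar = list(source_position_mm = c(0, 0, 60), e0 = 1,
               reference_distance_mm = 10, tumor_contrast = 8,
               voxel_pitch_mm = 1, threshold = 2,
               exclusion_radius_mm = 10),
    aperture = list(mode = "sar_guided", rows = 3, cols = 3,
                    angular_step_deg = 10, standoff_mm = 10,
                    layout = "grid", n_positions = 36,
                    plane_height_mm = 20),
    acquisition = list(n_samples = 512, t_max_s = 5e-9),
    imaging = list(n_x = 350, n_y = 350, region_mm = c(-50, 50, -50, 50),
                   medium_permittivity = "auto", intensity_exponent = 2,
                   interpolation = "linear", detection = "envelope",
                   velocity_model = "sqrt", time_offset_s = "auto",
                   plane_z_mm = "auto")),
    class = "run_config")
}

# Recursively merge user values into defaults, rejecting unknown keys.
merge_config <- function(default, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    default[[nm]] <-
      if (is.list(default[[nm]]) && is.list(user[[nm]]) &&
          !is.null(names(default[[nm]])) && nm != "tumors")
        merge_config(default[[nm]], user[[nm]], paste0(path, ".", nm))
      else user[[nm]]
  }
  default
}

#' Read and validate a run configuration file
#'
#' Loads a YAML or JSON config, merges it over [default_run_config()] and
#' rejects unknown keys with a field-path message. Top-level sections
#' (`phantom`, `pulse`, ...) may be partial; omitted fields keep defaults.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- read_config_file(path)
  cfg <- merge_config(unclass(default_run_config()), user)
  structure(cfg, class = "run_config")
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic fan-out: a small polynomial hash of the stage name is
#' folded into the global seed modulo 2^31 - 1, so stages can be re-run in
#' isolation with reproducible randomness.
#'
#' @param seed Global integer seed.
#' @param stage Stage name string.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1))
}

config_phantom <- function(pc) {
  tis <- function(t) tissue_properties(t$permittivity, t$conductivity,
                                       t$density %||% 1000)
  tumors <- lapply(pc$tumors %||% list(), function(tum)
    tumor_sphere(unlist(tum$center_mm), tum$radius_mm,
                 tissue_properties(tum$permittivity, tum$conductivity,
                                   tum$density %||% 1000)))
  breast_phantom(pc$breast_radius_mm, pc$skin_thickness_mm,
                 skin = tis(pc$skin), interior = tis(pc$interior),
                 tumors = tumors)
}

config_pulse <- function(pc) {
  f0 <- pc$center_frequency_hz
  tau <- if (identical(pc$impulse_width_s, "auto")) 1 / f0
         else pc$impulse_width_s
  tc <- if (identical(pc$time_shift_s, "auto")) 5 * tau else pc$time_shift_s
  pulse_params(f0, tau, tc, amplitude = pc$amplitude)
}

#' Run the full SAR-guided imaging pipeline
#'
#' Executes the end-to-end chain for one seed: synthesize the illumination
#' field, compute the SAR map, locate its maximum, plan the antenna
#' aperture (SAR-guided grid or conventional full ring per the config),
#' simulate the tumor-free and cancerous scan records, reconstruct the DAS
#' image and, when the phantom contains a tumor, evaluate localization
#' quality. Stage progress is logged to stderr. When the SAR step yields
#' no confident detection the pipeline stops with status
#' `"no_detection"`.
#'
#' @param config A `run_config` (default [default_run_config()]).
#' @param out_dir Optional output directory: writes the resolved config,
#'   tumor estimate JSON, scan record directories, the image as TSV (and
#'   PNG if the `png` package is available) and the evaluation report.
#' @return List of class `cmi_pipeline`: `status` (`"ok"` or
#'   `"no_detection"`), `estimate`, `geometry`, `image`, `report`,
#'   `records`, `seeds`, `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  t_start <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[%6.2fs] %s",
                                         proc.time()[["elapsed"]] - t_start,
                                         msg))
  phantom <- config_phantom(config$phantom)
  pulse <- config_pulse(config$pulse)
  seeds <- list(baseline = stage_seed(config$seed, "baseline"),
                cancerous = stage_seed(config$seed, "cancerous"))

  stage("synthesizing illumination field / SAR map")
  sc <- config$sar
  field <- synthesize_field(phantom, unlist(sc$source_position_mm),
                            e0 = sc$e0,
                            reference_distance = sc$reference_distance_mm,
                            tumor_contrast = sc$tumor_contrast,
                            lattice = default_lattice(phantom,
                                                      sc$voxel_pitch_mm))
  est <- locate_tumor(sar_from_field(field, phantom),
                      threshold = sc$threshold,
                      exclusion_radius = sc$exclusion_radius_mm)
  if (!isTRUE(est$detected)) {
    stage("no confident SAR detection; stopping")
    return(structure(list(status = "no_detection", estimate = est,
                          config = config),
                     class = "cmi_pipeline"))
  }
  stage(sprintf("SAR max %.3g W/kg at (%.1f, %.1f, %.1f) mm",
                est$max_value, est$position[1], est$position[2],
                est$position[3]))

  ac <- config$aperture
  if (ac$mode == "sar_guided") {
    geometry <- plan_aperture(est$position, phantom,
                              standoff = ac$standoff_mm, rows = ac$rows,
                              cols = ac$cols,
                              angular_step = ac$angular_step_deg,
                              mode = ac$layout)
    focus <- est$position
  } else if (ac$mode == "full_ring") {
    geometry <- plan_full_ring(phantom, n_positions = ac$n_positions,
                               standoff = ac$standoff_mm,
                               plane_height = ac$plane_height_mm)
    focus <- c(0, 0, ac$plane_height_mm)
  } else stop("aperture mode must be 'sar_guided' or 'full_ring'",
              call. = FALSE)

  stage(sprintf("simulating %d-position scan (B, TB)",
                nrow(geometry$positions)))
  fc <- config$forward
  att <- unlist(fc$attenuation_np_per_mm)
  fw <- function(seed) forward_model_params(
    attenuation = att[c("skin", "interior", "air")],
    spreading_exponent = fc$spreading_exponent,
    directivity_exponent = fc$directivity_exponent,
    artifact_amplitude = fc$artifact_amplitude,
    artifact_decay = fc$artifact_decay_s,
    noise_sigma = fc$noise_sigma, seed = seed)
  taxis <- default_time_axis(config$acquisition$n_samples,
                             config$acquisition$t_max_s)
  tb <- simulate_scan(phantom, geometry, pulse, fw(seeds$cancerous),
                      with_tumors = TRUE, time_axis = taxis)
  b <- simulate_scan(phantom, geometry, pulse, fw(seeds$baseline),
                     with_tumors = FALSE, time_axis = taxis)

  ic <- config$imaging
  eps <- if (identical(ic$medium_permittivity, "auto"))
    effective_permittivity(
      phantom, geometry$positions[ceiling(nrow(geometry$positions) / 2), ],
      focus)
  else ic$medium_permittivity
  plane_z <- if (identical(ic$plane_z_mm, "auto")) focus[3] else ic$plane_z_mm
  toff <- if (identical(ic$time_offset_s, "auto")) {
    if (ic$detection == "envelope") pulse$time_shift
    else pulse_peak_time(pulse)
  } else ic$time_offset_s
  icfg <- imaging_config(n_x = ic$n_x, n_y = ic$n_y,
                         region = unlist(ic$region_mm),
                         medium_permittivity = eps,
                         intensity_exponent = ic$intensity_exponent,
                         interpolation = ic$interpolation,
                         detection = ic$detection,
                         time_offset = toff, plane_z = plane_z,
                         velocity_model = ic$velocity_model)
  stage(sprintf("reconstructing %d x %d image (eps_eff = %.2f)",
                ic$n_x, ic$n_y, eps))
  img <- reconstruct(tb, b, icfg)

  report <- if (length(phantom$tumors)) {
    tum <- phantom$tumors[[1]]
    evaluate_image(img, tum$center[1:2], tum$radius)
  } else NULL
  stage("done")

  res <- structure(list(status = "ok", estimate = est,
                        geometry = geometry, image = img, report = report,
                        records = list(cancerous = tb, tumor_free = b),
                        seeds = seeds, config = config),
                   class = "cmi_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(res$config)
  cfg$provenance <- list(config_hash = rlang::hash(unclass(res$config)),
                         seeds = res$seeds)
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tumor_estimate(res$estimate, file.path(out_dir, "estimate.json"))
  if (res$status != "ok") return(invisible(out_dir))
  write_scan_record(res$records$cancerous, file.path(out_dir, "cancerous"))
  write_scan_record(res$records$tumor_free,
                    file.path(out_dir, "tumor_free"))
  write_image_tsv(res$image, file.path(out_dir, "image.tsv"))
  if (requireNamespace("png", quietly = TRUE))
    write_image_png(res$image, file.path(out_dir, "image.png"))
  if (!is.null(res$report))
    jsonlite::write_json(unclass(res$report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cmi_pipeline <- function(x, ...) {
  cat("SAR-guided CMI pipeline run: status", x$status, "\n")
  if (!is.null(x$estimate)) print(x$estimate)
  if (x$status == "ok") {
    print(x$image)
    if (!is.null(x$report)) print(x$report)
  }
  invisible(x)
}
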