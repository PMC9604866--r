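# Speed of light, mm/s (2.9979e8 m/s).
C_MM_S <- 2.9979e11

#' Antenna scan geometry
#'
#' An ordered set of monostatic antenna phase-center positions arranged
#' logically as a rows x cols grid (the grid structure drives row-average
#' clutter removal), each with a unit boresight direction. All positions
#' must lie in air, outside the phantom; this is validated against a
#' phantom at simulation time.
#'
#' @param positions n x 3 numeric matrix of positions, mm.
#' @param grid_rows,grid_cols Logical grid shape; `grid_rows * grid_cols`
#'   must equal `nrow(positions)`.
#' @param standoff Nominal antenna standoff from the skin surface, mm
#'   (default 10). Recorded for provenance; positions are authoritative.
#' @param boresights n x 3 matrix of pointing directions (normalized
#'   internally). Default: toward the origin.
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(positions, grid_rows, grid_cols, standoff = 10,
                          boresights = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix (mm)", call. = FALSE)
  n <- nrow(positions)
  if (grid_rows * grid_cols != n)
    stop(sprintf("grid_rows * grid_cols (%d x %d) must equal %d positions",
                 grid_rows, grid_cols, n), call. = FALSE)
  if (is.null(boresights))
    boresights <- -positions
  boresights <- as.matrix(boresights)
  stopifnot(nrow(boresights) == n, ncol(boresights) == 3L)
  nrm <- sqrt(rowSums(boresights^2))
  if (any(nrm == 0)) stop("zero boresight vector", call. = FALSE)
  boresights <- boresights / nrm
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  dimnames(boresights) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions, grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), standoff = standoff,
                 boresights = boresights),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("Scan geometry: %d positions (%d x %d grid), standoff %.1f mm\n",
              nrow(x$positions), x$grid_rows, x$grid_cols, x$standoff))
  invisible(x)
}

#' Forward-model parameters
#'
#' Parameterizes the point-scatterer monostatic backscatter model that
#' stands in for a full-wave solver: per-tissue amplitude attenuation
#' (Np/mm, applied over the round-trip path), power-law spreading
#' (amplitude 1/d^`spreading_exponent` with d the one-way path length in
#' mm), a cos^n antenna directivity pattern about the boresight, a
#' position-independent antenna reverberation artifact (damped sinusoid at
#' the pulse center frequency), and seeded additive white Gaussian noise.
#'
#' Defaults: alpha_skin = 0.1 Np/mm, alpha_interior = 0.02 Np/mm, air
#' lossless; spreading exponent 2; directivity exponent 4; artifact
#' amplitude 0.01; noiseless.
#'
#' @param attenuation Named vector of Np/mm values with entries `skin`,
#'   `interior`, `air`.
#' @param spreading_exponent Non-negative; 2 gives round-trip 1/d^2
#'   amplitude spreading.
#' @param directivity_exponent n in cos^n; 0 disables the pattern.
#' @param artifact_amplitude Amplitude of the reverberation artifact.
#' @param artifact_decay Artifact 1/e decay time, seconds.
#' @param noise_sigma Std. dev. of additive Gaussian noise (signal units).
#' @param seed Integer RNG seed recorded in provenance.
#' @return Object of class `forward_model_params`.
#' @export
forward_model_params <- function(attenuation = c(skin = 0.1,
                                                 interior = 0.02, air = 0),
                                 spreading_exponent = 2,
                                 directivity_exponent = 4,
                                 artifact_amplitude = 0.01,
                                 artifact_decay = 5e-10,
                                 noise_sigma = 0,
                                 seed = 1L) {
  stopifnot(all(c("skin", "interior", "air") %in% names(attenuation)),
            all(attenuation >= 0), spreading_exponent >= 0,
            directivity_exponent >= 0, artifact_amplitude >= 0,
            noise_sigma >= 0)
  structure(list(attenuation = attenuation,
                 spreading_exponent = spreading_exponent,
                 directivity_exponent = directivity_exponent,
                 artifact_amplitude = artifact_amplitude,
                 artifact_decay = artifact_decay,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "forward_model_params")
}

#' Straight-ray path lengths through the phantom layers
#'
#' Splits the segment from an exterior point to an interior target into
#' air / skin / interior lengths using sphere-crossing solutions (no
#' refraction at interfaces, consistent with the DAS imaging model; the
#' hemisphere is treated as a full sphere for crossing purposes, adequate
#' for antennas approaching the curved surface).
#'
#' @param position Exterior point, 3-vector mm.
#' @param target Target point, 3-vector mm (inside or outside).
#' @param phantom A `breast_phantom`.
#' @return Named numeric vector `c(air=, skin=, interior=)` in mm.
#' @export
ray_path_lengths <- function(position, target, phantom) {
  p0 <- as.numeric(position); q <- as.numeric(target)
  d <- q - p0
  len <- sqrt(sum(d^2))
  if (len == 0) return(c(air = 0, skin = 0, interior = 0))
  r_out <- phantom$breast_radius
  r_in <- phantom$breast_radius - phantom$skin_thickness
  cross <- function(R) {
    # first t in [0,1] with |p0 + t d| = R
    a <- sum(d^2); b <- 2 * sum(p0 * d); cc <- sum(p0^2) - R^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    ts <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    ts <- ts[ts >= 0 & ts <= 1]
    if (length(ts)) ts[1] else NA_real_
  }
  t_out <- cross(r_out)
  t_in <- cross(r_in)
  if (is.na(t_out)) return(c(air = len, skin = 0, interior = 0))
  if (is.na(t_in))
    return(c(air = t_out * len, skin = (1 - t_out) * len, interior = 0))
  c(air = t_out * len, skin = (t_in - t_out) * len,
    interior = (1 - t_in) * len)
}

#' Monostatic round-trip delay to a target
#'
#' Two-way travel time along the straight ray, with the air segment at c
#' and tissue segments at c/sqrt(eps_r) of the respective layer.
#'
#' @inheritParams ray_path_lengths
#' @return Delay in seconds.
#' @examples
#' ph <- make_default_phantom()
#' round_trip_delay(c(0, 0, 60), c(0, 0, 30), ph)
#' @export
round_trip_delay <- function(position, target, phantom) {
  seg <- ray_path_lengths(position, target, phantom)
  2 * (seg[["air"]] +
       seg[["skin"]] * sqrt(phantom$skin$permittivity) +
       seg[["interior"]] * sqrt(phantom$interior$permittivity)) / C_MM_S
}

#' Simulate a monostatic scan record
#'
#' Produces one backscatter waveform per antenna position: reverberation
#' artifact + skin specular echo + one echo per tumor + optional noise.
#' Echo delays use piecewise straight-ray propagation
#' ([round_trip_delay()]); amplitudes combine the Fresnel-style impedance
#' contrast at each interface, exp(-alpha d) attenuation over the round
#' trip, 1/d^spreading geometric spreading, the cos^n directivity toward
#' boresight, and a (radius / 5 mm)^3 Rayleigh-type size factor for
#' tumors. With `with_tumors = FALSE` the tumor sum is omitted, yielding
#' the tumor-free baseline record B; otherwise the cancerous record TB.
#'
#' Noise is drawn once per record from `params$seed`, independent of the
#' tumor content, so B and TB of the same seed share identical noise and
#' two calls with equal arguments are bit-identical.
#'
#' @param phantom A `breast_phantom`.
#' @param geometry A `scan_geometry`; every position must be in air.
#' @param pulse A [pulse_params()] object.
#' @param params A [forward_model_params()] object.
#' @param with_tumors Include tumor echoes? Default TRUE.
#' @param time_axis Shared time grid, seconds (default
#'   [default_time_axis()]).
#' @return A `scan_record` (label `"cancerous"` or `"tumor_free"`).
#' @export
simulate_scan <- function(phantom, geometry, pulse, params,
                          with_tumors = TRUE,
                          time_axis = default_time_axis()) {
  stopifnot(inherits(phantom, "breast_phantom"),
            inherits(geometry, "scan_geometry"),
            inherits(pulse, "pulse_params"),
            inherits(params, "forward_model_params"))
  labs <- phantom_contains(phantom, geometry$positions)
  if (any(labs != "air"))
    stop("geometry error: antenna position(s) ",
         paste(which(labs != "air"), collapse = ", "),
         " are inside the phantom", call. = FALSE)
  check_uniform_grid(time_axis)
  n_pos <- nrow(geometry$positions)
  nt <- length(time_axis)

  art <- params$artifact_amplitude *
    sin(2 * pi * pulse$center_frequency * time_axis) *
    exp(-time_axis / params$artifact_decay)

  gamma <- function(e1, e2) (sqrt(e1) - sqrt(e2)) / (sqrt(e1) + sqrt(e2))
  g_skin <- gamma(1, phantom$skin$permittivity)
  sig <- matrix(rep(art, n_pos), nrow = n_pos, byrow = TRUE)

  for (i in seq_len(n_pos)) {
    pos <- geometry$positions[i, ]
    bs <- geometry$boresights[i, ]
    # specular skin echo along the radial line (nearest surface point)
    d_air <- sqrt(sum(pos^2)) - phantom$breast_radius
    if (d_air > 0) {
      ang <- angle_between(bs, -pos)
      amp <- g_skin * directivity(ang, params$directivity_exponent) /
        d_air^params$spreading_exponent
      sig[i, ] <- sig[i, ] +
        amp * monocycle_values(pulse, time_axis - 2 * d_air / C_MM_S)
    }
    if (with_tumors) {
      for (tum in phantom$tumors) {
        seg <- ray_path_lengths(pos, tum$center, phantom)
        d_tot <- sum(seg)
        tau <- round_trip_delay(pos, tum$center, phantom)
        g_tum <- gamma(phantom$interior$permittivity,
                       tum$tissue$permittivity)
        atten <- exp(-2 * sum(params$attenuation[c("air", "skin",
                                                   "interior")] *
                              seg[c("air", "skin", "interior")]))
        ang <- angle_between(bs, tum$center - pos)
        amp <- g_tum * atten * (tum$radius / 5)^3 *
          directivity(ang, params$directivity_exponent) /
          d_tot^params$spreading_exponent
        sig[i, ] <- sig[i, ] +
          amp * monocycle_values(pulse, time_axis - tau)
      }
    }
  }
  if (params$noise_sigma > 0) {
    old <- .Random.seed_save()
    set.seed(params$seed)
    sig <- sig + matrix(stats::rnorm(n_pos * nt, 0, params$noise_sigma),
                        nrow = n_pos)
    .Random.seed_restore(old)
  }
  scan_record(geometry, time_axis, sig,
              label = if (with_tumors) "cancerous" else "tumor_free",
              meta = list(seed = params$seed,
                          pulse = unclass(pulse),
                          params_hash = rlang::hash(unclass(params)),
                          phantom_hash = rlang::hash(unclass(phantom))))
}

# save/restore global RNG state so simulation does not disturb user RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca)))
}

directivity <- function(angle, n) {
  if (n == 0) return(1)
  ifelse(angle >= pi / 2, 0, cos(angle)^n)
}

#' Monostatic scan record
#'
#' Container pairing a [scan_geometry()] with one time-domain waveform per
#' position on a shared uniform time axis, plus a processing-stage label
#' (`tumor_free`, `cancerous`, `calibrated`, `processed`) and provenance
#' metadata.
#'
#' @param geometry A `scan_geometry`.
#' @param time_axis Shared time grid, seconds.
#' @param signals n_positions x n_times numeric matrix.
#' @param label Stage label.
#' @param meta Named list of provenance fields.
#' @return Object of class `scan_record`.
#' @export
scan_record <- function(geometry, time_axis, signals,
                        label = c("cancerous", "tumor_free", "calibrated",
                                  "processed"),
                        meta = list()) {
  label <- match.arg(label)
  stopifnot(inherits(geometry, "scan_geometry"))
  signals <- as.matrix(signals)
  if (nrow(signals) != nrow(geometry$positions))
    stop("one waveform per antenna position required", call. = FALSE)
  if (ncol(signals) != length(time_axis))
    stop("signals and time axis length mismatch", call. = FALSE)
  check_uniform_grid(time_axis)
  structure(list(geometry = geometry, time_axis = as.numeric(time_axis),
                 signals = signals, label = label, meta = meta),
            class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf(
    "Scan record [%s]: %d positions (%d x %d), %d samples, %.2f ns window\n",
    x$label, nrow(x$signals), x$geometry$grid_rows, x$geometry$grid_cols,
    ncol(x$signals), diff(range(x$time_axis)) * 1e9))
  invisible(x)
}

#' Write / read a scan record as a plain-text directory
#'
#' Layout: `geometry.tsv` (position and boresight columns), `signals.tsv`
#' (first column `time_s`, then one column per position) and `meta.json`
#' (label, grid shape, standoff, provenance).
#'
#' @param record A `scan_record`.
#' @param dir Directory path (created if needed).
#' @return `read_scan_record()` returns a `scan_record`;
#'   `write_scan_record()` returns `dir` invisibly.
#' @export
write_scan_record <- function(record, dir) {
  stopifnot(inherits(record, "scan_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geo <- record$geometry
  utils::write.table(
    data.frame(x = geo$positions[, 1], y = geo$positions[, 2],
               z = geo$positions[, 3],
               bx = geo$boresights[, 1], by = geo$boresights[, 2],
               bz = geo$boresights[, 3]),
    file.path(dir, "geometry.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  sigs <- as.data.frame(t(record$signals))
  names(sigs) <- sprintf("s%03d", seq_len(nrow(record$signals)))
  utils::write.table(cbind(data.frame(time_s = record$time_axis), sigs),
                     file.path(dir, "signals.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(label = record$label, grid_rows = geo$grid_rows,
         grid_cols = geo$grid_cols, standoff = geo$standoff,
         meta = record$meta),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname write_scan_record
#' @export
read_scan_record <- function(dir) {
  geo_df <- utils::read.delim(file.path(dir, "geometry.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sig_df <- utils::read.delim(file.path(dir, "signals.tsv"))
  geometry <- scan_geometry(as.matrix(geo_df[, c("x", "y", "z")]),
                            meta$grid_rows, meta$grid_cols,
                            standoff = meta$standoff,
                            boresights = as.matrix(geo_df[, c("bx", "by",
                                                              "bz")]))
  scan_record(geometry, sig_df$time_s,
              t(as.matrix(sig_df[, -1, drop = FALSE])),
              label = meta$label, meta = as.list(meta$meta))
}

#' Import per-position two-column waveform files as a scan record
#'
#' @param files Character vector of delimited-text waveform files
#'   (columns `time_s`, `amplitude`), one per antenna position, in
#'   geometry order.
#' @param geometry Matching `scan_geometry`.
#' @param label Stage label for the assembled record.
#' @return A `scan_record`.
#' @export
import_scan_waveforms <- function(files, geometry, label = "cancerous") {
  wfs <- lapply(files, read_waveform_tsv)
  t0 <- wfs[[1]]$time
  for (w in wfs)
    if (length(w$time) != length(t0) || max(abs(w$time - t0)) > 1e-15)
      stop("all imported waveforms must share one time axis", call. = FALSE)
  scan_record(geometry, t0, do.call(rbind, lapply(wfs, `[[`, "samples")),
              label = label,
              meta = list(imported_from = basename(files)))
}
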