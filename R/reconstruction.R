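#' Imaging configuration for DAS synthetic focusing
#'
#' Controls the delay-and-sum image formation. The image is formed on an
#' `n_x` x `n_y` pixel grid mapped onto a physical rectangle in the
#' xy-plane at height `plane_z`; each antenna's `h` is its z-offset from
#' that plane. Round-trip time uses a single effective medium permittivity
#' (default: the skin value 37; see [effective_permittivity()] for a
#' path-based estimate). `velocity_model = "sqrt"` uses the physical tissue
#' wave speed c/sqrt(eps_r); `"literal"` uses c/eps_r, reproducing a common
#' typeset form of the round-trip equation.
#'
#' @param n_x,n_y Pixel counts, >= 2. Default 350 x 350.
#' @param region Physical rectangle `c(x_min, x_max, y_min, y_max)` in mm.
#'   Default the 100 mm x 100 mm footprint centered on the origin.
#' @param medium_permittivity Effective eps_r for delay computation,
#'   >= 1. Default 37.
#' @param intensity_exponent Even integer >= 2 applied to each sampled
#'   value before summing. Default 2.
#' @param interpolation `"linear"` (default) or `"nearest"` fractional-delay
#'   sampling.
#' @param detection `"raw"` (default; sample the processed signal itself)
#'   or `"envelope"` (sample its analytic-signal magnitude, which centers
#'   the response of a bipolar pulse).
#' @param time_offset Seconds added to every computed delay before
#'   sampling, aligning the waveform's internal pulse reference (e.g.
#'   [pulse_peak_time()] for raw sampling of a causal monocycle). Default 0.
#' @param plane_z Imaging plane height, mm. Default 0.
#' @param velocity_model `"sqrt"` (default) or `"literal"`.
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(n_x = 350, n_y = 350,
                           region = c(-50, 50, -50, 50),
                           medium_permittivity = 37,
                           intensity_exponent = 2,
                           interpolation = c("linear", "nearest"),
                           detection = c("raw", "envelope"),
                           time_offset = 0, plane_z = 0,
                           velocity_model = c("sqrt", "literal")) {
  interpolation <- match.arg(interpolation)
  detection <- match.arg(detection)
  velocity_model <- match.arg(velocity_model)
  if (n_x < 2 || n_y < 2) stop("pixel grid must be >= 2 x 2", call. = FALSE)
  if (length(region) != 4 || region[2] <= region[1] ||
      region[4] <= region[3])
    stop("region must be a non-degenerate c(x_min, x_max, y_min, y_max)",
         call. = FALSE)
  if (medium_permittivity < 1)
    stop("medium_permittivity must be >= 1", call. = FALSE)
  if (intensity_exponent < 2 || intensity_exponent %% 2 != 0)
    stop("intensity_exponent must be an even integer >= 2", call. = FALSE)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 region = as.numeric(region),
                 medium_permittivity = medium_permittivity,
                 intensity_exponent = as.integer(intensity_exponent),
                 interpolation = interpolation, detection = detection,
                 time_offset = time_offset, plane_z = plane_z,
                 velocity_model = velocity_model),
            class = "imaging_config")
}

#' Calibration: subtract the tumor-free baseline
#'
#' Per antenna position, T(t) = TB(t) - B(t): the cancerous record minus
#' the tumor-free record, isolating an approximate tumor waveform. Both
#' records must share geometry and time axis.
#'
#' @param cancerous `scan_record` with tumors (TB).
#' @param tumor_free Baseline `scan_record` (B).
#' @return A `scan_record` with label `"calibrated"`.
#' @export
calibrate <- function(cancerous, tumor_free) {
  stopifnot(inherits(cancerous, "scan_record"),
            inherits(tumor_free, "scan_record"))
  if (!isTRUE(all.equal(cancerous$time_axis, tumor_free$time_axis,
                        tolerance = 1e-12)))
    stop("records must share one time axis", call. = FALSE)
  if (!isTRUE(all.equal(cancerous$geometry$positions,
                        tumor_free$geometry$positions,
                        tolerance = 1e-9)))
    stop("records must share one scan geometry", call. = FALSE)
  scan_record(cancerous$geometry, cancerous$time_axis,
              cancerous$signals - tumor_free$signals,
              label = "calibrated",
              meta = c(cancerous$meta,
                       list(baseline_seed = tumor_free$meta$seed)))
}

#' Row-average clutter removal
#'
#' For each logical grid row, the row-mean signal A_X(t) (sum over the
#' row's antennas divided by the number of antennas in that row) is
#' subtracted from every signal in the row: P_XY(t) = T_XY(t) - A_X(t).
#' Signals common to a whole row (antenna reverberation, equal-standoff
#' skin reflections) cancel exactly, while position-dependent tumor
#' responses survive. By construction the clutter-removed signals sum to
#' zero within each row at every time sample.
#'
#' A degenerate single-column row annihilates its own signal (P = 0); this
#' is emitted with a warning. A 1 x n ring geometry subtracts the mean over
#' all positions (its single row), the ring-mode variant.
#'
#' @param calibrated A `scan_record` (typically label `"calibrated"`).
#' @return A `scan_record` with label `"processed"`.
#' @export
remove_clutter <- function(calibrated) {
  stopifnot(inherits(calibrated, "scan_record"))
  geo <- calibrated$geometry
  if (geo$grid_cols == 1L && geo$grid_rows > 1L)
    warning("single-column rows: row-average clutter removal annihilates the signal (P = 0)",
            call. = FALSE)
  sig <- calibrated$signals
  out <- sig
  for (row in seq_len(geo$grid_rows)) {
    idx <- (row - 1L) * geo$grid_cols + seq_len(geo$grid_cols)
    avg <- colMeans(sig[idx, , drop = FALSE])
    out[idx, ] <- sweep(sig[idx, , drop = FALSE], 2, avg)
  }
  scan_record(geo, calibrated$time_axis, out, label = "processed",
              meta = calibrated$meta)
}

#' Synthetic-focusing round-trip distance
#'
#' D = 2 sqrt((X - x_i)^2 + (Y - y_j)^2 + h^2), the monostatic round-trip
#' distance from an antenna at planar offset (X, Y) and height h to the
#' pixel (x_i, y_j) in the imaging plane. All in mm. Vectorized over
#' pixels.
#'
#' @param antenna_xy Antenna (X, Y), length-2.
#' @param pixel_xy Pixel coordinates: length-2 vector or n x 2 matrix.
#' @param h Antenna height above the imaging plane, mm.
#' @return Distance(s) in mm.
#' @export
focusing_distance <- function(antenna_xy, pixel_xy, h) {
  px <- if (is.matrix(pixel_xy)) pixel_xy else matrix(pixel_xy, ncol = 2,
                                                      byrow = TRUE)
  2 * sqrt((antenna_xy[1] - px[, 1])^2 + (antenna_xy[2] - px[, 2])^2 + h^2)
}

#' Round-trip travel time in an effective medium
#'
#' t = D sqrt(eps_r) / c with c = 2.9979e8 m/s (distance in mm). With
#' `velocity_model = "literal"`, t = D eps_r / c instead.
#'
#' @param distance Round-trip distance(s), mm, >= 0.
#' @param medium_permittivity Effective relative permittivity >= 1.
#' @param velocity_model `"sqrt"` (default) or `"literal"`.
#' @return Time(s) in seconds.
#' @examples
#' round_trip_time(20, 37)  # ~4.058e-10 s
#' @export
round_trip_time <- function(distance, medium_permittivity,
                            velocity_model = c("sqrt", "literal")) {
  velocity_model <- match.arg(velocity_model)
  stopifnot(all(distance >= 0), medium_permittivity >= 1)
  slow <- if (velocity_model == "sqrt") sqrt(medium_permittivity)
          else medium_permittivity
  distance * slow / C_MM_S
}

#' Path-based effective medium permittivity
#'
#' The round-trip delay model uses one effective permittivity; this
#' estimates it from the actual straight-ray path between an antenna
#' position and a focal target: sqrt(eps_eff) is the optical path length
#' (air + skin sqrt(eps_skin) + interior sqrt(eps_int)) divided by the
#' geometric length, and the return value is its square. This is the
#' "estimated average of the environment permittivity" appropriate to the
#' scan at hand; the skin-only value 37 remains the configuration default.
#'
#' @param phantom A `breast_phantom`.
#' @param position Antenna position, 3-vector mm.
#' @param target Focal target, 3-vector mm.
#' @return Effective relative permittivity (scalar >= 1).
#' @export
effective_permittivity <- function(phantom, position, target) {
  seg <- ray_path_lengths(position, target, phantom)
  tot <- sum(seg)
  if (tot == 0) return(1)
  opt <- seg[["air"]] + seg[["skin"]] * sqrt(phantom$skin$permittivity) +
    seg[["interior"]] * sqrt(phantom$interior$permittivity)
  max(1, (opt / tot)^2)
}

# Analytic-signal magnitude via FFT (envelope of a real signal).
signal_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Form a DAS intensity image from processed signals
#'
#' For each pixel (x_i, y_j), every channel is sampled at its computed
#' round-trip delay (plus `time_offset`) and the samples, raised to the
#' configured even power, are summed:
#' I(x_i, y_j) = sum_XY P_XY(t_XY(x_i, y_j))^q. Delays falling outside the
#' recorded window contribute 0 and are counted in the returned object's
#' `out_of_span` field.
#'
#' @param processed A `scan_record` (label `"processed"` expected; others
#'   accepted with a message).
#' @param config An [imaging_config()].
#' @return Object of class `cmi_image`: raw `intensity` matrix
#'   (`n_x` x `n_y`, x indexing rows), pixel coordinate vectors `x`, `y`,
#'   the config, an out-of-span sample counter and provenance.
#' @export
form_image <- function(processed, config = imaging_config()) {
  stopifnot(inherits(processed, "scan_record"),
            inherits(config, "imaging_config"))
  if (processed$label != "processed")
    message("forming image from a record labelled '", processed$label, "'")
  if (nrow(processed$signals) == 0) stop("empty scan record", call. = FALSE)
  xs <- seq(config$region[1], config$region[2], length.out = config$n_x)
  ys <- seq(config$region[3], config$region[4], length.out = config$n_y)
  px <- cbind(rep(xs, times = config$n_y), rep(ys, each = config$n_x))
  t0 <- processed$time_axis[1]
  dt <- processed$time_axis[2] - t0
  nt <- length(processed$time_axis)
  acc <- numeric(nrow(px))
  out_of_span <- 0L
  for (k in seq_len(nrow(processed$signals))) {
    pos <- processed$geometry$positions[k, ]
    h <- abs(pos[3] - config$plane_z)
    d <- focusing_distance(pos[1:2], px, h)
    tq <- round_trip_time(d, config$medium_permittivity,
                          config$velocity_model) + config$time_offset
    y <- processed$signals[k, ]
    if (config$detection == "envelope") y <- signal_envelope(y)
    f <- (tq - t0) / dt + 1
    if (config$interpolation == "nearest") {
      i0 <- round(f)
      ok <- i0 >= 1 & i0 <= nt
      smp <- numeric(length(f))
      smp[ok] <- y[i0[ok]]
    } else {
      i0 <- floor(f)
      w <- f - i0
      ok <- i0 >= 1 & i0 < nt
      smp <- numeric(length(f))
      smp[ok] <- y[i0[ok]] * (1 - w[ok]) + y[i0[ok] + 1] * w[ok]
    }
    out_of_span <- out_of_span + sum(!ok)
    acc <- acc + smp^config$intensity_exponent
  }
  structure(list(intensity = matrix(acc, nrow = config$n_x),
                 x = xs, y = ys, config = config,
                 out_of_span = out_of_span,
                 provenance = list(record_label = processed$label,
                                   meta = processed$meta)),
            class = "cmi_image")
}

#' Full reconstruction chain
#'
#' `form_image(remove_clutter(calibrate(cancerous, tumor_free)), config)`,
#' with provenance of all stages carried through.
#'
#' @inheritParams calibrate
#' @param config An [imaging_config()].
#' @return A `cmi_image`.
#' @export
reconstruct <- function(cancerous, tumor_free, config = imaging_config()) {
  img <- form_image(remove_clutter(calibrate(cancerous, tumor_free)),
                    config)
  img$provenance$stages <- c("calibrate", "remove_clutter", "form_image")
  img
}

#' Pixel coordinates of the image intensity maximum
#'
#' Ties break toward the first pixel in column-major order (x fastest).
#'
#' @param image A `cmi_image`.
#' @return Length-2 vector (x, y) in mm, or `NULL` for an all-zero image.
#' @export
image_peak <- function(image) {
  stopifnot(inherits(image, "cmi_image"))
  if (all(image$intensity == 0)) return(NULL)
  idx <- arrayInd(which.max(image$intensity), dim(image$intensity))
  c(image$x[idx[1]], image$y[idx[2]])
}

#' @export
print.cmi_image <- function(x, ...) {
  pk <- image_peak(x)
  cat(sprintf("DAS intensity image: %d x %d pixels over [%g, %g] x [%g, %g] mm\n",
              x$config$n_x, x$config$n_y, x$config$region[1],
              x$config$region[2], x$config$region[3], x$config$region[4]))
  if (is.null(pk)) cat("  all-zero image\n")
  else cat(sprintf("  peak %.4g at (%.2f, %.2f) mm; %d out-of-span samples\n",
                   max(x$intensity), pk[1], pk[2], x$out_of_span))
  invisible(x)
}

#' @export
summary.cmi_image <- function(object, ...) {
  pk <- image_peak(object)
  structure(list(peak_value = max(object$intensity), peak_xy = pk,
                 pixel_pitch = c(diff(object$x[1:2]),
                                 diff(object$y[1:2])),
                 out_of_span = object$out_of_span),
            class = "summary.cmi_image")
}

#' @export
print.summary.cmi_image <- function(x, ...) {
  cat(sprintf("peak %.4g at (%.2f, %.2f) mm; pixel pitch %.3f x %.3f mm; %d out-of-span\n",
              x$peak_value, x$peak_xy[1], x$peak_xy[2],
              x$pixel_pitch[1], x$pixel_pitch[2], x$out_of_span))
  invisible(x)
}

#' @export
plot.cmi_image <- function(x, normalize = TRUE, ...) {
  z <- x$intensity
  if (normalize && max(z) > 0) z <- z / max(z)
  graphics::image(x$x, x$y, z, xlab = "x (mm)", ylab = "y (mm)",
                  col = grDevices::hcl.colors(64, "inferno"),
                  asp = 1, ...)
  invisible(x)
}

#' Write an image as delimited text / normalized PNG
#'
#' `write_image_tsv()` stores the raw intensity matrix with x/y coordinate
#' headers (first row: y coordinates; first column: x coordinates).
#' `write_image_png()` writes a normalized gray-scale PNG (requires the
#' `png` package).
#'
#' @param image A `cmi_image`.
#' @param path Output file path.
#' @return `path`, invisibly. `read_image_tsv()` returns a `cmi_image`
#'   with a default-derived config.
#' @export
write_image_tsv <- function(image, path) {
  stopifnot(inherits(image, "cmi_image"))
  m <- rbind(c(NA, image$y), cbind(image$x, image$intensity))
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  xs <- m[-1, 1]
  ys <- m[1, -1]
  intensity <- unname(m[-1, -1, drop = FALSE])
  cfg <- imaging_config(n_x = length(xs), n_y = length(ys),
                        region = c(min(xs), max(xs), min(ys), max(ys)))
  structure(list(intensity = intensity, x = xs, y = ys, config = cfg,
                 out_of_span = 0L, provenance = list(source = path)),
            class = "cmi_image")
}

#' @rdname write_image_tsv
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  z <- image$intensity
  if (max(z) > 0) z <- z / max(z)
  # transpose so x runs along image width, y upward
  png::writePNG(t(z)[rev(seq_len(ncol(z))), , drop = FALSE], path)
  invisible(path)
}
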