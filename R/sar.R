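#' Regular 3-D electric-field magnitude grid
#'
#' Voxel lattice (regular, ascending axes, mm) carrying the internal
#' electric-field magnitude |E| in V/m at each voxel. Optionally carries the
#' illuminating source position as provenance (set by
#' [synthesize_field()]), which the tumor detection confidence test uses
#' for range compensation.
#'
#' @param x,y,z Ascending, regularly spaced coordinate vectors, mm.
#' @param magnitude Numeric array, dim `c(length(x), length(y), length(z))`,
#'   values >= 0.
#' @param source_position Optional 3-vector, mm.
#' @return Object of class `field_grid`.
#' @export
field_grid <- function(x, y, z, magnitude, source_position = NULL) {
  for (ax in list(x, y, z)) check_regular_axis(ax)
  magnitude <- as.array(magnitude)
  if (!identical(dim(magnitude), c(length(x), length(y), length(z))))
    stop("magnitude array dim must be (length(x), length(y), length(z))",
         call. = FALSE)
  if (length(magnitude) == 0) stop("empty grid", call. = FALSE)
  if (any(magnitude < 0)) stop("field magnitudes must be >= 0", call. = FALSE)
  structure(list(x = x, y = y, z = z, magnitude = magnitude,
                 source_position = source_position),
            class = "field_grid")
}

check_regular_axis <- function(ax) {
  if (length(ax) < 1L) stop("empty grid axis", call. = FALSE)
  if (length(ax) > 1L) {
    d <- diff(ax)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * abs(d[1]))
      stop("grid axes must be regular and ascending", call. = FALSE)
  }
  invisible(ax)
}

#' Default voxel lattice covering a phantom
#'
#' Bounding box of the hemisphere at a given pitch (default 1 mm, fine
#' enough to resolve a 1 mm radius tumor).
#'
#' @param phantom A `breast_phantom`.
#' @param pitch Voxel pitch, mm.
#' @return List with `x`, `y`, `z` coordinate vectors.
#' @export
default_lattice <- function(phantom, pitch = 1) {
  r <- phantom$breast_radius
  list(x = seq(-r, r, by = pitch), y = seq(-r, r, by = pitch),
       z = seq(0, r, by = pitch))
}

# n x 3 matrix of all voxel coordinates, x varying fastest (lexicographic
# voxel order used for argmax tie-breaking).
grid_coords <- function(g) {
  as.matrix(expand.grid(x = g$x, y = g$y, z = g$z, KEEP.OUT.ATTRS = FALSE))
}

#' Synthesize a stand-in illumination field
#'
#' Deterministic surrogate for a solved electromagnetic field: a spherical
#' 1/d incident-field decay from the source, with the magnitude inside
#' tumor spheres multiplied by a dielectric-contrast enhancement that
#' peaks at the tumor center and falls off quadratically to 1 at the
#' tumor surface (the internal field of a high-contrast dielectric sphere
#' concentrates centrally). This emulates the empirical observation that
#' malignant inclusions absorb markedly more energy than the surrounding
#' tissue, so that the SAR maximum falls inside the tumor, essentially at
#' its center, under the default contrast.
#'
#' @param phantom A `breast_phantom`.
#' @param source_position Source (antenna) location, 3-vector mm; must be
#'   in air.
#' @param e0 Field magnitude at the reference distance, V/m. Default 1.
#' @param reference_distance Distance at which |E| = e0, mm. Default 10
#'   (the nominal antenna standoff).
#' @param tumor_contrast Multiplicative |E| enhancement inside tumors.
#'   Default 8.
#' @param lattice Voxel lattice as from [default_lattice()]; default is
#'   the phantom's 1 mm lattice.
#' @return A `field_grid` with `source_position` recorded.
#' @export
synthesize_field <- function(phantom, source_position, e0 = 1,
                             reference_distance = 10, tumor_contrast = 8,
                             lattice = default_lattice(phantom)) {
  src <- as.numeric(source_position)
  if (phantom_contains(phantom, src) != "air")
    stop("field source must be outside the phantom", call. = FALSE)
  pts <- grid_coords(lattice)
  d <- sqrt((pts[, 1] - src[1])^2 + (pts[, 2] - src[2])^2 +
            (pts[, 3] - src[3])^2)
  d <- pmax(d, reference_distance / 100)  # guard against singularity
  mag <- e0 * reference_distance / d
  lab <- phantom_contains(phantom, pts)
  for (i in seq_along(phantom$tumors)) {
    tum <- phantom$tumors[[i]]
    inside <- lab == paste0("tumor", i)
    rr <- sqrt((pts[inside, 1] - tum$center[1])^2 +
               (pts[inside, 2] - tum$center[2])^2 +
               (pts[inside, 3] - tum$center[3])^2) / tum$radius
    mag[inside] <- mag[inside] * (1 + (tumor_contrast - 1) * (1 - rr^2))
  }
  field_grid(lattice$x, lattice$y, lattice$z,
             array(mag, dim = c(length(lattice$x), length(lattice$y),
                                length(lattice$z))),
             source_position = src)
}

#' Specific absorption rate from a field grid
#'
#' Per voxel, SAR = sigma |E|^2 / rho (W/kg), with conductivity and density
#' taken from the phantom tissue at that voxel; air voxels get SAR 0.
#'
#' @param field A `field_grid`.
#' @param phantom A `breast_phantom`.
#' @return Object of class `sar_map` (same lattice, `sar` array in W/kg).
#' @examples
#' # sigma = 1.2 S/m, E = 100 V/m, rho = 1000 kg/m^3  ->  12 W/kg
#' @export
sar_from_field <- function(field, phantom) {
  stopifnot(inherits(field, "field_grid"),
            inherits(phantom, "breast_phantom"))
  pts <- grid_coords(field)
  lab <- phantom_contains(phantom, pts)
  tis <- tissue_lookup(phantom, lab)
  sar <- as.numeric(field$magnitude)^2 * tis$conductivity / tis$density
  sar[lab == "air"] <- 0
  if (!any(lab != "air"))
    stop("grid does not overlap the phantom", call. = FALSE)
  structure(list(x = field$x, y = field$y, z = field$z,
                 sar = array(sar, dim = dim(field$magnitude)),
                 source_position = field$source_position),
            class = "sar_map")
}

#' @export
print.sar_map <- function(x, ...) {
  cat(sprintf("SAR map: %d x %d x %d voxels, max %.4g W/kg\n",
              length(x$x), length(x$y), length(x$z), max(x$sar)))
  invisible(x)
}

#' Locate the tumor as the SAR maximum
#'
#' Returns the coordinates and value of the global SAR maximum (ties broken
#' by lexicographic voxel order: x varying fastest, then y, then z), plus a
#' detection confidence. Confidence is the ratio of the peak to the largest
#' value outside an exclusion ball around the peak; when the map records
#' the illuminating source position, both values are first range-compensated
#' (multiplied by squared distance to the source) so the smooth incident
#' 1/d^2 falloff does not masquerade as a localized absorber. A confident
#' detection requires `peak_ratio >= threshold`.
#'
#' @param sar A `sar_map`.
#' @param threshold Minimum peak ratio to declare detection. Default 2.
#' @param exclusion_radius Radius (mm) of the ball around the peak excluded
#'   from the background maximum. Default 10 (twice the design tumor
#'   radius).
#' @return Object of class `tumor_estimate`: list with `position` (mm),
#'   `max_value` (W/kg), `detected` (logical), `peak_ratio`. An all-zero
#'   map yields `detected = FALSE` and `position = NULL` (a "no detection"
#'   signal rather than a position).
#' @export
locate_tumor <- function(sar, threshold = 2, exclusion_radius = 10) {
  stopifnot(inherits(sar, "sar_map"))
  if (length(sar$sar) == 0) stop("empty SAR map", call. = FALSE)
  if (all(sar$sar == 0))
    return(structure(list(position = NULL, max_value = 0, detected = FALSE,
                          peak_ratio = NA_real_, threshold = threshold),
                     class = "tumor_estimate"))
  idx <- which.max(sar$sar)  # first maximum in lexicographic voxel order
  pts <- grid_coords(sar)
  peak <- pts[idx, ]
  vals <- as.numeric(sar$sar)
  if (!is.null(sar$source_position)) {
    src <- sar$source_position
    d2 <- (pts[, 1] - src[1])^2 + (pts[, 2] - src[2])^2 +
      (pts[, 3] - src[3])^2
    comp <- vals * d2
  } else comp <- vals
  dist_peak2 <- (pts[, 1] - peak[1])^2 + (pts[, 2] - peak[2])^2 +
    (pts[, 3] - peak[3])^2
  outside <- dist_peak2 > exclusion_radius^2 & vals > 0
  bg <- if (any(outside)) max(comp[outside]) else 0
  ratio <- if (bg > 0) comp[idx] / bg else Inf
  structure(list(position = as.numeric(peak), max_value = vals[idx],
                 detected = ratio >= threshold, peak_ratio = ratio,
                 threshold = threshold),
            class = "tumor_estimate")
}

#' @export
print.tumor_estimate <- function(x, ...) {
  if (is.null(x$position)) {
    cat("Tumor estimate: no detection (all-zero SAR map)\n")
  } else {
    cat(sprintf(
      "Tumor estimate: (%.2f, %.2f, %.2f) mm, SAR max %.4g W/kg, peak ratio %.2f -> %s\n",
      x$position[1], x$position[2], x$position[3], x$max_value,
      x$peak_ratio, if (x$detected) "detected" else "not confident"))
  }
  invisible(x)
}

# Rodrigues rotation of vector v about unit axis k by angle a (radians).
rotate_about <- function(v, k, a) {
  k <- k / sqrt(sum(k^2))
  v * cos(a) + cross3(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal basis (e1, e2) perpendicular to unit vector u.
perp_basis <- function(u) {
  a <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) c(1, 0, 0)
       else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- cross3(u, a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

#' Plan a reduced aperture around a tumor estimate
#'
#' Places `rows x cols` antenna positions on the sphere of radius
#' `breast_radius + standoff` centered on the origin, in an angular grid
#' around the radial direction through the tumor estimate. Rows are arcs of
#' their own great circles: row offsets step by `angular_step` along one
#' great circle through the estimate direction, and each row is then swept
#' by `angular_step` increments along the great circle perpendicular to it,
#' so consecutive positions along a row are separated by exactly
#' `angular_step` (the scan trajectory reading of the angular separation;
#' across-row neighbour separations match it to within a few percent for
#' off-center rows, exactly on the central column). All boresights point at
#' the tumor estimate.
#'
#' With `mode = "arc"`, all `rows * cols` positions lie along one great
#' circle arc through the estimate with `angular_step` spacing (a 9-antenna
#' arc spans 80 degrees), the alternative single-trajectory reading.
#'
#' @param tumor_estimate 3-vector mm (inside the phantom) or a
#'   `tumor_estimate` object.
#' @param phantom A `breast_phantom`.
#' @param standoff Antenna standoff from the skin surface, mm. Default 10.
#' @param rows,cols Grid shape. Defaults 3 x 3.
#' @param angular_step Angular separation between neighbouring positions,
#'   degrees. Default 10.
#' @param mode `"grid"` (default) or `"arc"`.
#' @return A `scan_geometry`.
#' @export
plan_aperture <- function(tumor_estimate, phantom, standoff = 10,
                          rows = 3, cols = 3, angular_step = 10,
                          mode = c("grid", "arc")) {
  mode <- match.arg(mode)
  if (inherits(tumor_estimate, "tumor_estimate")) {
    if (is.null(tumor_estimate$position))
      stop("no detection: tumor estimate carries no position", call. = FALSE)
    tumor_estimate <- tumor_estimate$position
  }
  est <- as.numeric(tumor_estimate)
  if (sqrt(sum(est^2)) < 1e-9)
    stop("tumor estimate at the origin: radial direction undefined",
         call. = FALSE)
  if (phantom_contains(phantom, est) == "air")
    stop("tumor estimate must lie inside the phantom", call. = FALSE)
  u <- est / sqrt(sum(est^2))
  basis <- perp_basis(u)
  radius <- phantom$breast_radius + standoff
  s <- angular_step * pi / 180
  if (mode == "arc") {
    n <- rows * cols
    offs <- (seq_len(n) - (n + 1) / 2) * s
    dirs <- t(vapply(offs, function(a) rotate_about(u, basis$e1, a),
                     numeric(3)))
  } else {
    row_off <- (seq_len(rows) - (rows + 1) / 2) * s
    col_off <- (seq_len(cols) - (cols + 1) / 2) * s
    dirs <- matrix(NA_real_, rows * cols, 3)
    k <- 1L
    for (i in seq_len(rows)) {
      v <- rotate_about(u, basis$e1, row_off[i])     # row anchor
      axis <- rotate_about(basis$e2, basis$e1, row_off[i])  # sweep axis
      for (j in seq_len(cols)) {
        dirs[k, ] <- rotate_about(v, axis, col_off[j])
        k <- k + 1L
      }
    }
  }
  positions <- dirs * radius
  boresights <- matrix(rep(est, each = nrow(positions)),
                       ncol = 3) - positions
  scan_geometry(positions, grid_rows = rows, grid_cols = cols,
                standoff = standoff, boresights = boresights)
}

#' Plan a conventional full-ring scan
#'
#' Uniformly spaced monostatic positions on a horizontal ring (the
#' conventional 360-degree scan baseline; 36 positions give 10-degree
#' spacing). All positions lie at `breast_radius + standoff` from the
#' origin, in the plane `z = plane_height`; boresights point horizontally
#' at the central axis. Logical grid shape is 1 x n.
#'
#' @param phantom A `breast_phantom`.
#' @param n_positions Number of positions, >= 3. Default 36.
#' @param standoff Standoff from the skin surface, mm. Default 10.
#' @param plane_height Ring plane z, mm. Default 0. Must be smaller in
#'   magnitude than the ring radius.
#' @return A `scan_geometry` with `grid_rows = 1`.
#' @export
plan_full_ring <- function(phantom, n_positions = 36, standoff = 10,
                           plane_height = 0) {
  if (n_positions < 3) stop("need at least 3 ring positions", call. = FALSE)
  radius <- phantom$breast_radius + standoff
  if (abs(plane_height) >= radius)
    stop("plane_height must be below the scan radius", call. = FALSE)
  rho <- sqrt(radius^2 - plane_height^2)
  phi <- 2 * pi * (seq_len(n_positions) - 1) / n_positions
  positions <- cbind(rho * cos(phi), rho * sin(phi),
                     rep(plane_height, n_positions))
  boresights <- cbind(-cos(phi), -sin(phi), rep(0, n_positions))
  scan_geometry(positions, grid_rows = 1L, grid_cols = n_positions,
                standoff = standoff, boresights = boresights)
}

#' Write a tumor estimate to JSON
#'
#' Emits `{x_mm, y_mm, z_mm, sar_w_per_kg, detected, peak_ratio}`.
#'
#' @param estimate A `tumor_estimate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tumor_estimate <- function(estimate, path) {
  stopifnot(inherits(estimate, "tumor_estimate"))
  obj <- if (is.null(estimate$position)) {
    list(detected = FALSE)
  } else {
    list(x_mm = estimate$position[1], y_mm = estimate$position[2],
         z_mm = estimate$position[3], sar_w_per_kg = estimate$max_value,
         detected = estimate$detected, peak_ratio = estimate$peak_ratio)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
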