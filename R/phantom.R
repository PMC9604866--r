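#' Tissue dielectric properties
#'
#' Bundle of the three material constants that govern microwave propagation
#' and absorption in a tissue: relative permittivity \eqn{\epsilon_r}
#' (dimensionless), conductivity \eqn{\sigma} (S/m) and mass density
#' \eqn{\rho} (kg/m^3). Density defaults to 1000 kg/m^3 (soft tissue is close
#' to water); SAR-maximum localization is invariant to a common density
#' scale, so only relative densities matter.
#'
#' @param permittivity Relative permittivity, > 0.
#' @param conductivity Conductivity in S/m, > 0.
#' @param density Mass density in kg/m^3, > 0. Default 1000.
#' @return An object of class `tissue_properties`.
#' @examples
#' tissue_properties(50, 1.2)   # malignant tissue
#' @export
tissue_properties <- function(permittivity, conductivity, density = 1000) {
  for (v in c(permittivity = permittivity, conductivity = conductivity,
              density = density)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tissue properties must be single strictly positive numbers",
           call. = FALSE)
  }
  structure(list(permittivity = permittivity, conductivity = conductivity,
                 density = density),
            class = "tissue_properties")
}

#' Default tissue set
#'
#' Skin: eps_r = 37, sigma = 1.1 S/m. Tumor: eps_r = 50, sigma = 1.2 S/m.
#' The normal breast interior is modelled as adipose-dominated tissue with
#' eps_r = 9, sigma = 0.4 S/m (typical literature values); all are
#' overridable when constructing a phantom.
#'
#' @return Named list with elements `skin`, `interior`, `tumor`.
#' @export
default_tissues <- function() {
  list(skin     = tissue_properties(37, 1.1),
       interior = tissue_properties(9, 0.4),
       tumor    = tissue_properties(50, 1.2))
}

#' Spherical tumor inclusion
#'
#' @param center Numeric length-3, tumor center in mm (phantom frame:
#'   origin at the hemisphere base center, hemisphere in z >= 0).
#' @param radius Tumor radius in mm, > 0.
#' @param tissue `tissue_properties` of the tumor (default: malignant,
#'   eps_r = 50, sigma = 1.2).
#' @return Object of class `tumor_sphere`.
#' @export
tumor_sphere <- function(center, radius, tissue = default_tissues()$tumor) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("tumor center must be a finite 3-vector (mm)", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("tumor radius must be a single positive number (mm)", call. = FALSE)
  stopifnot(inherits(tissue, "tissue_properties"))
  structure(list(center = center, radius = radius, tissue = tissue),
            class = "tumor_sphere")
}

#' Hemispherical breast phantom
#'
#' A 50 mm radius hemisphere with a 2 mm skin shell, the classic desk-scale
#' breast model for confocal microwave imaging studies. The coordinate frame
#' is right-handed, in millimetres, with the origin at the center of the
#' hemisphere base and the hemisphere occupying z >= 0; antennas approach
#' from outside the curved surface. The skin shell is the region between
#' radius `breast_radius - skin_thickness` and `breast_radius`.
#'
#' Each tumor must satisfy the geometry invariants: positive radius, center
#' in the z >= 0 half-space, and `|center| + radius <= breast_radius -
#' skin_thickness` so the sphere lies fully in the interior.
#'
#' @param breast_radius Outer hemisphere radius, mm. Default 50.
#' @param skin_thickness Skin shell thickness, mm. Default 2.
#' @param skin,interior `tissue_properties` of the skin shell and the
#'   normal interior.
#' @param tumors List of [tumor_sphere()] objects (possibly empty).
#' @return Object of class `breast_phantom`.
#' @seealso [make_default_phantom()], [phantom_contains()]
#' @export
breast_phantom <- function(breast_radius = 50, skin_thickness = 2,
                           skin = default_tissues()$skin,
                           interior = default_tissues()$interior,
                           tumors = list()) {
  if (!(breast_radius > skin_thickness && skin_thickness > 0))
    stop("geometry error: need breast_radius > skin_thickness > 0",
         call. = FALSE)
  stopifnot(inherits(skin, "tissue_properties"),
            inherits(interior, "tissue_properties"))
  if (inherits(tumors, "tumor_sphere")) tumors <- list(tumors)
  ph <- structure(list(breast_radius = breast_radius,
                       skin_thickness = skin_thickness,
                       skin = skin, interior = interior,
                       tumors = tumors),
                  class = "breast_phantom")
  for (i in seq_along(tumors)) {
    tum <- tumors[[i]]
    if (!inherits(tum, "tumor_sphere"))
      stop("tumors must be tumor_sphere objects", call. = FALSE)
    d <- sqrt(sum(tum$center^2))
    if (tum$center[3] < 0)
      stop(sprintf(
        "geometry error: tumor %d center z = %.2f mm lies below the hemisphere base (z >= 0 required)",
        i, tum$center[3]), call. = FALSE)
    if (d + tum$radius > breast_radius - skin_thickness)
      stop(sprintf(
        "geometry error: tumor %d (|center| = %.2f mm + radius %.2f mm) extends beyond the interior radius %.2f mm",
        i, d, tum$radius, breast_radius - skin_thickness), call. = FALSE)
  }
  ph
}

#' Default single-tumor phantom
#'
#' The standard study phantom: 50 mm hemisphere, 2 mm skin, one spherical
#' tumor. The default tumor center (20, -13, 14) mm is an off-center,
#' mid-depth placement in the upper-outer region of the model.
#'
#' @param tumor_center 3-vector, mm. Default `c(20, -13, 14)`.
#' @param tumor_radius mm, default 5 (the Stage-1 limiting size).
#' @param tumor_tissue `tissue_properties`, default eps_r = 50, sigma = 1.2.
#' @param interior,skin Optional tissue overrides.
#' @return A `breast_phantom` with one tumor.
#' @examples
#' ph <- make_default_phantom()
#' phantom_contains(ph, c(20, -13, 14))  # "tumor1"
#' @export
make_default_phantom <- function(tumor_center = c(20, -13, 14),
                                 tumor_radius = 5,
                                 tumor_tissue = default_tissues()$tumor,
                                 interior = default_tissues()$interior,
                                 skin = default_tissues()$skin) {
  breast_phantom(
    breast_radius = 50, skin_thickness = 2,
    skin = skin, interior = interior,
    tumors = list(tumor_sphere(tumor_center, tumor_radius, tumor_tissue)))
}

#' Classify points by phantom region
#'
#' Partitions space into `"air"`, `"skin"`, `"interior"` and `"tumor<i>"`
#' labels. A point inside a tumor sphere is labelled by that tumor's index
#' (`"tumor1"`, ...), taking precedence over `"interior"`; overlapping
#' tumors resolve to the lowest index. Boundaries are closed towards the
#' denser label (a point at exactly the outer radius is skin, at exactly a
#' tumor radius is tumor).
#'
#' @param phantom A `breast_phantom`.
#' @param points Numeric 3-vector, or an n x 3 matrix of points (mm).
#' @return Character vector of labels, one per point.
#' @export
phantom_contains <- function(phantom, points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3,
                                                  byrow = TRUE)
  if (ncol(pts) != 3L) stop("points must be 3-vectors (mm)", call. = FALSE)
  r <- sqrt(rowSums(pts^2))
  lab <- rep("air", nrow(pts))
  inside <- pts[, 3] >= 0 & r <= phantom$breast_radius
  skin_in <- phantom$breast_radius - phantom$skin_thickness
  lab[inside & r > skin_in] <- "skin"
  lab[inside & r <= skin_in] <- "interior"
  for (i in seq_along(phantom$tumors)) {
    tum <- phantom$tumors[[i]]
    dt <- sqrt((pts[, 1] - tum$center[1])^2 +
               (pts[, 2] - tum$center[2])^2 +
               (pts[, 3] - tum$center[3])^2)
    hit <- dt <= tum$radius & lab == "interior"
    lab[hit] <- paste0("tumor", i)
  }
  lab
}

# Per-point (sigma, rho) lookup used by SAR computation; air gets NA.
tissue_lookup <- function(phantom, labels) {
  sig <- rho <- rep(NA_real_, length(labels))
  set <- function(which, tis) {
    sig[which] <<- tis$conductivity
    rho[which] <<- tis$density
  }
  set(labels == "skin", phantom$skin)
  set(labels == "interior", phantom$interior)
  for (i in seq_along(phantom$tumors))
    set(labels == paste0("tumor", i), phantom$tumors[[i]]$tissue)
  list(conductivity = sig, density = rho)
}

#' @export
print.breast_phantom <- function(x, ...) {
  cat(sprintf("Hemispherical breast phantom: radius %.1f mm, skin %.1f mm\n",
              x$breast_radius, x$skin_thickness))
  cat(sprintf("  skin:     eps_r = %.2f, sigma = %.2f S/m\n",
              x$skin$permittivity, x$skin$conductivity))
  cat(sprintf("  interior: eps_r = %.2f, sigma = %.2f S/m\n",
              x$interior$permittivity, x$interior$conductivity))
  if (length(x$tumors) == 0) cat("  tumors:   none\n")
  for (i in seq_along(x$tumors)) {
    tum <- x$tumors[[i]]
    cat(sprintf(
      "  tumor %d:  center (%.1f, %.1f, %.1f) mm, radius %.1f mm, eps_r = %.2f, sigma = %.2f S/m\n",
      i, tum$center[1], tum$center[2], tum$center[3], tum$radius,
      tum$tissue$permittivity, tum$tissue$conductivity))
  }
  invisible(x)
}

#' Read / write a phantom configuration file
#'
#' Phantoms serialize to a small YAML or JSON document with keys
#' `breast_radius_mm`, `skin_thickness_mm`, per-tissue
#' `{permittivity, conductivity, density}` blocks and a `tumors` list of
#' `{center_mm, radius_mm, permittivity, conductivity, density}` entries.
#' Format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param phantom A `breast_phantom`.
#' @param path File path.
#' @return `read_phantom_config()` returns a `breast_phantom`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
write_phantom_config <- function(phantom, path) {
  tis <- function(t) list(permittivity = t$permittivity,
                          conductivity = t$conductivity,
                          density = t$density)
  obj <- list(
    breast_radius_mm = phantom$breast_radius,
    skin_thickness_mm = phantom$skin_thickness,
    skin = tis(phantom$skin), interior = tis(phantom$interior),
    tumors = lapply(phantom$tumors, function(tum)
      c(list(center_mm = tum$center, radius_mm = tum$radius),
        tis(tum$tissue))))
  write_config_file(obj, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  obj <- read_config_file(path)
  need <- c("breast_radius_mm", "skin_thickness_mm", "skin", "interior")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("phantom config missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tis <- function(t) tissue_properties(t$permittivity, t$conductivity,
                                       t$density %||% 1000)
  tumors <- lapply(obj$tumors %||% list(), function(tum)
    tumor_sphere(unlist(tum$center_mm), tum$radius_mm,
                 tissue_properties(tum$permittivity, tum$conductivity,
                                   tum$density %||% 1000)))
  breast_phantom(obj$breast_radius_mm, obj$skin_thickness_mm,
                 skin = tis(obj$skin), interior = tis(obj$interior),
                 tumors = tumors)
}

# Small shared helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

write_config_file <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("config files must be .yaml/.yml or .json", call. = FALSE)
  invisible(path)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                              simplifyDataFrame = FALSE)
  else stop("config files must be .yaml/.yml or .json", call. = FALSE)
}
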