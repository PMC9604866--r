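test_that("SAR arithmetic: sigma E^2 / rho per voxel, zero in air", {
  ph <- make_default_phantom()
  lat <- list(x = c(20, 40, 60), y = c(-13, 7), z = c(14, 34))
  mag <- array(100, dim = c(3, 2, 2))
  f <- field_grid(lat$x, lat$y, lat$z, mag)
  sm <- sar_from_field(f, ph)
  # tumor voxel (20, -13, 14): sigma 1.2, E = 100, rho 1000 -> 12 W/kg
  expect_equal(sm$sar[1, 1, 1], 12)
  # interior voxel (40, -13, 14): sigma 0.4 -> 4 W/kg
  expect_equal(sm$sar[2, 1, 1], 4)
  # air voxel (60, ...) -> 0
  expect_equal(sm$sar[3, 1, 1], 0)
  # uniform field: SAR ratio equals sigma/rho ratio
  expect_equal(sm$sar[1, 1, 1] / sm$sar[2, 1, 1], (1.2 / 1000) / (0.4 / 1000))
})

test_that("SAR is homogeneous of degree 2 in the field", {
  ph <- make_default_phantom()
  f1 <- synthesize_field(ph, c(0, 0, 60),
                         lattice = default_lattice(ph, 4))
  f3 <- f1; f3$magnitude <- 3 * f3$magnitude
  s1 <- sar_from_field(f1, ph); s3 <- sar_from_field(f3, ph)
  expect_equal(s3$sar, 9 * s1$sar, tolerance = 1e-12)
  # zero field -> all-zero map
  f0 <- f1; f0$magnitude[] <- 0
  expect_true(all(sar_from_field(f0, ph)$sar == 0))
})

test_that("superposed fields never reduce SAR anywhere", {
  ph <- make_default_phantom()
  lat <- default_lattice(ph, 5)
  fa <- synthesize_field(ph, c(0, 0, 60), lattice = lat)
  fb <- synthesize_field(ph, c(55, 0, 20), lattice = lat)
  fsum <- fa; fsum$magnitude <- fa$magnitude + fb$magnitude
  ssum <- sar_from_field(fsum, ph)$sar
  expect_true(all(ssum >= sar_from_field(fa, ph)$sar - 1e-15))
  expect_true(all(ssum >= sar_from_field(fb, ph)$sar - 1e-15))
})

test_that("locate_tumor returns the unique maximum and documented ties", {
  lat <- list(x = 0:3, y = 0:2, z = 0:2)
  sar <- array(0, dim = c(4, 3, 3))
  sar[3, 2, 1] <- 5
  sm <- structure(c(lat, list(sar = sar, source_position = NULL)),
                  class = "sar_map")
  est <- locate_tumor(sm)
  expect_equal(est$position, c(2, 1, 0))
  expect_equal(est$max_value, 5)
  # constant map: first voxel in lexicographic order (x fastest)
  smc <- sm; smc$sar <- array(1, dim = dim(sar))
  expect_equal(locate_tumor(smc)$position, c(0, 0, 0))
  # all-zero map: a no-detection signal, not a position
  smz <- sm; smz$sar <- array(0, dim = dim(sar))
  est0 <- locate_tumor(smz)
  expect_false(est0$detected)
  expect_null(est0$position)
})

test_that("SAR argmax recovers tumors of radius 1, 3 and 5 mm", {
  for (r in c(1, 3, 5)) {
    ph <- make_default_phantom(tumor_radius = r)
    est <- locate_tumor(sar_from_field(
      synthesize_field(ph, c(0, 0, 60)), ph))
    expect_true(est$detected)
    d <- sqrt(sum((est$position - ph$tumors[[1]]$center)^2))
    expect_lte(d, r)  # exhaustive grid scan lands inside the sphere
  }
})

test_that("a healthy phantom yields no confident detection", {
  ph0 <- breast_phantom()
  est <- locate_tumor(sar_from_field(synthesize_field(ph0, c(0, 0, 60)),
                                     ph0))
  expect_false(est$detected)
  expect_lt(est$peak_ratio, 2)
})

test_that("aperture planning places the grid around the estimate", {
  ph <- make_default_phantom(tumor_center = c(0, 0, 25))
  geo <- plan_aperture(c(0, 0, 25), ph)
  expect_equal(nrow(geo$positions), 9)
  expect_equal(sqrt(rowSums(geo$positions^2)), rep(60, 9),
               tolerance = 1e-12)                     # 50 + 10 mm
  expect_equal(geo$positions[5, ], c(x = 0, y = 0, z = 60),
               tolerance = 1e-9)                      # central on +z
  expect_true(all(phantom_contains(ph, geo$positions) == "air"))
  # single position: along the radial ray through the estimate
  g1 <- plan_aperture(c(10, 5, 20), ph, rows = 1, cols = 1)
  u <- c(10, 5, 20) / sqrt(sum(c(10, 5, 20)^2))
  expect_equal(as.numeric(g1$positions[1, ]), 60 * u, tolerance = 1e-9)
  expect_error(plan_aperture(c(0, 0, 0), ph), "origin")
  expect_error(plan_aperture(c(0, 0, 70), ph), "inside the phantom")
})

test_that("within-row angular separations equal the configured step", {
  ph <- make_default_phantom()
  sep <- function(a, b) {
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  }
  for (est in list(c(20, -13, 14), c(0, 0, 25), c(-10, 22, 8))) {
    geo <- plan_aperture(est, ph)
    p <- geo$positions
    for (row in 0:2) for (j in 1:2)
      expect_equal(sep(p[row * 3 + j, ], p[row * 3 + j + 1, ]), 10,
                   tolerance = 1e-6)
    # central-column across-row separations are exact too
    expect_equal(sep(p[2, ], p[5, ]), 10, tolerance = 1e-6)
    expect_equal(sep(p[5, ], p[8, ]), 10, tolerance = 1e-6)
    # boresights point at the estimate
    to_est <- sweep(-p, 2, -est)
    cosang <- rowSums(to_est * geo$boresights) /
      sqrt(rowSums(to_est^2))
    expect_equal(cosang, rep(1, 9), tolerance = 1e-9)
  }
})

test_that("arc layout spaces all positions along one trajectory", {
  ph <- make_default_phantom()
  geo <- plan_aperture(c(20, -13, 14), ph, rows = 3, cols = 3,
                       mode = "arc")
  p <- geo$positions
  sep <- function(a, b) acos(sum(a * b) / 3600) * 180 / pi
  for (j in 1:8) expect_equal(sep(p[j, ], p[j + 1, ]), 10,
                              tolerance = 1e-6)
  # 9 positions at 10 degrees span 80 degrees end to end
  expect_equal(sep(p[1, ], p[9, ]), 80, tolerance = 1e-6)
})

test_that("full-ring planning gives uniform azimuth spacing", {
  ph <- make_default_phantom()
  g36 <- plan_full_ring(ph, 36)
  expect_equal(nrow(g36$positions), 36)
  az <- atan2(g36$positions[, 2], g36$positions[, 1]) * 180 / pi
  expect_equal(diff(az[1:18]), rep(10, 17), tolerance = 1e-9)
  g4 <- plan_full_ring(ph, 4)
  az4 <- atan2(g4$positions[, 2], g4$positions[, 1]) * 180 / pi
  expect_equal(diff(az4[1:2]), 90, tolerance = 1e-9)
  # equal distance from the z-axis, all in air
  expect_equal(sqrt(rowSums(g36$positions[, 1:2]^2)),
               rep(60, 36), tolerance = 1e-9)
  expect_true(all(phantom_contains(ph, g36$positions) == "air"))
})

test_that("tumor estimates serialize to JSON", {
  ph <- make_default_phantom()
  est <- locate_tumor(sar_from_field(
    synthesize_field(ph, c(0, 0, 60),
                     lattice = default_lattice(ph, 2)), ph))
  path <- withr::local_tempfile(fileext = ".json")
  write_tumor_estimate(est, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(c(back$x_mm, back$y_mm, back$z_mm), est$position)
  expect_true(back$detected)
})
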