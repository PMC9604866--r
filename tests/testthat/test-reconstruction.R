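test_that("calibration subtracts the baseline per position", {
  pair <- simulated_pair()
  self <- calibrate(pair$tb, pair$tb)
  expect_true(all(self$signals == 0))             # TB - TB
  zero <- scan_record(pair$tb$geometry, pair$tb$time_axis,
                      matrix(0, nrow(pair$tb$signals),
                             ncol(pair$tb$signals)),
                      label = "tumor_free")
  expect_equal(calibrate(pair$tb, zero)$signals, pair$tb$signals)  # B = 0
  # mismatched time axes rejected
  other <- simulate_scan(make_default_phantom(), pair$tb$geometry,
                         quick_pulse(), forward_model_params(),
                         time_axis = default_time_axis(256))
  expect_error(calibrate(pair$tb, other), "time axis")
})

test_that("row-average clutter removal reproduces the worked example", {
  geo <- scan_geometry(cbind(c(-10, 0, 10), 0, 70), 1, 3)
  taxis <- default_time_axis(8)
  sig <- rbind(rep(1, 8), rep(2, 8), rep(3, 8))
  rec <- scan_record(geo, taxis, sig, label = "calibrated")
  out <- remove_clutter(rec)
  expect_equal(out$signals, rbind(rep(-1, 8), rep(0, 8), rep(1, 8)))
  expect_equal(out$label, "processed")
  # identical signals in a row vanish
  same <- scan_record(geo, taxis, rbind(sig[1, ], sig[1, ], sig[1, ]),
                      label = "calibrated")
  expect_true(all(remove_clutter(same)$signals == 0))
})

test_that("clutter-removed signals sum to zero within each row", {
  set.seed(5)
  geo <- scan_geometry(cbind(runif(9, 55, 70), runif(9, -20, 20),
                             runif(9, 30, 60)), 3, 3)
  sig <- matrix(rnorm(9 * 64), 9)
  rec <- scan_record(geo, default_time_axis(64), sig, label = "calibrated")
  p <- remove_clutter(rec)$signals
  for (row in 0:2) {
    s <- colSums(p[row * 3 + 1:3, ])
    expect_lt(max(abs(s)), 1e-12 * max(abs(sig)))
  }
})

test_that("single-column rows annihilate with a warning", {
  geo <- scan_geometry(cbind(0, 0, c(60, 70, 80)), 3, 1)
  rec <- scan_record(geo, default_time_axis(16), matrix(rnorm(48), 3),
                     label = "calibrated")
  expect_warning(out <- remove_clutter(rec), "annihilates")
  expect_true(all(out$signals == 0))
})

test_that("focusing distance matches scalar hand computations", {
  expect_equal(focusing_distance(c(0, 0), c(0, 0), 10), 20)     # 2h
  expect_equal(focusing_distance(c(30, 40), c(0, 0), 0), 100)   # 3-4-5
  set.seed(13)
  for (k in 1:100) {
    a <- runif(2, -50, 50); px <- runif(2, -50, 50); h <- runif(1, 0, 40)
    manual <- 2 * sqrt((a[1] - px[1])^2 + (a[2] - px[2])^2 + h^2)
    expect_equal(focusing_distance(a, px, h), manual, tolerance = 1e-12)
  }
})

test_that("round-trip time follows D sqrt(eps)/c with a literal variant", {
  expect_equal(round_trip_time(0, 37), 0)
  expect_equal(round_trip_time(20, 1), 6.671e-11, tolerance = 1e-4)
  expect_equal(round_trip_time(20, 37), 0.020 * sqrt(37) / 2.9979e8,
               tolerance = 1e-12)
  expect_equal(round_trip_time(20, 37), 4.058e-10, tolerance = 1e-4)
  expect_equal(round_trip_time(20, 37, "literal"), 0.020 * 37 / 2.9979e8,
               tolerance = 1e-12)
})

test_that("an impulse at a pixel's delay contributes its squared value", {
  geo <- scan_geometry(matrix(c(0, 0, 10), 1), 1, 1)
  cfg <- imaging_config(n_x = 3, n_y = 3, region = c(-1, 1, -1, 1),
                        medium_permittivity = 1,
                        interpolation = "nearest")
  # pixel (0,0): D = 20 mm, eps 1 -> t = 6.671e-11 s
  t_hit <- round_trip_time(20, 1)
  taxis <- seq(0, 63, by = 1) * (t_hit / 20)     # delay lands on sample 21
  sig <- matrix(0, 1, 64); sig[1, 21] <- 2
  rec <- scan_record(geo, taxis, sig, label = "processed")
  img <- form_image(rec, cfg)
  expect_equal(img$intensity[2, 2], 4)            # central pixel, 2^2
  # all-zero signals give an all-zero image
  rec0 <- scan_record(geo, taxis, matrix(0, 1, 64), label = "processed")
  expect_true(all(form_image(rec0, cfg)$intensity == 0))
})

test_that("image intensity is homogeneous of degree q in the signals", {
  pair <- simulated_pair(params = clean_forward())
  proc <- remove_clutter(calibrate(pair$tb, pair$b))
  cfg <- small_config(time_offset = quick_pulse()$time_shift,
                      detection = "envelope", plane_z = 14,
                      medium_permittivity = 6.6)
  i1 <- form_image(proc, cfg)
  proc3 <- proc; proc3$signals <- 3 * proc3$signals
  i3 <- form_image(proc3, cfg)
  expect_equal(i3$intensity, 9 * i1$intensity, tolerance = 1e-10)
  q4 <- form_image(proc3, small_config(intensity_exponent = 4,
                                       time_offset = cfg$time_offset,
                                       detection = "envelope",
                                       plane_z = 14,
                                       medium_permittivity = 6.6))
  expect_true(all(q4$intensity >= 0))
})

test_that("permuting antennas within rows leaves the image unchanged", {
  pair <- simulated_pair(params = clean_forward())
  cfg <- small_config(time_offset = quick_pulse()$time_shift,
                      detection = "envelope", plane_z = 14,
                      medium_permittivity = 6.6)
  base <- reconstruct(pair$tb, pair$b, cfg)
  perm <- c(3, 1, 2, 5, 6, 4, 9, 8, 7)   # permute columns within each row
  shuffle <- function(rec) {
    geo <- rec$geometry
    g2 <- scan_geometry(geo$positions[perm, ], geo$grid_rows,
                        geo$grid_cols, geo$standoff,
                        geo$boresights[perm, ])
    scan_record(g2, rec$time_axis, rec$signals[perm, ], label = rec$label,
                meta = rec$meta)
  }
  permuted <- reconstruct(shuffle(pair$tb), shuffle(pair$b), cfg)
  expect_equal(permuted$intensity, base$intensity, tolerance = 1e-12)
})

test_that("a tumor-free record pair reconstructs to a near-zero image", {
  ph0 <- breast_phantom()
  geo <- plan_aperture(c(0, 0, 25), ph0)
  tb <- simulate_scan(ph0, geo, quick_pulse(), clean_forward())
  b <- simulate_scan(ph0, geo, quick_pulse(), clean_forward(),
                     with_tumors = FALSE)
  img <- reconstruct(tb, b, small_config())
  expect_true(all(img$intensity < 1e-25))
})

test_that("noiseless point scatterer focuses within a pixel of the truth", {
  ph <- make_default_phantom()
  case <- sarcmi:::run_case(ph, "sar_guided", 9, seed = 1,
                            forward = clean_forward())
  pitch <- diff(case$image$x[1:2])
  err <- localization_error(case$image, ph$tumors[[1]]$center[1:2])
  expect_lte(err, sqrt(2) * pitch)
})

test_that("ring-geometry records run through the same chain", {
  ph <- make_default_phantom()
  geo <- plan_full_ring(ph, 12, plane_height = 20)
  tb <- simulate_scan(ph, geo, quick_pulse(), clean_forward())
  b <- simulate_scan(ph, geo, quick_pulse(), clean_forward(),
                     with_tumors = FALSE)
  img <- reconstruct(tb, b, small_config(
    medium_permittivity = effective_permittivity(
      ph, geo$positions[1, ], c(0, 0, 20)),
    detection = "envelope", plane_z = 20,
    time_offset = quick_pulse()$time_shift))
  expect_s3_class(img, "cmi_image")
  expect_gt(max(img$intensity), 0)
})

test_that("images round-trip through delimited text", {
  pair <- simulated_pair(params = clean_forward())
  img <- reconstruct(pair$tb, pair$b,
                     small_config(detection = "envelope", plane_z = 14,
                                  medium_permittivity = 6.6,
                                  time_offset = quick_pulse()$time_shift))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_image_tsv(img, path)
  back <- read_image_tsv(path)
  expect_equal(back$intensity, img$intensity, tolerance = 1e-7)
  expect_equal(back$x, img$x, tolerance = 1e-7)
})
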