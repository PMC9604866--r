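test_that("round-trip delay handles degenerate and vacuum cases", {
  ph <- make_default_phantom()
  expect_equal(round_trip_delay(c(0, 0, 60), c(0, 0, 60), ph), 0)
  # permittivity-1 phantom: pure vacuum speed over 10 mm one-way
  ph1 <- breast_phantom(skin = tissue_properties(1 + 1e-12, 1.1),
                        interior = tissue_properties(1 + 1e-12, 0.4))
  expect_equal(round_trip_delay(c(0, 0, 60), c(0, 0, 30), ph1),
               2 * 0.030 / 2.9979e8, tolerance = 1e-9)
  expect_equal(2 * 0.010 / 2.9979e8, 6.671e-11, tolerance = 1e-4)
})

test_that("on-axis delay matches the three-segment hand computation", {
  ph <- make_default_phantom()
  # antenna 10 mm above the pole, target 18 mm below the skin inner face:
  # air 10 mm, skin 2 mm (eps 37), interior 18 mm (eps 9)
  c_mm <- 2.9979e11
  expected <- 2 * (10 + 2 * sqrt(37) + 18 * sqrt(9)) / c_mm
  expect_equal(round_trip_delay(c(0, 0, 60), c(0, 0, 30), ph), expected,
               tolerance = 1e-12)
})

test_that("ray path lengths agree with a dense midpoint-sampling oracle", {
  set.seed(11)
  ph <- make_default_phantom()
  for (k in 1:10) {
    u <- c(rnorm(2), abs(rnorm(1))); u <- u / sqrt(sum(u^2))
    pos <- u * runif(1, 55, 80)
    tgt <- c(runif(2, -15, 15), runif(1, 5, 35))
    if (sqrt(sum(tgt^2)) > 45) next
    seg <- ray_path_lengths(pos, tgt, ph)
    # oracle: classify midpoints of 20000 equal sub-segments
    n <- 20000
    tt <- (seq_len(n) - 0.5) / n
    pts <- cbind(pos[1] + tt * (tgt[1] - pos[1]),
                 pos[2] + tt * (tgt[2] - pos[2]),
                 pos[3] + tt * (tgt[3] - pos[3]))
    r <- sqrt(rowSums(pts^2))
    len <- sqrt(sum((tgt - pos)^2)) / n
    expect_equal(seg[["air"]], sum(r > 50) * len, tolerance = 2e-3)
    expect_equal(seg[["skin"]], sum(r <= 50 & r > 48) * len,
                 tolerance = 2e-2)
    expect_equal(seg[["interior"]], sum(r <= 48) * len, tolerance = 2e-3)
  }
})

test_that("simulation is deterministic and ignores absent tumors", {
  ph0 <- breast_phantom()  # no tumor
  geo <- plan_aperture(c(0, 0, 25), ph0)
  p <- quick_pulse()
  fp <- forward_model_params(noise_sigma = 1e-5, seed = 42)
  r1 <- simulate_scan(ph0, geo, p, fp, with_tumors = TRUE)
  r2 <- simulate_scan(ph0, geo, p, fp, with_tumors = FALSE)
  expect_identical(r1$signals, r2$signals)  # empty tumor sum
  r3 <- simulate_scan(ph0, geo, p, fp, with_tumors = TRUE)
  expect_identical(r1$signals, r3$signals)  # bit-identical rerun
})

test_that("deleting tumors reproduces the tumor-free baseline exactly", {
  ph <- make_default_phantom()
  ph0 <- breast_phantom(skin = ph$skin, interior = ph$interior)
  geo <- default_aperture(ph)
  fp <- forward_model_params(noise_sigma = 2e-6, seed = 9)
  b_flag <- simulate_scan(ph, geo, quick_pulse(), fp, with_tumors = FALSE)
  b_del <- simulate_scan(ph0, geo, quick_pulse(), fp, with_tumors = TRUE)
  expect_identical(b_flag$signals, b_del$signals)
})

test_that("calibrated signal peaks at the analytic round-trip delay", {
  ph <- make_default_phantom()
  geo <- default_aperture(ph)
  pair <- simulated_pair(ph, geo, clean_forward())
  cal <- calibrate(pair$tb, pair$b)
  p <- quick_pulse()
  for (i in seq_len(nrow(geo$positions))) {
    tau <- round_trip_delay(geo$positions[i, ], ph$tumors[[1]]$center, ph)
    t_pk <- cal$time_axis[which.max(abs(cal$signals[i, ]))]
    # envelope of the monocycle peaks within tau/(2 pi) of Tc + tau
    expect_lt(abs(t_pk - (tau + p$time_shift)),
              p$impulse_width / 2)
  }
})

test_that("echo amplitude follows inverse-square spreading", {
  # lossless tissue-free phantom (permittivity ~1, no skin contrast),
  # isotropic antenna: amplitude ratio at doubled distance is 4
  ph <- breast_phantom(skin = tissue_properties(1 + 1e-12, 1.1),
                       interior = tissue_properties(1 + 1e-12, 0.4),
                       tumors = list(tumor_sphere(c(0, 0, 20), 5)))
  fp <- clean_forward(attenuation = c(skin = 0, interior = 0, air = 0),
                      directivity_exponent = 0)
  p <- quick_pulse()
  mk <- function(z) scan_geometry(matrix(c(0, 0, z), 1), 1, 1,
                                  boresights = matrix(c(0, 0, -1), 1))
  taxis <- default_time_axis(2048, 5e-9)
  near <- simulate_scan(ph, mk(60), p, fp, time_axis = taxis)   # d = 40
  far <- simulate_scan(ph, mk(100), p, fp, time_axis = taxis)   # d = 80
  expect_equal(max(abs(near$signals)) / max(abs(far$signals)), 4,
               tolerance = 1e-2)
})

test_that("calibration cancels the reverberation artifact exactly", {
  ph <- make_default_phantom()
  geo <- default_aperture(ph)
  with_art <- simulated_pair(ph, geo, forward_model_params(
    artifact_amplitude = 0.05, noise_sigma = 0))
  no_art <- simulated_pair(ph, geo, clean_forward())
  expect_equal(calibrate(with_art$tb, with_art$b)$signals,
               calibrate(no_art$tb, no_art$b)$signals, tolerance = 1e-14)
})

test_that("antennas inside the phantom are rejected", {
  ph <- make_default_phantom()
  geo <- scan_geometry(matrix(c(0, 0, 30), 1), 1, 1)
  expect_error(simulate_scan(ph, geo, quick_pulse(),
                             forward_model_params()),
               "inside the phantom")
})

test_that("scan records round-trip through the text container", {
  pair <- simulated_pair(params = forward_model_params(noise_sigma = 1e-6,
                                                       seed = 3))
  dir <- withr::local_tempdir()
  write_scan_record(pair$tb, dir)
  back <- read_scan_record(dir)
  expect_equal(back$signals, pair$tb$signals, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$geometry$positions, pair$tb$geometry$positions,
               tolerance = 1e-12)
  expect_equal(back$label, pair$tb$label)
})

test_that("per-position waveform files can be imported as a record", {
  pair <- simulated_pair()
  dir <- withr::local_tempdir()
  files <- character(0)
  for (i in seq_len(nrow(pair$tb$signals))) {
    f <- file.path(dir, sprintf("pos%02d.tsv", i))
    write_waveform_tsv(waveform(pair$tb$time_axis, pair$tb$signals[i, ]), f)
    files <- c(files, f)
  }
  rec <- import_scan_waveforms(files, pair$tb$geometry)
  expect_equal(rec$signals, pair$tb$signals, ignore_attr = TRUE,
               tolerance = 1e-12)
})
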