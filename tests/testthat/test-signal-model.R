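test_that("protocol_spec validates durations and pressures", {
  p <- protocol_spec()
  expect_equal(protocol_duration(p), 1020)
  expect_error(protocol_spec(baseline_s = 0), "durations")
  expect_error(protocol_spec(occlusion_pressure_mmHg = 30), "exceed")
})

test_that("pulse_recording enforces length tolerance by truncation only", {
  p <- protocol_spec()
  n <- 510000
  rec <- pulse_recording(rnorm(n), 500, p)
  expect_equal(length(rec$samples), n)
  # 0.5 s long: truncated back to nominal
  rec2 <- pulse_recording(rnorm(n + 250), 500, p)
  expect_equal(length(rec2$samples), n)
  # 0.5 s short: kept as-is, never padded
  rec3 <- pulse_recording(rnorm(n - 250), 500, p)
  expect_equal(length(rec3$samples), n - 250)
  expect_error(pulse_recording(rnorm(n - 1000), 500, p), "too short")
  expect_error(pulse_recording(c(rnorm(n - 1), NA), 500, p), "non-finite")
})

test_that("segment_phases partitions the recording exactly", {
  rec <- pulse_recording(rnorm(510000), 500)
  ph <- segment_phases(rec)
  expect_equal(ph$baseline, c(1L, 150000L))
  expect_equal(ph$occlusion, c(150001L, 240000L))
  expect_equal(ph$hyperemia, c(240001L, 510000L))
  # contiguous cover, no gap or overlap
  expect_equal(ph$occlusion[1], ph$baseline[2] + 1L)
  expect_equal(ph$hyperemia[1], ph$occlusion[2] + 1L)
  expect_equal(ph$hyperemia[2], length(rec$samples))

  p2 <- protocol_spec(baseline_s = 60, occlusion_s = 30, hyperemia_s = 60)
  rec2 <- pulse_recording(rnorm(15000), 100, p2)
  ph2 <- segment_phases(rec2)
  expect_equal(ph2$baseline, c(1L, 6000L))
  expect_equal(ph2$occlusion, c(6001L, 9000L))
  expect_equal(ph2$hyperemia, c(9001L, 15000L))
})

test_that("recordings shorter than the occlusion end cannot be segmented", {
  p <- protocol_spec(baseline_s = 10, occlusion_s = 10, hyperemia_s = 10)
  rec <- pulse_recording(rnorm(3000), 100, p)
  rec$samples <- rec$samples[1:1500]  # truncate below the hyperemia onset
  expect_error(segment_phases(rec), "hyperemic")
})

test_that("CSV recordings round-trip exactly and reject malformed rows", {
  p <- protocol_spec(baseline_s = 20, occlusion_s = 20, hyperemia_s = 20)
  rec <- pulse_recording(rnorm(6000), 100, p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  rec2 <- read_recording(path, fs_hz = 100, protocol = p)
  expect_identical(rec2$samples, rec$samples)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("value", "1.0", "NaN", "2.0"), bad)
  expect_error(read_recording(bad, 100, p), "row 3")

  # two-column form with inconsistent time base
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,value", paste(seq(0, 1, by = 0.02), rnorm(51), sep = ",")),
             bad2)
  expect_error(read_recording(bad2, 100), "fs")
})

test_that("amplitude_series and beat_set enforce their invariants", {
  expect_error(amplitude_series(c(1, -1, 2), 2, 1:3), "> 0")
  expect_error(amplitude_series(c(1, 1, 2), 5, 1:3), "phase_split")
  s <- amplitude_series(c(1, 2, 3), 2, c(0.5, 1.4, 2.2))
  expect_equal(as.data.frame(s)$phase, c("baseline", "hyperemia", "hyperemia"))

  expect_error(beat_set(c(10, 20), c(5, 30), c(1, 1), 500), "precede")
  expect_error(beat_set(c(10, 8), c(15, 12), c(1, 1), 500), "increasing")
  expect_error(beat_set(10, 15, -1, 500), "> 0")
})

test_that("detrended_series rejects inconsistent reconstructions", {
  src <- amplitude_series(c(1, 2, 3, 4), 2, 1:4)
  expect_silent(detrended_series(c(-1.5, -0.5, 0.5, 1.5), rep(2.5, 4), src))
  expect_error(detrended_series(c(-1.5, -0.5, 0.5, 1.6), rep(2.5, 4), src),
               "reconstruct")
})

test_that("JSON result documents round-trip losslessly", {
  x <- c(rnorm(150))
  curve <- mse_curve(x, mse_config(tau_max = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_result(curve, path)
  curve2 <- read_result(path)
  expect_equal(curve2$s_e, curve$s_e, tolerance = 1e-12)
  expect_equal(curve2$n_tau, curve$n_tau)
  expect_equal(curve2$flags, curve$flags)

  di <- dilatation_index(1.0, 1.5, windows = list(baseline = c(240, 300),
                                                  rh = c(480, 540)))
  write_result(di, path)
  di2 <- read_result(path)
  expect_equal(di2$di_percent, 150)
  expect_equal(di2$windows$rh, c(480, 540))
})

test_that("degenerate entropy scales serialize as null with a flag", {
  # constant-ish coarse series at large tau -> B = 0 can occur; force a NaN
  curve <- mse_curve(rnorm(150), mse_config(tau_max = 5))
  curve$s_e[3] <- NaN
  curve$flags[3] <- "undefined"
  path <- withr::local_tempfile(fileext = ".json")
  write_result(curve, path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_null(raw$s_e[[3]])
  expect_equal(raw$flags[[3]], "undefined")
  curve2 <- read_result(path)
  expect_true(is.nan(curve2$s_e[3]))
})
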