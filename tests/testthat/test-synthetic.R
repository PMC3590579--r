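test_that("the generator is deterministic and parameter-validated", {
  p <- group_archetype(1)
  s1 <- simulate_amplitude_series(p, seed = 9)
  s2 <- simulate_amplitude_series(p, seed = 9)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$beat_times_s, s2$beat_times_s)
  r1 <- render_waveform(s1, p, seed = 9)
  r2 <- render_waveform(s2, p, seed = 9)
  expect_identical(r1$recording$samples, r2$recording$samples)

  expect_error(archetype_params(gain = -1), "positive")
  expect_error(archetype_params(complexity = 1.2), "complexity")
  expect_error(simulate_amplitude_series(p, n_beats = 10), ">= 20")
})

test_that("gain 1 with zero fluctuation gives a constant series", {
  p <- archetype_params(gain = 1, fluct_cv = 0, hr_cv = 0)
  s <- simulate_amplitude_series(p, seed = 3)
  expect_equal(diff(range(s$values)), 0)
  expect_equal(s$values[1], p$base_amp)
})

test_that("default protocol at 71 bpm yields close to the nominal 379/621 split", {
  s <- simulate_amplitude_series(group_archetype(1), seed = 42)
  nb <- s$phase_split - 1L
  nh <- length(s$values) - nb
  # 71 bpm over 5 + 9 min: about 355 baseline and 639 hyperemic beats
  expect_gt(nb, 330); expect_lt(nb, 400)
  expect_gt(nh, 590); expect_lt(nh, 660)
  expect_gt(length(s$values), 950)
  # no beat time falls in the occlusion phase
  expect_false(any(s$beat_times_s >= 300 & s$beat_times_s < 480))
})

test_that("the hyperemic envelope follows the programmed exponential decay", {
  p <- archetype_params(gain = 2, fluct_cv = 0, hr_cv = 0, rh_tau_s = 300)
  s <- simulate_amplitude_series(p, seed = 1)
  t_h <- s$beat_times_s[s$phase_split:length(s$values)]
  v_h <- s$values[s$phase_split:length(s$values)]
  expected <- p$base_amp * (1 + (p$gain - 1) * exp(-(t_h - 480) / 300))
  expect_equal(v_h, expected, tolerance = 1e-12)
})

test_that("1/f synthesis has the right spectral slope", {
  slopes <- vapply(1:10, function(s) {
    x <- withr::with_seed(s, meipulse:::pink_noise(2048))
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
    unname(stats::coef(stats::lm(log(sp$spec) ~ log(sp$freq)))[2])
  }, numeric(1))
  expect_true(all(slopes > -1.3 & slopes < -0.7))
})

test_that("pink-dominated fluctuations raise MEI_LS relative to white", {
  n_pairs <- 12
  wins <- 0
  for (s in seq_len(n_pairs)) {
    p1 <- archetype_params(complexity = 1)
    p0 <- archetype_params(complexity = 0)
    m1 <- mei(mse_curve(emd_detrend(
      simulate_amplitude_series(p1, seed = 100 + s), trend_imfs = "auto")))
    m0 <- mei(mse_curve(emd_detrend(
      simulate_amplitude_series(p0, seed = 100 + s), trend_imfs = "auto")))
    wins <- wins + (m1$mei_ls > m0$mei_ls)
  }
  expect_gte(wins / n_pairs, 0.9)
})

test_that("a rendered single beat peaks at the programmed amplitude", {
  protocol <- protocol_spec(baseline_s = 10, occlusion_s = 1, hyperemia_s = 10)
  params <- archetype_params(hr_bpm = 60, hr_cv = 0, gain = 1, fluct_cv = 0,
                             snr_db = 200)
  s <- simulate_amplitude_series(params, seed = 1, protocol = protocol)
  rw <- render_waveform(s, params, seed = 1, protocol = protocol)
  x <- rw$recording$samples
  # subtract DC and wander floor: peak height above the local minimum
  k <- which.max(x)
  base <- min(x[max(1, k - 250):k])
  expect_equal(x[k] - base, s$values[1], tolerance = 0.02)
})

test_that("too-fast heart rates are rejected as overlapping beats", {
  protocol <- protocol_spec(baseline_s = 10, occlusion_s = 1, hyperemia_s = 10)
  s <- amplitude_series(rep(1, 21), 11, seq(0.25, 5.25, by = 0.25))
  attr(s, "onsets_s") <- seq(0.2, 5.2, by = 0.25)
  attr(s, "rr_s") <- rep(0.25, 21)
  expect_error(render_waveform(s, archetype_params(), protocol = protocol),
               "overlapping beats")
})

test_that("simulate_cohort derives deterministic per-subject seeds and metadata", {
  c1 <- simulate_cohort(c(2, 2, 2, 2), master_seed = 11)
  c2 <- simulate_cohort(c(2, 2, 2, 2), master_seed = 11)
  expect_equal(length(c1$subjects), 8)
  expect_identical(vapply(c1$subjects, `[[`, 1, "seed"),
                   vapply(c2$subjects, `[[`, 1, "seed"))
  expect_identical(c1$subjects[[3]]$series$values,
                   c2$subjects[[3]]$series$values)
  expect_identical(c1$subjects[[5]]$meta, c2$subjects[[5]]$meta)
  expect_equal(vapply(c1$subjects, `[[`, 1, "group"), rep(1:4, each = 2))
  # default sizes reproduce the 140-subject reference design
  expect_equal(sum(eval(formals(simulate_cohort)$group_sizes)), 140)
})

test_that("rendered recordings round-trip through CSV identically", {
  protocol <- protocol_spec(baseline_s = 20, occlusion_s = 5, hyperemia_s = 20)
  params <- archetype_params()
  s <- simulate_amplitude_series(params, seed = 2, protocol = protocol)
  rec <- render_waveform(s, params, seed = 2, protocol = protocol)$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  rec2 <- read_recording(path, fs_hz = 500, protocol = protocol)
  expect_identical(rec2$samples, rec$samples)
})
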