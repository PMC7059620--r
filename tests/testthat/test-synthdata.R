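test_that("stimulus envelope has the requested layout and is nonnegative", {
  expect_equal(make_stimulus_envelope(0, 0.1, 0.2)$value, numeric(0))

  env <- make_stimulus_envelope(3, syllable_dur = 0.1, gap_dur = 0.2)
  expect_equal(nrow(env), ceiling(3 * 0.3 * 200))
  expect_true(all(env$value >= 0))
  # syllables occupy 1/3 of the motif; above-half-max fraction is close to
  # that, shaved slightly by the raised-cosine ramps
  frac <- mean(env$value > 0.5 * max(env$value))
  expect_gt(frac, 1 / 3 - 0.05)
  expect_lt(frac, 1 / 3 + 0.05)

  for (s in 1:5)
    expect_gte(min(make_stimulus_envelope(4, seed = s)$value), 0)
  expect_error(make_stimulus_envelope(3, syllable_dur = -0.1), "nonnegative")
})

test_that("population sampling converges to group targets and respects geometry", {
  expect_equal(nrow(simulate_unit_population(0, 0, seed = 1)), 0)

  pop <- simulate_unit_population(200, 200, seed = 7)
  tg <- group_feature_targets()
  for (grp in c("surface", "depth")) {
    p <- pop[pop$group == grp, ]
    t <- tg[tg$group == grp, ]
    expect_lt(abs(median(p$duration_s) / t$duration_s - 1), 0.2)
    amp <- p$trough_amp_uV - p$peak_amp_uV
    expect_lt(abs(median(amp) / t$amplitude_uV - 1), 0.2)
    expect_lt(abs(median(p$trough_amp_uV / p$peak_amp_uV) / t$trough_peak_ratio - 1), 0.2)
  }
  # units sit on electrodes of their own probe
  geom <- default_geometry()
  probe_of <- geom$probe[match(pop$electrode_id, geom$electrode_id)]
  expect_equal(probe_of, pop$group)

  bad <- group_feature_targets()
  bad$group[1] <- "cerebellum"
  expect_error(simulate_unit_population(2, 2, feature_targets = bad), "Unknown group")
})

test_that("sessions are bit-identical under the same seed and empty for empty input", {
  pop <- simulate_unit_population(2, 2, seed = 5)
  s1 <- simulate_session(pop, session_config(n_trials = 3, seed = 9))
  s2 <- simulate_session(pop, session_config(n_trials = 3, seed = 9))
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$waveforms, s2$waveforms)

  s0 <- simulate_session(pop[0, ], session_config(n_trials = 3, seed = 9))
  expect_equal(nrow(s0$spikes), 0)
  expect_equal(nrow(s0$events), 3)
})

test_that("spike generation matches Poisson count statistics and is ordered", {
  pop <- simulate_unit_population(1, 0, seed = 2)
  pop$baseline_rate <- 5
  pop$stimulus_gain <- 0
  pop$bursting <- FALSE
  # ~100 s of silence; drive off so the Poisson SE oracle applies
  cfg <- session_config(n_trials = 9, isi_low = 9.99, isi_high = 10.01,
                        n_syllables = 1, syllable_dur = 0.3, gap_dur = 0.3,
                        seed = 4, drive_sd = 0)
  ses <- simulate_session(pop, cfg)
  n <- nrow(ses$spikes)
  expected <- 5 * ses$duration_s
  expect_lt(abs(n - expected), 3 * sqrt(expected))
  expect_true(all(diff(ses$spikes$time_s) > 0))

  pop$baseline_rate <- 0
  ses0 <- simulate_session(pop, cfg)
  expect_equal(nrow(ses0$spikes), 0)
})

test_that("planted response lag is recovered by the response pipeline", {
  pop <- simulate_unit_population(0, 1, seed = 3, stimulus_gain = 40,
                                  response_lag = 0.05)
  pop$bursting <- FALSE
  ses <- simulate_session(pop, session_config(n_trials = 50, seed = 3))
  rs <- response_summary(ses)
  expect_lte(abs(rs$lag_ms - 50), 5) # within one 5 ms bin
})

test_that("waveform rendering is exact without noise and feature round-trips", {
  u <- list(peak_amp_uV = -40, trough_amp_uV = 20, duration_s = 4e-4)
  wf0 <- render_waveform_snippets(u, n_snippets = 1, noise_sd = 0)
  f <- waveform_features(wf0)
  expect_equal(f$amplitude_uV, 60, tolerance = 1e-6)
  expect_equal(f$trough_peak_ratio, -0.5, tolerance = 1e-6)
  expect_equal(f$duration_s, 4e-4, tolerance = 0.1)

  # CLT bound on the average of noisy snippets
  wf <- render_waveform_snippets(u, n_snippets = 50, noise_sd = 10, seed = 1)
  rms <- sqrt(mean((wf$uV - wf0$uV)^2))
  expect_lt(rms, 3 * 10 / sqrt(50))

  expect_error(render_waveform_snippets(u, n_snippets = 50, noise_sd = -1), "noise_sd")
})

test_that("session CSV round-trip preserves the tables", {
  ses <- small_session()
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(as.data.frame(back$spikes), as.data.frame(ses$spikes))
  expect_equal(as.data.frame(back$events), as.data.frame(ses$events))
  expect_equal(back$duration_s, ses$duration_s)
})
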