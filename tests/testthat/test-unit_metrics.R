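test_that("waveform features follow the peak/trough conventions", {
  # peak (minimum) at sample 31, post-peak maximum at sample 41, fs = 30 kHz
  v <- numeric(60)
  v[31] <- -40
  v[41] <- 20
  v[5] <- 5 # an early bump: must not be picked as the trough
  w <- tibble::tibble(time_s = (0:59) / 30000, uV = v)
  f <- waveform_features(w)
  expect_equal(f$amplitude_uV, 60)
  expect_equal(f$duration_s, 10 / 30000)
  expect_equal(f$trough_peak_ratio, -0.5)

  # even-symmetric waveform has symmetry exactly 1
  sym <- tibble::tibble(time_s = (0:40) / 30000,
                        uV = -exp(-((0:40) - 20)^2 / 30))
  expect_equal(waveform_features(sym)$symmetry, 1)

  # monotone waveform: no interior minimum
  mono <- tibble::tibble(time_s = (0:19) / 30000, uV = seq(0, -19))
  expect_error(waveform_features(mono), "minimum")
})

test_that("waveform features are invariant to offset and equivariant to scale", {
  u <- list(peak_amp_uV = -35, trough_amp_uV = 15, duration_s = 3e-4)
  w <- render_waveform_snippets(u, 1, noise_sd = 0)
  f0 <- waveform_features(w)
  for (off in c(-12, 40)) {
    f <- waveform_features(dplyr::mutate(w, uV = uV + off))
    expect_equal(f$duration_s, f0$duration_s)
    expect_equal(f$amplitude_uV, f0$amplitude_uV)
  }
  for (cc in c(0.5, 3)) {
    f <- waveform_features(dplyr::mutate(w, uV = uV * cc))
    expect_equal(f$amplitude_uV, cc * f0$amplitude_uV)
    expect_equal(f$trough_peak_ratio, f0$trough_peak_ratio)
    expect_equal(f$symmetry, f0$symmetry)
  }
})

test_that("spike rate and refractory fraction match their definitions", {
  expect_equal(spike_rate(numeric(0), 10), 0)
  expect_equal(spike_rate(runif(150, 0, 100), 100), 1.5)
  expect_error(spike_rate(1:3, 0), "> 0")

  set.seed(8)
  tr <- rpoisson_train(2, 500)
  expect_lt(abs(spike_rate(tr, 500) - 2), 3 * sqrt(2 / 500))

  expect_equal(refractory_violation_fraction(c(0, 0.001, 0.010)), 0.5)
  expect_equal(refractory_violation_fraction(c(0, 0.1, 0.2)), 0)
  expect_equal(refractory_violation_fraction(0.5), 0)
})

test_that("log-ISI density is normalized with the expected mode structure", {
  set.seed(21)
  tr <- cumsum(rexp(2000, 1)) # exponential ISIs at 1 Hz
  prof <- log_isi_density(tr)
  expect_equal(sum(prof$density), 1)
  # mode of the log10 of an Exp(1) variable sits at log10(1 s) = 0
  mode_at <- prof$log10_isi[which.max(prof$density)]
  expect_lt(abs(mode_at - 0), 2.5 / 10)

  # burst mixture: two local maxima more than a decade apart
  set.seed(22)
  trb <- rburst_train(1, 2000)
  profb <- log_isi_density(trb)
  pk <- profb$log10_isi[profb$density >= 0.05 * max(profb$density)]
  expect_gt(diff(range(pk)), 1)
  expect_gt(void_parameter(profb), 0.7)
})

test_that("void parameter matches its formula and degenerate cases", {
  # constructed density: peaks 0.04 and 0.025 with a 0.01 valley between;
  # hand arithmetic: void = 1 - 0.01 / sqrt(0.04 * 0.025)
  centers <- seq(-3.45, 1.45, by = 0.1)
  d <- numeric(50)
  d[8:22] <- c(0.02, 0.03, 0.04, 0.03, 0.02, 0.012, 0.01, 0.012, 0.018,
               0.022, 0.025, 0.02, 0.012, 0.006, 0.002)
  prof <- tibble::tibble(log10_isi = centers, density = d)
  expect_equal(void_parameter(prof), 1 - 0.01 / sqrt(0.04 * 0.025))

  # zero valley: void = 1
  d2 <- numeric(50); d2[10] <- 0.3; d2[30] <- 0.2
  expect_equal(void_parameter(tibble::tibble(log10_isi = centers, density = d2)), 1)

  # unimodal: undefined
  d3 <- dnorm(centers, 0, 0.5); d3 <- d3 / sum(d3)
  expect_true(is.na(void_parameter(tibble::tibble(log10_isi = centers, density = d3))))

  expect_true(classify_bursting(0.9))
  expect_false(classify_bursting(0.5))
  expect_false(classify_bursting(NA_real_))
})

test_that("Poisson trains are non-bursting and burst trains bursting (40 seeds)", {
  n_seeds <- 40
  poisson_ok <- 0
  burst_ok <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    lam <- runif(1, 1, 5)
    tr <- cumsum(rexp(1000, lam))
    if (!classify_bursting(void_parameter(log_isi_density(tr)))) poisson_ok <- poisson_ok + 1
    trb <- rburst_train(1, 1000)
    if (classify_bursting(void_parameter(log_isi_density(trb)))) burst_ok <- burst_ok + 1
  }
  expect_gte(poisson_ok, 0.95 * n_seeds)
  expect_gte(burst_ok, 0.95 * n_seeds)
})

test_that("unit yield is the per-class electrode percentage", {
  lab <- tibble::tibble(electrode_id = c("e1", "e2", "e3", "e4", "e4"),
                        label = c("SUA", "SUA", "SUA", "SUA", "MUA"))
  y <- unit_yield(lab, 29)
  expect_equal(y$yield_pct[y$label == "SUA"], 100 * 4 / 29)
  expect_equal(round(y$yield_pct[y$label == "SUA"], 2), 13.79)
  expect_equal(y$yield_pct[y$label == "MUA"], 100 * 1 / 29)

  all32 <- tibble::tibble(electrode_id = sprintf("e%02d", 1:32), label = "SUA")
  expect_equal(unit_yield(all32, 32)$yield_pct, 100)
  expect_error(unit_yield(all32, 0), "n_functional")
})

test_that("unit_features assembles the per-unit table", {
  ses <- small_session()
  uf <- unit_features(ses)
  expect_equal(nrow(uf), nrow(ses$units))
  expect_true(all(c("duration_s", "amplitude_uV", "trough_peak_ratio",
                    "symmetry", "rate_hz", "void", "bursting") %in% names(uf)))
  expect_true(all(uf$rate_hz >= 0))
  expect_true(all(uf$amplitude_uV > 0, na.rm = TRUE))
})
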