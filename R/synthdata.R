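#' Group-level waveform and firing targets for the synthetic population
#'
#' Central tendencies used by [simulate_unit_population()] for each recording
#' group. Surface units are short-duration, small-amplitude and more biphasic
#' (trough/peak closer to -1) than depth units; depth units burst more often.
#'
#' @return A tibble with one row per group (`surface`, `depth`) and columns
#'   `duration_s`, `amplitude_uV`, `trough_peak_ratio`, `spike_rate_hz`,
#'   `p_bursting`.
#' @export
#' @examples
#' group_feature_targets()
group_feature_targets <- function() {
  tibble(
    group             = c("surface", "depth"),
    duration_s        = c(0.167e-3, 0.5e-3),
    amplitude_uV      = c(53.4, 107.3),
    trough_peak_ratio = c(-0.65, -0.32),
    spike_rate_hz     = c(1.95, 1.52),
    p_bursting        = c(14 / 23, 34 / 46)
  )
}

#' Default electrode geometry: surface grid plus depth shank
#'
#' Builds a 3D electrode table for a planar surface grid (32 contacts on a
#' 200 um pitch by default) and a single-shank penetrating probe inserted
#' through the grid centre. Surface contacts sit at z = 0; depth sites run
#' from `insertion_depth_um` downward at `site_spacing_um` intervals.
#'
#' @param n_rows,n_cols Surface grid layout (default 8 x 4 = 32 contacts).
#' @param pitch_um Surface contact pitch in micrometres.
#' @param n_depth_sites Number of depth-probe sites.
#' @param site_spacing_um Spacing between depth sites, micrometres.
#' @param insertion_depth_um Depth (z, um) of the shallowest depth site.
#' @return Tibble with columns `electrode_id`, `probe`, `x_um`, `y_um`, `z_um`.
#' @export
#' @examples
#' g <- default_geometry()
#' physical_distance(g, "s01", "s02")
default_geometry <- function(n_rows = 8, n_cols = 4, pitch_um = 200,
                             n_depth_sites = 16, site_spacing_um = 50,
                             insertion_depth_um = 600) {
  surf <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols)) %>%
    mutate(
      electrode_id = sprintf("s%02d", row_number()),
      probe = "surface",
      x_um = (.data$col - 1) * pitch_um,
      y_um = (.data$row - 1) * pitch_um,
      z_um = 0
    ) %>%
    select("electrode_id", "probe", "x_um", "y_um", "z_um")
  cx <- (n_cols - 1) * pitch_um / 2
  cy <- (n_rows - 1) * pitch_um / 2
  dep <- tibble(
    electrode_id = sprintf("d%02d", seq_len(n_depth_sites)),
    probe = "depth",
    x_um = cx,
    y_um = cy,
    z_um = insertion_depth_um + (seq_len(n_depth_sites) - 1) * site_spacing_um
  )
  bind_rows(surf, dep)
}

#' Synthetic song-like amplitude envelope
#'
#' Lays out `n_syllables` raised-cosine-gated syllables separated by silent
#' gaps, sampled on a 200 Hz grid (the rate used throughout the
#' stimulus-response analysis). This emulates the amplitude envelope of a
#' song motif: a sparse sequence of sound bursts with smooth on/offsets.
#'
#' @param n_syllables Number of syllables (0 gives an all-zero envelope).
#' @param syllable_dur,gap_dur Syllable and gap durations, seconds.
#' @param rate Sample rate of the envelope grid, Hz.
#' @param seed Optional integer; when given, syllable amplitudes are drawn
#'   uniformly in (0.6, 1) and each syllable/gap duration is jittered by
#'   +/-40% so the motif is aperiodic, as real song is. With `seed = NULL`
#'   the layout is exactly regular with unit amplitudes.
#' @param ramp Raised-cosine on/offset duration, seconds.
#' @return Tibble with columns `t_s` (sample times, left-edge convention)
#'   and `value` (nonnegative).
#' @export
#' @examples
#' env <- make_stimulus_envelope(3, syllable_dur = 0.1, gap_dur = 0.2)
#' range(env$value)
make_stimulus_envelope <- function(n_syllables, syllable_dur = 0.15,
                                   gap_dur = 0.15, rate = 200, seed = NULL,
                                   ramp = 0.005) {
  check_scalar(n_syllables, "n_syllables", nonneg = TRUE)
  if (syllable_dur < 0 || gap_dur < 0 || ramp < 0)
    abort("Durations must be nonnegative.")
  check_scalar(rate, "rate", positive = TRUE)
  amps <- rep(1, n_syllables)
  syl <- rep(syllable_dur, n_syllables)
  gap <- rep(gap_dur, n_syllables)
  if (!is.null(seed) && n_syllables >= 1) {
    # local stream, do not disturb the caller's RNG
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    amps <- runif(n_syllables, 0.6, 1)
    syl <- syllable_dur * runif(n_syllables, 0.6, 1.4)
    gap <- gap_dur * runif(n_syllables, 0.6, 1.4)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  total <- sum(syl + gap)
  n <- ceiling(round(total * rate, 9))
  t <- (seq_len(n) - 1) / rate
  value <- numeric(n)
  if (n_syllables >= 1) {
    starts <- cumsum(c(0, (syl + gap)[-n_syllables]))
    for (k in seq_len(n_syllables)) {
      rk <- min(ramp, syl[k] / 2)
      tt <- t - starts[k]
      inside <- tt >= 0 & tt < syl[k]
      w <- numeric(n)
      w[inside] <- 1
      if (rk > 0) {
        on <- inside & tt < rk
        off <- inside & tt > syl[k] - rk
        w[on] <- 0.5 * (1 - cos(pi * tt[on] / rk))
        w[off] <- 0.5 * (1 - cos(pi * (syl[k] - tt[off]) / rk))
      }
      value <- value + amps[k] * w
    }
  }
  tibble(t_s = t, value = pmax(value, 0))
}

#' Simulate a population of surface and depth units
#'
#' Draws per-unit waveform and firing parameters around group-level targets
#' (see [group_feature_targets()]): log-normal duration, amplitude and baseline rate
#' (so sample medians converge to the targets as n grows), a negative
#' trough/peak ratio, and a per-group bursting probability. Units are
#' assigned to electrodes of their own probe, without replacement while
#' contacts remain.
#'
#' @param n_surface,n_depth Number of units per group (0 allowed).
#' @param feature_targets Tibble as returned by [group_feature_targets()]; groups
#'   other than `surface`/`depth` are an error.
#' @param geometry Electrode table, see [default_geometry()].
#' @param seed Integer seed for reproducibility.
#' @param stimulus_gain Envelope-driven rate gain, Hz per unit envelope.
#' @param response_lag Neural response lag, seconds (must be in [0, 0.2)).
#' @return Tibble of unit specifications, one row per unit: `unit_id`,
#'   `group`, `electrode_id`, `label`, `baseline_rate`, `stimulus_gain`,
#'   `response_lag`, `bursting`, `intra_burst_isi`, `burst_rate`,
#'   `peak_amp_uV` (negative), `trough_amp_uV` (positive), `duration_s`.
#' @export
#' @examples
#' pop <- simulate_unit_population(4, 8, seed = 1)
#' dplyr::count(pop, group)
simulate_unit_population <- function(n_surface, n_depth,
                                     feature_targets = group_feature_targets(),
                                     geometry = default_geometry(),
                                     seed = NULL,
                                     stimulus_gain = 15,
                                     response_lag = 0.05) {
  check_scalar(n_surface, "n_surface", nonneg = TRUE)
  check_scalar(n_depth, "n_depth", nonneg = TRUE)
  if (!all(feature_targets$group %in% c("surface", "depth")))
    abort("Unknown group name in `feature_targets` (expected surface/depth).")
  if (response_lag < 0 || response_lag >= 0.2)
    abort("`response_lag` must lie in [0, 0.2) seconds.")
  if (!is.null(seed)) set.seed(seed)

  draw_group <- function(grp, n, prefix) {
    if (n == 0) return(NULL)
    tg <- feature_targets[feature_targets$group == grp, ]
    if (nrow(tg) != 1) abort(sprintf("No targets for group '%s'.", grp))
    dur <- rlnorm(n, log(tg$duration_s), 0.2)
    amp <- rlnorm(n, log(tg$amplitude_uV), 0.25)
    ratio <- -rlnorm(n, log(-tg$trough_peak_ratio), 0.2)
    rate <- rlnorm(n, log(tg$spike_rate_hz), 0.4)
    peak <- -amp / (1 - ratio)
    elig <- geometry$electrode_id[geometry$probe == grp]
    if (length(elig) == 0) abort(sprintf("Geometry has no '%s' electrodes.", grp))
    eid <- if (n <= length(elig)) sample(elig, n) else sample(elig, n, replace = TRUE)
    tibble(
      unit_id = sprintf("%s%03d", prefix, seq_len(n)),
      group = grp,
      electrode_id = eid,
      label = "SUA",
      baseline_rate = rate,
      stimulus_gain = stimulus_gain,
      response_lag = response_lag,
      bursting = as.logical(rbinom(n, 1, tg$p_bursting)),
      intra_burst_isi = 0.003,
      burst_rate = rate / 2,
      peak_amp_uV = peak,
      trough_amp_uV = ratio * peak,
      duration_s = dur
    )
  }
  out <- bind_rows(draw_group("surface", n_surface, "su"),
                   draw_group("depth", n_depth, "du"))
  if (is.null(out)) {
    out <- tibble(
      unit_id = character(), group = character(), electrode_id = character(),
      label = character(), baseline_rate = numeric(), stimulus_gain = numeric(),
      response_lag = numeric(), bursting = logical(), intra_burst_isi = numeric(),
      burst_rate = numeric(), peak_amp_uV = numeric(), trough_amp_uV = numeric(),
      duration_s = numeric()
    )
  }
  out
}

#' Session configuration
#'
#' Trial schedule and simulation settings for [simulate_session()]. Defaults
#' follow the recording protocol the analysis targets: 54 stimulus
#' presentations at inter-stimulus intervals drawn uniformly between 7 and
#' 15 s, neural data nominally at 20 or 30 kHz, and a 200 Hz envelope grid.
#'
#' @param n_trials Number of stimulus presentations.
#' @param isi_low,isi_high Uniform inter-stimulus interval bounds, seconds
#'   (silence between the end of one stimulus and the next onset).
#' @param n_syllables,syllable_dur,gap_dur Stimulus envelope layout, passed
#'   to [make_stimulus_envelope()].
#' @param sample_rate Neural sample rate, Hz (20000 or 30000 by default;
#'   used for waveform rendering).
#' @param env_rate Envelope/intensity grid rate, Hz.
#' @param seed Integer master seed. Per-unit spike streams are derived from
#'   it by stable hashing of `unit_id`, so editing the population does not
#'   perturb the remaining units' spikes.
#' @param coupling_scale_um Length scale (um) of the distance decay of the
#'   shared-drive coupling.
#' @param drive_sd Log-normal modulation depth of the shared drive
#'   (dimensionless; 0 disables shared synchrony).
#' @param drive_tau Ornstein-Uhlenbeck time constant of the shared drive,
#'   seconds.
#' @param waveform_noise_sd Per-sample snippet noise for waveform rendering,
#'   microvolts.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_trials = 54, isi_low = 7, isi_high = 15,
                           n_syllables = 5, syllable_dur = 0.15,
                           gap_dur = 0.15, sample_rate = 30000,
                           env_rate = 200, seed = 1,
                           coupling_scale_um = 300, drive_sd = 2.5,
                           drive_tau = 0.1, waveform_noise_sd = 5) {
  check_scalar(n_trials, "n_trials", positive = TRUE)
  if (isi_low >= isi_high) abort("`isi_low` must be < `isi_high`.")
  structure(list(
    n_trials = as.integer(n_trials), isi_low = isi_low, isi_high = isi_high,
    n_syllables = n_syllables, syllable_dur = syllable_dur, gap_dur = gap_dur,
    sample_rate = sample_rate, env_rate = env_rate, seed = as.integer(seed),
    coupling_scale_um = coupling_scale_um, drive_sd = drive_sd,
    drive_tau = drive_tau, waveform_noise_sd = waveform_noise_sd
  ), class = "session_config")
}

# shift a series to the right by k samples, zero-padding at the start
shift_right <- function(v, k) {
  k <- as.integer(k)
  if (k <= 0) return(v)
  c(rep(0, k), v[seq_len(length(v) - k)])
}

# stationary OU process on a regular grid (unit stationary variance)
ou_process <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  innov <- rnorm(n, sd = sqrt(1 - a^2))
  innov[1] <- rnorm(1) # stationary start
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Simulate a full recording session
#'
#' Generates spike trains, the stimulus schedule and per-unit average
#' waveforms for a unit population. Non-bursting units fire as an
#' inhomogeneous Poisson process with intensity
#' `baseline_rate + stimulus_gain * envelope(t - response_lag)`, realised by
#' thinning against the piecewise-constant intensity on the 200 Hz envelope
#' grid. Bursting units instead emit Poisson burst onsets at `burst_rate`
#' (modulated the same way) with `1 + Geometric(0.5)` spikes per burst at
#' intra-burst intervals jittered by +/-20%, which produces the bimodal
#' log-ISI structure the void parameter detects. The ongoing (baseline)
#' intensity of every unit is multiplied by
#' a mean-preserving log-normal shared drive built from one latent
#' Ornstein-Uhlenbeck modulator per spatial cluster (one cluster per
#' electrode site): each unit mixes the cluster modulators with weights
#' `exp(-d / coupling_scale_um)` in its distance `d` to each cluster, so the
#' drive correlation -- and hence the spike-train synchrony -- of a unit
#' pair decays with the physical distance between their electrodes. The
#' stimulus-evoked term is left unmodulated, so evoked responses are
#' reliable across trials while ongoing activity co-fluctuates.
#'
#' @param population Unit table from [simulate_unit_population()].
#' @param config A [session_config()].
#' @param geometry Electrode table, see [default_geometry()].
#' @return A list of class `ecog_session` with elements `units`, `geometry`,
#'   `spikes` (tibble `unit_id`, `time_s`, `label`, `electrode_id`, `group`),
#'   `events` (tibble `onset_s`, `stimulus_id`), `stimulus` (one-motif
#'   envelope, 200 Hz), `envelope` (session-long envelope, 200 Hz),
#'   `waveforms` (long tibble `unit_id`, `time_ms`, `uV`), `duration_s`, and
#'   `config`. Identical seeds and configs reproduce the session exactly.
#' @export
#' @examples
#' pop <- simulate_unit_population(2, 2, seed = 1)
#' ses <- simulate_session(pop, session_config(n_trials = 5, seed = 1))
#' dplyr::count(ses$spikes, unit_id)
simulate_session <- function(population, config = session_config(),
                             geometry = default_geometry()) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  fs_env <- config$env_rate
  stim <- make_stimulus_envelope(config$n_syllables, config$syllable_dur,
                                 config$gap_dur, rate = fs_env,
                                 seed = config$seed + 7L)
  stim_dur <- config$n_syllables * (config$syllable_dur + config$gap_dur)

  gaps <- runif(config$n_trials, config$isi_low, config$isi_high)
  onsets <- 3 + cumsum(c(0, (stim_dur + gaps)[-config$n_trials]))
  duration <- onsets[length(onsets)] + stim_dur + 3
  n_grid <- ceiling(duration * fs_env)
  env_sess <- numeric(n_grid)
  for (o in onsets) {
    i0 <- round(o * fs_env)
    idx <- i0 + seq_along(stim$value)
    keep <- idx <= n_grid
    env_sess[idx[keep]] <- env_sess[idx[keep]] + stim$value[keep]
  }
  # one latent OU modulator per spatial cluster (one cluster per electrode
  # site); each unit mixes them with weights decaying with distance, so the
  # drive correlation of a unit pair decays with their physical separation
  centers <- geometry[, c("x_um", "y_um", "z_um")]
  drives <- matrix(0, n_grid, nrow(centers))
  for (c_i in seq_len(nrow(centers)))
    drives[, c_i] <- ou_process(n_grid, 1 / fs_env, config$drive_tau)
  mix_weights <- function(x, y, z) {
    w <- exp(-sqrt((centers$x_um - x)^2 + (centers$y_um - y)^2 +
                     (centers$z_um - z)^2) / config$coupling_scale_um)
    w / sqrt(sum(w^2)) # unit-variance mixed drive
  }

  events <- tibble(onset_s = onsets, stimulus_id = "stim01")
  empty_spikes <- tibble(unit_id = character(), time_s = numeric(),
                         label = character(), electrode_id = character(),
                         group = character())
  if (nrow(population) == 0) {
    return(structure(list(
      units = population, geometry = geometry, spikes = empty_spikes,
      events = events, stimulus = stim,
      envelope = tibble(t_s = (seq_len(n_grid) - 1) / fs_env, value = env_sess),
      waveforms = tibble(unit_id = character(), time_ms = numeric(), uV = numeric()),
      duration_s = duration, config = config
    ), class = "ecog_session"))
  }

  # exact sampling of an inhomogeneous Poisson process with piecewise-
  # constant intensity on the envelope grid: per-bin Poisson counts with
  # uniform placement inside each bin
  sample_poisson <- function(lam_grid) {
    counts <- rpois(n_grid, lam_grid / fs_env)
    hit <- which(counts > 0)
    if (length(hit) == 0) return(numeric(0))
    tt <- (rep(hit, counts[hit]) - 1 +
             runif(sum(counts[hit]))) / fs_env
    tt[tt <= duration]
  }

  spike_rows <- vector("list", nrow(population))
  wf_rows <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    u <- population[i, ]
    g <- geometry[geometry$electrode_id == u$electrode_id, ]
    if (nrow(g) == 0) abort(sprintf("Electrode '%s' not in geometry.", u$electrode_id))
    s <- config$drive_sd
    modulator <- if (s > 0) {
      m_i <- as.numeric(drives %*% mix_weights(g$x_um, g$y_um, g$z_um))
      exp(s * m_i - s^2 / 2)
    } else rep(1, n_grid)

    set.seed((config$seed * 1000003 + stable_hash(u$unit_id)) %% 2147483647)
    lag_samp <- round(u$response_lag * fs_env)
    stim_term <- u$stimulus_gain * shift_right(env_sess, lag_samp)
    times <- if (isTRUE(u$bursting)) {
      onset_lam <- u$burst_rate * modulator + stim_term / 2
      bursts <- sample_poisson(onset_lam)
      if (length(bursts) == 0) numeric(0) else {
        n_extra <- rgeom(length(bursts), 0.5)
        unlist(lapply(seq_along(bursts), function(k) {
          if (n_extra[k] == 0) return(bursts[k])
          isis <- u$intra_burst_isi * runif(n_extra[k], 0.8, 1.2)
          bursts[k] + c(0, cumsum(isis))
        }))
      }
    } else {
      sample_poisson(u$baseline_rate * modulator + stim_term)
    }
    times <- sort(times)
    times <- times[times >= 0 & times <= duration]
    if (length(times) > 1) times <- times[c(TRUE, diff(times) > 1e-9)]
    spike_rows[[i]] <- tibble(unit_id = u$unit_id, time_s = times,
                              label = u$label, electrode_id = u$electrode_id,
                              group = u$group)
    wf <- render_waveform_snippets(u, n_snippets = 50,
                                   noise_sd = config$waveform_noise_sd,
                                   seed = (config$seed * 1000003 +
                                             stable_hash(u$unit_id) + 1L) %% 2147483647,
                                   sample_rate = config$sample_rate)
    wf_rows[[i]] <- mutate(wf, unit_id = u$unit_id, .before = 1)
  }

  structure(list(
    units = population, geometry = geometry,
    spikes = arrange(bind_rows(spike_rows), .data$unit_id, .data$time_s),
    events = events, stimulus = stim,
    envelope = tibble(t_s = (seq_len(n_grid) - 1) / fs_env, value = env_sess),
    waveforms = bind_rows(wf_rows),
    duration_s = duration, config = config
  ), class = "ecog_session")
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf("<ecog_session> %d units, %d spikes, %d trials, %.1f s\n",
              nrow(x$units), nrow(x$spikes), nrow(x$events), x$duration_s))
  invisible(x)
}

#' Render an average action-potential waveform for one unit
#'
#' Builds a biphasic difference-of-Gaussians template (a negative peak, the
#' initial depolarization, followed by a positive trough) whose extrema match
#' the unit's `peak_amp_uV`/`trough_amp_uV` and whose peak-to-trough interval
#' matches `duration_s`, then averages `n_snippets` noisy realisations, as an
#' average over uniformly sampled spike events would.
#'
#' @param unit One-row tibble (or list) with `peak_amp_uV` (negative),
#'   `trough_amp_uV` (positive) and `duration_s`.
#' @param n_snippets Number of snippets averaged (>= 1).
#' @param noise_sd Per-sample i.i.d. noise, microvolts (>= 0).
#' @param seed Optional integer seed.
#' @param sample_rate Waveform sample rate, Hz.
#' @return Tibble with `time_ms` and `uV` (the snippet average).
#' @export
#' @examples
#' u <- list(peak_amp_uV = -40, trough_amp_uV = 20, duration_s = 4e-4)
#' wf <- render_waveform_snippets(u, n_snippets = 10, noise_sd = 0)
#' waveform_features(wf)
render_waveform_snippets <- function(unit, n_snippets = 50, noise_sd = 5,
                                     seed = NULL, sample_rate = 30000) {
  if (n_snippets < 1) abort("`n_snippets` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  peak <- unit$peak_amp_uV
  trough <- unit$trough_amp_uV
  dur <- unit$duration_s
  if (!(peak < 0 && trough > 0 && dur > 0))
    abort("Unit waveform parameters must satisfy peak < 0 < trough, duration > 0.")
  s1 <- dur / 4
  s2 <- dur / 2.5
  dt <- 1 / sample_rate
  t <- seq(-2 * dur, 3.5 * dur, by = dt)
  g1 <- exp(-t^2 / (2 * s1^2))
  g2 <- exp(-(t - dur)^2 / (2 * s2^2))
  # fixed point so the realised extrema equal the requested amplitudes even
  # when the two lobes overlap
  a <- peak; b <- trough
  for (it in 1:3) {
    w <- a * g1 + b * g2
    ip <- which.min(w)
    after <- seq(ip + 1L, length(w))
    itr <- ip + which.max(w[after])
    M <- rbind(c(g1[ip], g2[ip]), c(g1[itr], g2[itr]))
    if (abs(det(M)) < 1e-12) break
    ab <- solve(M, c(peak, trough))
    a <- ab[1]; b <- ab[2]
  }
  template <- a * g1 + b * g2
  if (!is.null(seed)) set.seed(seed)
  avg <- if (noise_sd > 0) {
    template + rowMeans(matrix(rnorm(length(template) * n_snippets, 0, noise_sd),
                               nrow = length(template)))
  } else template
  tibble(time_ms = (t - t[1]) * 1000, uV = avg)
}

#' Write / read a session directory of plain CSV files
#'
#' `write_session()` saves a simulated (or assembled) session as
#' `spikes.csv`, `units.csv`, `events.csv`, `envelope.csv`, `geometry.csv`
#' and `waveforms.csv`; `read_session()` restores it.
#'
#' @param session An `ecog_session` list.
#' @param dir Directory path (created if missing).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns an `ecog_session` list.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$units, file.path(dir, "units.csv"), row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(session$envelope, file.path(dir, "envelope.csv"), row.names = FALSE)
  utils::write.csv(session$geometry, file.path(dir, "geometry.csv"), row.names = FALSE)
  utils::write.csv(session$waveforms, file.path(dir, "waveforms.csv"), row.names = FALSE)
  writeLines(sprintf("duration_s,%.9f", session$duration_s),
             file.path(dir, "session.csv"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  rd <- function(f) as_tibble(utils::read.csv(file.path(dir, f)))
  meta <- utils::read.csv(file.path(dir, "session.csv"), header = FALSE)
  structure(list(
    units = rd("units.csv"), geometry = rd("geometry.csv"),
    spikes = rd("spikes.csv"), events = rd("events.csv"),
    stimulus = NULL, envelope = rd("envelope.csv"),
    waveforms = rd("waveforms.csv"),
    duration_s = as.numeric(meta$V2[1]), config = NULL
  ), class = "ecog_session")
}
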