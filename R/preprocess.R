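# ---- time-series helpers ----------------------------------------------------

# accept either a tibble (t_s, value) or a bare numeric vector + sample_rate
ts_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) abort("Time-series data frame needs a `value` column.")
    x$value
  } else as.numeric(x)
}

ts_rate <- function(x, sample_rate = NULL) {
  if (!is.null(sample_rate)) return(sample_rate)
  if (is.data.frame(x) && "t_s" %in% names(x) && nrow(x) > 1)
    return(1 / median(diff(x$t_s)))
  abort("Supply `sample_rate` (or a `t_s` column it can be inferred from).")
}

ts_start <- function(x) if (is.data.frame(x) && "t_s" %in% names(x)) x$t_s[1] else 0

# forward-backward IIR filtering with odd-reflection padding and steady-state
# initial conditions (the padded record is treated as if it had sat at its
# first value forever), so edge transients are fully suppressed. The pad
# length scales with the filter's slowest corner frequency `f_char` so the
# remaining transient decays below numerical noise inside the pad.
filtfilt_refl <- function(b, a, x, fs, f_char) {
  n <- length(x)
  pad <- min(as.integer(ceiling(25 * fs / f_char)), n - 1L)
  dc <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1),
                              init.y = rep(z[1] * dc, length(a) - 1)))
  }
  xe <- c(2 * x[1] - x[seq(pad + 1L, 2L)], x,
          2 * x[n] - x[seq(n - 1L, n - pad)])
  y <- rev(pass(rev(pass(xe))))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase Butterworth high-pass filter
#'
#' Filters forward and backward with a Butterworth high-pass (3rd order,
#' 300 Hz cutoff by default), giving a sharp cutoff without phase
#' distortion. Edges are handled by odd-reflection padding with
#' steady-state filter initialization.
#'
#' @param x Tibble with `t_s`/`value` columns, or a numeric vector (then
#'   `sample_rate` is required).
#' @param cutoff High-pass cutoff, Hz; must be below Nyquist.
#' @param order Filter order.
#' @param sample_rate Sample rate, Hz (inferred from `t_s` when omitted).
#' @return Tibble with `t_s` and filtered `value`, same length as the input.
#' @export
#' @examples
#' fs <- 20000
#' x <- tibble::tibble(t_s = (0:999) / fs, value = sin(2 * pi * 1000 * (0:999) / fs))
#' y <- highpass_zero_phase(x)
highpass_zero_phase <- function(x, cutoff = 300, order = 3, sample_rate = NULL) {
  fs <- ts_rate(x, sample_rate)
  if (cutoff >= fs / 2) abort("`cutoff` must be below the Nyquist frequency.")
  check_scalar(order, "order", positive = TRUE)
  v <- ts_values(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  y <- filtfilt_refl(bf$b, bf$a, v, fs, cutoff)
  tibble(t_s = ts_start(x) + (seq_along(y) - 1) / fs, value = y)
}

#' Detect stimulus onsets from a sync-tone channel
#'
#' The playback system records a 1-5 kHz sync waveform alongside the neural
#' data; each tone burst marks one stimulus onset. The channel is band-pass
#' filtered, rectified, and thresholded at `threshold_frac` times the 95th
#' percentile of the rectified magnitude (robust to overall amplitude
#' scaling); one onset is reported per burst, with a refractory period
#' between detections.
#'
#' @param sync Tibble with `t_s`/`value`, or numeric vector plus `sample_rate`.
#' @param band Band-pass corner frequencies, Hz.
#' @param threshold_frac Fraction of the 95th-percentile magnitude.
#' @param refractory_s Minimum separation between detections, seconds.
#' @param sample_rate Sample rate, Hz.
#' @return Tibble with a single `onset_s` column (empty on silence).
#' @export
detect_stimulus_onsets <- function(sync, band = c(1000, 5000),
                                   threshold_frac = 0.5, refractory_s = 1,
                                   sample_rate = NULL) {
  fs <- ts_rate(sync, sample_rate)
  if (band[2] >= fs / 2) abort("Upper band edge must be below Nyquist.")
  v <- ts_values(sync)
  if (max(abs(v)) == 0) return(tibble(onset_s = numeric(0)))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  m <- abs(filtfilt_refl(bf$b, bf$a, v, fs, band[1]))
  thr <- threshold_frac * quantile(m, 0.95, names = FALSE)
  if (thr <= 0) return(tibble(onset_s = numeric(0)))
  cand <- which(m > thr)
  keep <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if ((i - last) / fs >= refractory_s) keep <- c(keep, i)
    last <- i
  }
  tibble(onset_s = ts_start(sync) + (keep - 1) / fs)
}

# analytic signal via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of an audio stimulus
#'
#' Estimates the stimulus amplitude envelope as the magnitude of the
#' analytic signal (Hilbert transform), zero-phase low-pass filtered and
#' resampled to the 200 Hz grid shared with the 5 ms binned spike counts.
#' Values are clipped at zero.
#'
#' @param audio Tibble with `t_s`/`value`, or numeric vector plus
#'   `sample_rate`. Sample rate must exceed 400 Hz.
#' @param lowpass_cutoff Low-pass cutoff, Hz; must be below half the target
#'   rate (the cutoff is unstated in the protocol this mirrors; 50 Hz keeps
#'   syllable-scale modulation and respects the 100 Hz target Nyquist).
#' @param target_rate Output envelope rate, Hz.
#' @param sample_rate Input sample rate, Hz.
#' @return Tibble with `t_s` and nonnegative `value` at `target_rate`.
#' @export
amplitude_envelope <- function(audio, lowpass_cutoff = 50, target_rate = 200,
                               sample_rate = NULL) {
  fs <- ts_rate(audio, sample_rate)
  if (fs <= 400) abort("Audio sample rate must exceed 400 Hz.")
  if (lowpass_cutoff >= target_rate / 2)
    abort("`lowpass_cutoff` must be below the target Nyquist (target_rate / 2).")
  v <- ts_values(audio)
  mag <- Mod(analytic_signal(v))
  bf <- signal::butter(4, lowpass_cutoff / (fs / 2), type = "low")
  sm <- filtfilt_refl(bf$b, bf$a, mag, fs, lowpass_cutoff)
  # the series is already zero-phase band-limited below the target Nyquist,
  # so resampling reduces to delay-free evaluation on the 200 Hz grid
  t_in <- (seq_along(sm) - 1) / fs
  t_out <- seq(0, t_in[length(t_in)], by = 1 / target_rate)
  y <- pmax(stats::approx(t_in, sm, xout = t_out)$y, 0)
  tibble(t_s = ts_start(audio) + t_out, value = y)
}
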