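# ---- trial-aligned spike counts ---------------------------------------------

#' Trial-aligned binned spike counts
#'
#' Counts spikes in 5 ms bins within a window around each stimulus onset
#' (200 ms before to 300 ms after, by default). Bins are half-open:
#' `[onset + edge, onset + edge + bin)`.
#'
#' @param t Spike times (numeric seconds or tibble with `time_s`).
#' @param onsets Stimulus onset times (numeric seconds or tibble with
#'   `onset_s`); assumed sorted.
#' @param window `(t_pre, t_post)` in seconds relative to onset.
#' @param bin_ms Bin width, ms.
#' @return Object of class `trial_counts`: a list with `counts`
#'   (trials x bins integer matrix), `window`, `bin_s` and `onsets`.
#'   Overlapping trial windows raise a warning but all trials are kept.
#' @export
#' @examples
#' tc <- bin_counts(c(0.012), onsets = 0, window = c(-0.2, 0.3))
#' sum(tc$counts)
bin_counts <- function(t, onsets, window = c(-0.2, 0.3), bin_ms = 5) {
  if (is.data.frame(t)) t <- t$time_s
  if (is.data.frame(onsets)) onsets <- onsets$onset_s
  if (bin_ms <= 0) abort("`bin_ms` must be > 0.")
  if (window[2] <= window[1]) abort("`window` must satisfy t_pre < t_post.")
  bin_s <- bin_ms / 1000
  nbins <- round((window[2] - window[1]) / bin_s)
  if (length(onsets) > 1 && any(diff(onsets) < (window[2] - window[1])))
    warn("Trial windows overlap; trials kept as-is.")
  counts <- matrix(0L, nrow = length(onsets), ncol = nbins)
  t <- sort(t)
  for (i in seq_along(onsets)) {
    rel <- t - onsets[i] - window[1]
    sel <- rel >= 0 & rel < (window[2] - window[1])
    if (any(sel)) {
      idx <- pmin(floor(rel[sel] / bin_s) + 1L, nbins)
      counts[i, ] <- tabulate(idx, nbins = nbins)
    }
  }
  structure(list(counts = counts, window = window, bin_s = bin_s,
                 onsets = onsets), class = "trial_counts")
}

#' @export
print.trial_counts <- function(x, ...) {
  cat(sprintf("<trial_counts> %d trials x %d bins (%.0f ms), window [%g, %g] s\n",
              nrow(x$counts), ncol(x$counts), x$bin_s * 1000,
              x$window[1], x$window[2]))
  invisible(x)
}

#' @describeIn bin_counts Long-format view of the count matrix.
#' @param x A `trial_counts`.
#' @param ... Unused.
#' @method tidy trial_counts
#' @export
tidy.trial_counts <- function(x, ...) {
  tibble(
    trial = rep(seq_len(nrow(x$counts)), ncol(x$counts)),
    t_s = rep(x$window[1] + (seq_len(ncol(x$counts)) - 1) * x$bin_s,
              each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
}

#' Trial-averaged, smoothed spike count series
#'
#' Per-bin mean across trials followed by a centred moving-average filter
#' (5 taps by default; windows shrink at the edges so constants pass
#' through unchanged). With 5 ms bins the output lives on a 200 Hz grid.
#'
#' @param tc A `trial_counts` from [bin_counts()] (>= 1 trial).
#' @param taps Moving-average length in bins.
#' @return Tibble with `t_s` (bin left edges relative to onset), `raw`
#'   (trial mean) and `value` (smoothed trial mean).
#' @export
trial_average_smooth <- function(tc, taps = 5) {
  stopifnot(inherits(tc, "trial_counts"))
  if (nrow(tc$counts) < 1) abort("At least one trial is required.")
  avg <- colMeans(tc$counts)
  tibble(
    t_s = tc$window[1] + (seq_along(avg) - 1) * tc$bin_s,
    raw = avg,
    value = smooth_boxcar(avg, taps)
  )
}

# ---- lag estimation ---------------------------------------------------------

#' Estimate the neural response lag from the stimulus envelope
#'
#' Cross-correlates the trial-averaged smoothed spike count with the
#' stimulus amplitude envelope over lags from 0 up to (but excluding)
#' 200 ms, on the shared 5 ms grid, and returns the lag of the maximal
#' absolute correlation. Lags beyond 200 ms are treated as physiologically
#' implausible and not searched. Downstream analyses shift the envelope
#' forward by this lag so response and stimulus are coherent.
#'
#' @param avg Smoothed average series (tibble with `value` or numeric).
#' @param env Envelope on the same 200 Hz grid and alignment (tibble with
#'   `value` or numeric).
#' @param max_lag_ms Upper lag bound (exclusive), ms.
#' @param bin_ms Grid step, ms.
#' @return Lag in ms. Zero variance in either series is an error.
#' @export
estimate_lag <- function(avg, env, max_lag_ms = 200, bin_ms = 5) {
  a <- ts_values(avg)
  e <- ts_values(env)
  n <- min(length(a), length(e))
  a <- a[seq_len(n)]; e <- e[seq_len(n)]
  if (sd(a) == 0 || sd(e) == 0)
    abort("Zero variance input; lag undefined.")
  lags <- seq(0L, as.integer(max_lag_ms / bin_ms) - 1L)
  rs <- vapply(lags, function(l) {
    k <- seq(l + 1L, n)
    if (length(k) < 3 || sd(a[k]) == 0 || sd(e[k - l]) == 0) return(NA_real_)
    cor(a[k], e[k - l])
  }, numeric(1))
  if (all(is.na(rs))) abort("Lag undefined: no valid overlap.")
  lags[which.max(abs(rs))] * bin_ms
}

# ---- onset-window correlation -----------------------------------------------

#' Onset-window Pearson correlation with Bonferroni control
#'
#' Pearson correlation between the average spike count and the (lag-shifted)
#' stimulus envelope over the onset window, with Bonferroni correction for
#' the family of tests performed in the run. A response is significant when
#' the corrected p-value is at or below `alpha` (0.01).
#'
#' Because the averaged count series is smoothed before correlating, its
#' samples are serially correlated and the textbook t test on `r` would be
#' anti-conservative. By default the p-value therefore uses an
#' effective-sample-size correction (the Pyper-Peterman cross-correlation
#' adjustment, estimated from the sample autocorrelations of both series);
#' `autocorr_adjust = FALSE` restores the naive test.
#'
#' @param avg Averaged (smoothed) spike-count series over the window.
#' @param env_shifted Envelope over the same window, already shifted by the
#'   response lag.
#' @param n_tests Bonferroni family size (>= 1).
#' @param alpha Corrected significance level.
#' @param autocorr_adjust Use the effective-sample-size p-value.
#' @return One-row tibble: `r`, `p_raw`, `p_adj`, `n_eff`, `significant`.
#'   Zero variance in either series gives `r = NA`, not significant.
#' @export
onset_window_correlation <- function(avg, env_shifted, n_tests = 1,
                                     alpha = 0.01, autocorr_adjust = TRUE) {
  if (n_tests < 1) abort("`n_tests` must be >= 1.")
  a <- ts_values(avg)
  e <- ts_values(env_shifted)
  n <- min(length(a), length(e))
  a <- a[seq_len(n)]; e <- e[seq_len(n)]
  if (n < 5 || sd(a) == 0 || sd(e) == 0) {
    return(tibble(r = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                  n_eff = NA_real_, significant = FALSE))
  }
  r <- cor(a, e)
  n_eff <- n
  if (autocorr_adjust) {
    # noise autocorrelation is estimated from the residuals after removing
    # the envelope-locked component, so a strong genuine response does not
    # inflate its own penalty
    res <- stats::residuals(stats::lm(a ~ e))
    K <- max(1L, floor(n / 5))
    ra <- as.numeric(stats::acf(res, lag.max = K, plot = FALSE)$acf)[-1]
    re <- as.numeric(stats::acf(e, lag.max = K, plot = FALSE)$acf)[-1]
    denom <- max(1, 1 + 2 * sum(ra * re))
    n_eff <- max(5, n / denom)
  }
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n_eff - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n_eff - 2)
  }
  p_adj <- min(1, p * n_tests)
  tibble(r = r, p_raw = p, p_adj = p_adj, n_eff = n_eff,
         significant = p_adj <= alpha)
}

# ---- effect size ------------------------------------------------------------

#' Stimulus-response effect size
#'
#' `(mu_peak - mu_base) / sigma_base`, where `mu_peak` is the average 5 ms
#' spike count in a window of +/- 50 ms about the peak response, `mu_base`
#' the average 5 ms count in a 1 s baseline window before stimulus onset,
#' and `sigma_base` the standard deviation of the baseline counts
#' (population normalization over the baseline bins).
#'
#' @param peak_counts Per-bin (trial-averaged) counts in the peak window.
#' @param baseline_counts Per-bin (trial-averaged) counts in the baseline
#'   window; must have positive variance.
#' @return Dimensionless effect size.
#' @export
#' @examples
#' effect_size(rep(3, 21), rep(c(0, 2), 100))
effect_size <- function(peak_counts, baseline_counts) {
  b <- ts_values(baseline_counts)
  p <- ts_values(peak_counts)
  sig <- sqrt(mean((b - mean(b))^2))
  if (sig == 0) abort("Baseline counts have zero variance; effect size undefined.")
  (mean(p) - mean(b)) / sig
}

# time (s, relative to onset) of the maximal smoothed-average bin centre
# within the search window; earliest bin on ties
peak_response_time <- function(avg, search = c(0, 0.3)) {
  sel <- which(avg$t_s >= search[1] & avg$t_s < search[2])
  if (length(sel) == 0) abort("Peak search window is empty.")
  i <- sel[which.max(avg$value[sel])]
  avg$t_s[i] + (avg$t_s[2] - avg$t_s[1]) / 2
}

#' Stimulus envelope values on an onset-aligned time grid
#'
#' Looks up the onset-aligned stimulus envelope at arbitrary times (seconds
#' relative to stimulus onset); times outside the stimulus return 0. Useful
#' for aligning the envelope with PSTH windows, including negative (pre-
#' onset) times and lag-shifted grids.
#'
#' @param stim Envelope tibble (`t_s`, `value`) starting at onset.
#' @param tvec Times (s, onset-aligned) at which to evaluate.
#' @param rate Envelope sample rate, Hz.
#' @return Numeric vector of envelope values.
#' @export
stim_env_at_grid <- function(stim, tvec, rate = 200) {
  idx <- round(tvec * rate) + 1L
  out <- numeric(length(tvec))
  ok <- idx >= 1L & idx <= length(stim$value)
  out[ok] <- stim$value[idx[ok]]
  out
}

# ---- per-unit response pipeline ---------------------------------------------

#' Stimulus-evoked response summary per unit
#'
#' Runs the full onset-response quantification for every unit in a session:
#' trial-aligned 5 ms counts, trial averaging and smoothing, response-lag
#' estimation against the stimulus envelope (lags below 200 ms), Pearson
#' correlation over the onset window (200 ms pre to 300 ms post) with the
#' lag-shifted envelope under Bonferroni control, and the effect size about
#' the peak response.
#'
#' @param session An `ecog_session` (needs `stimulus`, the onset-aligned
#'   envelope).
#' @param alpha Corrected significance level.
#' @param n_tests Bonferroni family size; default number of analysed units
#'   times number of distinct stimuli (the most conservative per-run family).
#' @param window Onset window, seconds relative to onset.
#' @param lag_window Window used for lag estimation; default `NULL` uses
#'   the full stimulus duration (the whole envelope).
#' @param smooth_taps Moving-average length.
#' @param label Unit label to analyse.
#' @param autocorr_adjust See [onset_window_correlation()].
#' @return Tibble with one row per unit: `unit_id`, `group`, `lag_ms`,
#'   `pearson_r`, `p_raw`, `p_adj`, `significant`, `peak_time_s`,
#'   `effect_size`.
#' @export
response_summary <- function(session, alpha = 0.01, n_tests = NULL,
                             window = c(-0.2, 0.3), lag_window = NULL,
                             smooth_taps = 5, label = "SUA",
                             autocorr_adjust = TRUE) {
  units <- session$units[session$units$label == label, ]
  onsets <- session$events$onset_s
  n_stim <- max(1L, dplyr::n_distinct(session$events$stimulus_id))
  if (is.null(n_tests)) n_tests <- nrow(units) * n_stim
  stim <- session$stimulus
  bin_s <- 0.005
  if (is.null(lag_window))
    lag_window <- c(0, max(stim$t_s) + bin_s)
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    tr <- session$spikes$time_s[session$spikes$unit_id == u$unit_id]
    na_row <- tibble(unit_id = u$unit_id, group = u$group, lag_ms = NA_real_,
                     pearson_r = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                     significant = FALSE, peak_time_s = NA_real_,
                     effect_size = NA_real_)
    avg_lag <- trial_average_smooth(bin_counts(tr, onsets, lag_window), smooth_taps)
    env_lag <- stim_env_at_grid(stim, avg_lag$t_s)
    if (sd(avg_lag$value) == 0 || sd(env_lag) == 0) return(na_row)
    lag_ms <- estimate_lag(avg_lag$value, env_lag)

    avg <- trial_average_smooth(bin_counts(tr, onsets, window), smooth_taps)
    env_shift <- stim_env_at_grid(stim, avg$t_s - lag_ms / 1000)
    owc <- onset_window_correlation(avg$value, env_shift, n_tests = n_tests,
                                    alpha = alpha,
                                    autocorr_adjust = autocorr_adjust)
    pk <- peak_response_time(avg, search = c(0, window[2]))
    base <- colMeans(bin_counts(tr, onsets, c(-1, 0))$counts)
    peak <- colMeans(bin_counts(tr, onsets, c(pk - 0.05, pk + 0.05))$counts)
    es <- tryCatch(effect_size(peak, base), error = function(e) NA_real_)
    tibble(unit_id = u$unit_id, group = u$group, lag_ms = lag_ms,
           pearson_r = owc$r, p_raw = owc$p_raw, p_adj = owc$p_adj,
           significant = owc$significant, peak_time_s = pk,
           effect_size = es)
  })
}
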