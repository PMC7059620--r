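# ---- waveform shape ---------------------------------------------------------

#' Extracellular waveform shape features
#'
#' Computes the shape features used to characterise single units. By the
#' extracellular convention adopted here, the *peak* is the waveform minimum
#' (initial depolarization) and the *trough* is the maximum occurring
#' strictly after the peak; *duration* is the peak-to-trough interval,
#' *amplitude* the overall maximum minus minimum, *trough/peak* the ratio of
#' the two extreme values (negative for canonical biphasic spikes), and
#' *symmetry* the Pearson correlation between the mean-removed waveform and
#' its time-reversal (1 for a waveform even-symmetric about its midpoint).
#'
#' @param w Tibble with a time column (`time_ms`, `time_s` or `t_s`) and a
#'   voltage column (`uV` or `value`). If a `unit_id` column is present,
#'   features are computed per unit.
#' @return Tibble with one row per waveform: `duration_s`, `amplitude_uV`,
#'   `trough_peak_ratio`, `symmetry` (plus `unit_id` when supplied).
#'   Monotone waveforms with no post-peak trough are an error.
#' @export
#' @examples
#' u <- list(peak_amp_uV = -40, trough_amp_uV = 20, duration_s = 4e-4)
#' waveform_features(render_waveform_snippets(u, 1, noise_sd = 0))
waveform_features <- function(w) {
  stopifnot(is.data.frame(w))
  if ("unit_id" %in% names(w)) {
    return(w %>%
             group_by(.data$unit_id) %>%
             dplyr::group_modify(~ waveform_features_one(.x)) %>%
             ungroup())
  }
  waveform_features_one(w)
}

waveform_features_one <- function(w) {
  tcol <- intersect(c("time_ms", "time_s", "t_s"), names(w))[1]
  vcol <- intersect(c("uV", "value"), names(w))[1]
  if (is.na(tcol) || is.na(vcol))
    abort("Waveform needs a time column (time_ms/time_s/t_s) and uV/value.")
  t_s <- w[[tcol]] / if (tcol == "time_ms") 1000 else 1
  v <- w[[vcol]]
  n <- length(v)
  if (n < 8) abort("Waveform must have at least 8 samples.")
  ip <- which.min(v)
  if (ip == 1L || ip == n)
    abort("Waveform has no strict interior minimum (no post-peak trough).")
  after <- seq(ip + 1L, n)
  itr <- ip + which.max(v[after]) # earliest index on ties (which.max rule)
  vc <- v - mean(v)
  sym <- if (sd(vc) == 0) NA_real_ else cor(vc, rev(vc))
  tibble(
    duration_s = t_s[itr] - t_s[ip],
    amplitude_uV = max(v) - min(v),
    trough_peak_ratio = v[itr] / v[ip],
    symmetry = sym
  )
}

# ---- firing statistics ------------------------------------------------------

#' Mean spike rate
#'
#' Number of spikes divided by the recording duration in seconds.
#'
#' @param t Spike times: a numeric vector, or a tibble with `time_s` (and
#'   optionally `unit_id`, in which case one rate per unit is returned).
#' @param duration Recording duration, seconds (> 0).
#' @return A scalar rate in Hz, or a tibble `unit_id`/`n_spikes`/`rate_hz`.
#' @export
#' @examples
#' spike_rate(c(0.1, 0.5, 2), duration = 10)
spike_rate <- function(t, duration) {
  check_scalar(duration, "duration", positive = TRUE)
  if (is.data.frame(t)) {
    if ("unit_id" %in% names(t)) {
      return(t %>% group_by(.data$unit_id) %>%
               summarise(n_spikes = n(), rate_hz = n() / duration, .groups = "drop"))
    }
    t <- t$time_s
  }
  length(t) / duration
}

#' Refractory-period violation fraction
#'
#' Fraction of consecutive inter-spike intervals at or below the refractory
#' period (2 ms by default). A well-isolated single unit has little to no
#' spikes 0-2 ms after spiking, so this fraction is a quality-control number
#' for SUA labels. Trains with fewer than two spikes return 0 by convention.
#'
#' @param t Numeric spike times (seconds) or a tibble with `time_s`.
#' @param refractory Refractory period, seconds.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' refractory_violation_fraction(c(0, 0.001, 0.010))
refractory_violation_fraction <- function(t, refractory = 0.002) {
  if (is.data.frame(t)) t <- t$time_s
  if (length(t) < 2) return(0)
  mean(diff(sort(t)) <= refractory)
}

# ---- log-ISI burst statistics ----------------------------------------------

# boxcar smoothing with a shrinking window at the edges
smooth_boxcar <- function(v, k) {
  if (k <= 1) return(v)
  h <- (k - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Normalized log inter-spike-interval density
#'
#' Histogram of log10(ISI) over a fixed range of decades, boxcar-smoothed
#' and normalized to sum to 1. The log scale captures both short (intra-burst)
#' and long (between-burst) spike-timing structure: bursting units show a
#' bimodal density, regular units a unimodal one.
#'
#' @param t Numeric spike times (seconds) or a tibble with `time_s`.
#' @param bins_per_decade Histogram resolution.
#' @param smooth Odd boxcar width in bins.
#' @param range_decades Range of log10(ISI seconds) covered.
#' @return Tibble with `log10_isi` (bin centres) and `density` (sums to 1
#'   whenever any ISI falls in range), with attribute `n_isi` giving the
#'   number of intervals used.
#' @export
log_isi_density <- function(t, bins_per_decade = 10, smooth = 3,
                            range_decades = c(-3.5, 1.5)) {
  if (is.data.frame(t)) t <- t$time_s
  isi <- diff(sort(t))
  isi <- isi[isi > 0]
  edges <- seq(range_decades[1], range_decades[2], by = 1 / bins_per_decade)
  centers <- edges[-length(edges)] + 0.5 / bins_per_decade
  l <- log10(isi)
  l <- l[l >= range_decades[1] & l < range_decades[2]]
  counts <- tabulate(findInterval(l, edges), nbins = length(centers))
  d <- smooth_boxcar(as.numeric(counts), smooth)
  if (sum(d) > 0) d <- d / sum(d)
  out <- tibble(log10_isi = centers, density = d)
  attr(out, "n_isi") <- length(isi)
  out
}

# local maxima with their topographic prominence
local_peaks <- function(d) {
  n <- length(d)
  idx <- which(vapply(seq_len(n), function(i) {
    (i == 1 || d[i] > d[i - 1]) && (i == n || d[i] >= d[i + 1]) && d[i] > 0
  }, logical(1)))
  prom <- vapply(idx, function(p) {
    lmin <- d[p]; i <- p
    while (i > 1 && d[i - 1] <= d[p]) { i <- i - 1; lmin <- min(lmin, d[i]) }
    if (i == 1) lmin <- min(d[1:p])
    rmin <- d[p]; i <- p
    while (i < n && d[i + 1] <= d[p]) { i <- i + 1; rmin <- min(rmin, d[i]) }
    if (i == n) rmin <- min(d[p:n])
    d[p] - max(lmin, rmin)
  }, numeric(1))
  list(idx = idx, prominence = prom)
}

#' Void parameter of a log-ISI density
#'
#' Locates the two most prominent local maxima of the smoothed log-ISI
#' density g(.) and returns `1 - g(minimum) / sqrt(g(peak1) * g(peak2))`,
#' where g(minimum) is the density minimum strictly between the two peaks.
#' Values near 1 indicate a deeply bimodal density, i.e. bursting. If fewer
#' than two sufficiently prominent peaks exist the statistic is undefined
#' and `NA` is returned (callers classify such units as non-bursting).
#'
#' @param profile Tibble from [log_isi_density()].
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   maximum density.
#' @return A number in \[0, 1\], or `NA_real_` when undefined.
#' @export
#' @examples
#' t <- cumsum(rep(c(0.003, 0.003, 1), 50))
#' void_parameter(log_isi_density(t))
void_parameter <- function(profile, min_prominence_frac = 0.05) {
  d <- profile$density
  if (all(d == 0)) return(NA_real_)
  pk <- local_peaks(d)
  keep <- pk$prominence >= min_prominence_frac * max(d)
  idx <- pk$idx[keep]
  prom <- pk$prominence[keep]
  if (length(idx) < 2) return(NA_real_)
  top <- idx[order(prom, decreasing = TRUE)[1:2]]
  i1 <- min(top); i2 <- max(top)
  if (i2 - i1 < 2) return(NA_real_) # no bin strictly between the peaks
  g_min <- min(d[(i1 + 1):(i2 - 1)])
  v <- 1 - g_min / sqrt(d[i1] * d[i2])
  min(max(v, 0), 1)
}

#' Classify a unit as bursting from its void parameter
#'
#' @param void Void parameter value(s); `NA` means undefined.
#' @param threshold Classification threshold (convention of the log-ISI
#'   burst-characterization literature).
#' @return Logical: `TRUE` iff the void parameter is defined and at least
#'   the threshold.
#' @export
classify_bursting <- function(void, threshold = 0.7) {
  !is.na(void) & void >= threshold
}

# ---- yield ------------------------------------------------------------------

#' Electrode unit yield
#'
#' Percentage of functional electrodes on which at least one unit of each
#' quality class was found: `100 * n_electrodes_with_class / n_functional`.
#'
#' @param labels Tibble with `electrode_id` and `label` (one row per unit).
#' @param n_functional Total number of functional electrodes (>= 1).
#' @return Tibble with `label`, `n_electrodes`, `yield_pct`.
#' @export
#' @examples
#' unit_yield(tibble::tibble(electrode_id = c("e1", "e2", "e2"),
#'                           label = c("SUA", "SUA", "MUA")), 29)
unit_yield <- function(labels, n_functional) {
  if (length(n_functional) != 1 || n_functional < 1)
    abort("`n_functional` must be a count >= 1.")
  labels %>%
    group_by(.data$label) %>%
    summarise(n_electrodes = dplyr::n_distinct(.data$electrode_id),
              .groups = "drop") %>%
    mutate(yield_pct = 100 * .data$n_electrodes / n_functional)
}

# ---- per-unit feature table -------------------------------------------------

#' Per-unit characterization table
#'
#' Combines waveform shape features, spike rate, refractory QC and the
#' void-parameter burst classification into one row per unit. Units with
#' fewer than 20 ISIs are non-bursting by convention (the void parameter is
#' left undefined).
#'
#' @param session An `ecog_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param burst_threshold Void-parameter threshold for [classify_bursting()].
#' @param min_isis Minimum ISIs required for burst classification.
#' @return Tibble with one row per unit: identifiers, group, waveform
#'   features, `rate_hz`, `refractory_violation`, `void`, `bursting`.
#' @export
unit_features <- function(session, burst_threshold = 0.7, min_isis = 20) {
  units <- session$units
  dur <- session$duration_s
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    tr <- session$spikes$time_s[session$spikes$unit_id == u$unit_id]
    wf <- session$waveforms[session$waveforms$unit_id == u$unit_id,
                            c("time_ms", "uV")]
    feats <- if (nrow(wf) >= 8) waveform_features(wf) else
      tibble(duration_s = NA_real_, amplitude_uV = NA_real_,
             trough_peak_ratio = NA_real_, symmetry = NA_real_)
    void <- if (length(tr) >= min_isis + 1) void_parameter(log_isi_density(tr))
            else NA_real_
    dplyr::bind_cols(
      tibble(unit_id = u$unit_id, group = u$group,
             electrode_id = u$electrode_id, label = u$label),
      feats,
      tibble(rate_hz = spike_rate(tr, dur),
             refractory_violation = refractory_violation_fraction(tr),
             void = void,
             bursting = classify_bursting(void, burst_threshold))
    )
  })
}
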