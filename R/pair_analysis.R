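# ---- cross-correlogram ------------------------------------------------------

spike_times_of <- function(t) {
  if (is.data.frame(t)) t <- t$time_s
  sort(as.numeric(t))
}

restrict_to_periods <- function(t, periods) {
  if (is.null(periods)) return(t)
  keep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(periods)))
    keep <- keep | (t >= periods$start[i] & t <= periods$end[i])
  t[keep]
}

#' Spike-train cross-correlogram
#'
#' Counts, for every spike pair, the number of times unit `y` (by
#' convention the surface unit) fired before or after unit `x` (the depth
#' unit): each pair with `ty - tx` inside `[-max_lag, max_lag)` ms
#' increments the half-open 5 ms bin containing `ty - tx`. Positive lags
#' therefore mean the surface unit fired after the depth unit. Counts are
#' raw co-occurrence counts, not rates.
#'
#' @param x,y Spike times (numeric seconds, or tibbles with `time_s`).
#' @param bin_ms Bin width, ms (> 0).
#' @param max_lag_ms Maximum absolute lag, ms.
#' @param periods Optional tibble with `start`/`end` columns (seconds);
#'   both spikes of a pair must fall inside an analysis period. `NULL`
#'   uses the whole recording (baseline plus stimulus).
#' @return Tibble of class `correlogram` with `lag_ms` (bin centres) and
#'   `count`.
#' @export
#' @examples
#' cc <- cross_correlogram(c(0, 1), c(0.002, 1.002))
#' correlogram_peak_lag(cc)
cross_correlogram <- function(x, y, bin_ms = 5, max_lag_ms = 100,
                              periods = NULL) {
  if (bin_ms <= 0) abort("`bin_ms` must be > 0.")
  xs <- restrict_to_periods(spike_times_of(x), periods)
  ys <- restrict_to_periods(spike_times_of(y), periods)
  edges <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  centers <- edges[-length(edges)] + bin_ms / 2
  counts <- integer(length(centers))
  if (length(xs) > 0 && length(ys) > 0) {
    ml_s <- max_lag_ms / 1000
    i1 <- findInterval(xs - ml_s - 1e-9, ys)
    i2 <- findInterval(xs + ml_s + 1e-9, ys)
    nper <- i2 - i1
    take <- nper > 0
    if (any(take)) {
      idx <- sequence(nvec = nper[take], from = i1[take] + 1L)
      d_ms <- (ys[idx] - rep(xs[take], nper[take])) * 1000
      d_ms <- d_ms[d_ms >= -max_lag_ms & d_ms < max_lag_ms]
      counts <- tabulate(findInterval(d_ms, edges), nbins = length(centers))
    }
  }
  structure(tibble(lag_ms = centers, count = as.integer(counts)),
            class = c("correlogram", class(tibble())))
}

#' Peak lag of a cross-correlogram
#'
#' Centre of the maximal-count bin. Ties are broken deterministically by
#' the smallest absolute lag, then by the negative lag before the positive.
#'
#' @param cc A `correlogram` from [cross_correlogram()].
#' @return Peak lag in ms. An all-zero correlogram is an error.
#' @export
correlogram_peak_lag <- function(cc) {
  if (all(cc$count == 0)) abort("Correlogram has no counts; peak undefined.")
  cand <- cc$lag_ms[cc$count == max(cc$count)]
  cand[order(abs(cand), cand)][1]
}

# ---- SPIKE-distance ---------------------------------------------------------

# distance from each value in v to its nearest neighbour in sorted z
nn_dist <- function(v, z) {
  j <- findInterval(v, z)
  dl <- ifelse(j >= 1, v - z[pmax(j, 1)], Inf)
  dr <- ifelse(j < length(z), z[pmin(j + 1, length(z))] - v, Inf)
  pmin(dl, dr)
}

# dissimilarity profile terms for one train over the segments (a, b):
# tP = last spike <= a, tF = first spike >= b, plus nearest-neighbour
# distances of tP and tF to the other train's spikes
train_terms <- function(spk, other, a, b) {
  iP <- findInterval(a, spk)
  last_le <- findInterval(b, spk)
  iF <- ifelse(spk[pmax(last_le, 1)] == b & last_le >= 1, last_le, last_le + 1L)
  tP <- spk[iP]
  tF <- spk[iF]
  list(tP = tP, tF = tF, isi = tF - tP,
       dP = nn_dist(tP, other), dF = nn_dist(tF, other))
}

#' SPIKE-distance between two spike trains
#'
#' Parameter-free, time-resolved dissimilarity between two spike trains
#' over an observation interval, following the definition based on
#' previous/following spike time differences normalized by the local mean
#' inter-spike intervals and averaged over time. Auxiliary spikes are
#' placed at the interval edges. The measure is 0 for identical (or fully
#' synchronous) trains, symmetric, and bounded by 1; larger values indicate
#' increasingly dyssynchronous trains.
#'
#' The dissimilarity profile is piecewise linear between consecutive spike
#' events, so the time average is computed exactly segment by segment.
#'
#' @param x,y Spike times (numeric seconds, or tibbles with `time_s`);
#'   spikes outside the interval are ignored.
#' @param interval Length-2 numeric `(t0, t1)`, `t1 > t0`.
#' @return Distance in \[0, 1\]. If exactly one train has no spikes in the
#'   interval the distance is 1 by the edge-spike convention adopted here;
#'   if both are empty it is 0.
#' @export
#' @examples
#' spike_distance(c(1, 2, 3), c(1, 2, 3), interval = c(0, 4))
spike_distance <- function(x, y, interval) {
  if (length(interval) != 2 || !(interval[2] > interval[1]))
    abort("`interval` must be (t0, t1) with t1 > t0.")
  t0 <- interval[1]; t1 <- interval[2]
  xs <- spike_times_of(x); xs <- xs[xs >= t0 & xs <= t1]
  ys <- spike_times_of(y); ys <- ys[ys >= t0 & ys <= t1]
  if (length(xs) == 0 && length(ys) == 0) return(0)
  if (length(xs) == 0 || length(ys) == 0) return(1)
  xa <- unique(c(t0, xs, t1))
  ya <- unique(c(t0, ys, t1))
  e <- sort(unique(c(xa, ya)))
  a <- e[-length(e)]
  b <- e[-1]
  tx <- train_terms(xa, ya, a, b)
  ty <- train_terms(ya, xa, a, b)
  s_at <- function(tt, trm) (trm$dP * (trm$tF - tt) + trm$dF * (tt - trm$tP)) / trm$isi
  profile_at <- function(tt) {
    s1 <- s_at(tt, tx); s2 <- s_at(tt, ty)
    mean_isi <- (tx$isi + ty$isi) / 2
    (s1 * ty$isi + s2 * tx$isi) / (2 * mean_isi^2)
  }
  seg <- (profile_at(a) + profile_at(b)) / 2 * (b - a)
  sum(seg) / (t1 - t0)
}

# ---- geometry ---------------------------------------------------------------

#' Euclidean distance between two electrodes
#'
#' @param g Geometry tibble with `electrode_id`, `x_um`, `y_um`, `z_um`.
#' @param e1,e2 Electrode identifiers (vectorized, recycled).
#' @return Distance(s) in micrometres. Unknown electrodes are an error.
#' @export
#' @examples
#' physical_distance(default_geometry(), "s01", "d01")
physical_distance <- function(g, e1, e2) {
  i1 <- match(e1, g$electrode_id)
  i2 <- match(e2, g$electrode_id)
  if (anyNA(i1) || anyNA(i2))
    abort("Unknown electrode id(s) in `e1`/`e2`.")
  sqrt((g$x_um[i1] - g$x_um[i2])^2 +
         (g$y_um[i1] - g$y_um[i2])^2 +
         (g$z_um[i1] - g$z_um[i2])^2)
}

# ---- pair table -------------------------------------------------------------

#' Surface-depth pair analysis table
#'
#' Forms every (depth SUA, surface SUA) pair and computes, for each, the
#' SPIKE-distance over the analysis interval, the physical distance between
#' the electrodes the units were recorded on, and the cross-correlogram
#' peak lag. The Pearson correlation of SPIKE-distance versus physical
#' distance across pairs (with its p-value) is attached: a positive
#' correlation indicates that unit pairs recorded further apart are less
#' synchronous.
#'
#' @param session An `ecog_session`.
#' @param interval Analysis interval `(t0, t1)`; default the whole session.
#' @param periods Optional correlogram analysis periods (see
#'   [cross_correlogram()]); default baseline plus stimulus, i.e. all data.
#' @param label Unit quality label to include (default `"SUA"`).
#' @return Tibble of class `pair_table` with one row per pair
#'   (`depth_unit`, `surface_unit`, `spike_dist`, `physical_dist_um`,
#'   `peak_lag_ms`) and attributes `pearson_r`, `p_value`, `n_pairs`
#'   (see [glance.pair_table()]). With fewer than 3 pairs, or zero variance
#'   in either column, the correlation is undefined (`NA`).
#' @export
pair_table <- function(session, interval = NULL, periods = NULL,
                       label = "SUA") {
  units <- session$units
  if (is.null(interval)) interval <- c(0, session$duration_s)
  dep <- units[units$group == "depth" & units$label == label, ]
  sur <- units[units$group == "surface" & units$label == label, ]
  grid <- tidyr::expand_grid(depth_unit = dep$unit_id,
                             surface_unit = sur$unit_id)
  rows <- purrr::pmap_dfr(grid, function(depth_unit, surface_unit) {
    xd <- session$spikes$time_s[session$spikes$unit_id == depth_unit]
    ysf <- session$spikes$time_s[session$spikes$unit_id == surface_unit]
    ed <- units$electrode_id[units$unit_id == depth_unit]
    es <- units$electrode_id[units$unit_id == surface_unit]
    cc <- cross_correlogram(xd, ysf, periods = periods)
    tibble(
      depth_unit = depth_unit, surface_unit = surface_unit,
      spike_dist = spike_distance(xd, ysf, interval),
      physical_dist_um = physical_distance(session$geometry, ed, es),
      peak_lag_ms = if (all(cc$count == 0)) NA_real_ else correlogram_peak_lag(cc)
    )
  })
  r <- NA_real_; p <- NA_real_
  if (nrow(rows) >= 3 &&
      sd(rows$spike_dist) > 0 && sd(rows$physical_dist_um) > 0) {
    ct <- cor.test(rows$spike_dist, rows$physical_dist_um, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else if (nrow(rows) >= 3) {
    rlang::inform("Zero variance across pairs; correlation undefined.")
  }
  structure(rows, class = c("pair_table", class(tibble())),
            pearson_r = r, p_value = p, n_pairs = nrow(rows))
}

#' @describeIn pair_table One-row model summary: `pearson_r`, `p_value`,
#'   `n_pairs`.
#' @param x A `pair_table`.
#' @param ... Unused.
#' @method glance pair_table
#' @export
glance.pair_table <- function(x, ...) {
  tibble(pearson_r = attr(x, "pearson_r"),
         p_value = attr(x, "p_value"),
         n_pairs = attr(x, "n_pairs"))
}

#' @describeIn pair_table Per-pair records as a plain tibble.
#' @method tidy pair_table
#' @export
tidy.pair_table <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(x)], .name_repair = "minimal")
}
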