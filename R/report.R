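# ---- group tests ------------------------------------------------------------

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the smaller sample has at most 8 observations and
#' there are no ties; otherwise the continuity-corrected normal
#' approximation with tie correction (the two agree to about 0.01 at
#' n = m = 8).
#'
#' @param a,b Nonempty numeric samples.
#' @return Two-sided p-value.
#' @export
#' @examples
#' group_compare_ranksum(c(1, 2, 3), c(4, 5, 6))
group_compare_ranksum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be nonempty.")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Pearson chi-square statistic without continuity correction, df = 1,
#' upper-tail p-value.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return Upper-tail p-value.
#' @export
#' @examples
#' group_compare_chisquare(matrix(c(14, 9, 34, 12), 2, byrow = TRUE))
group_compare_chisquare <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2.")
  if (any(table < 0)) abort("Counts must be nonnegative.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort("Zero margin in contingency table.")
  suppressWarnings(chisq.test(table, correct = FALSE)$p.value)
}

# ---- formatting -------------------------------------------------------------

#' Format a bursting fraction as "k/n = p%"
#'
#' Percentages rounded to 0 decimal places.
#'
#' @param k,n Numerator and denominator counts.
#' @return Character string, e.g. `"14/23 = 61%"`.
#' @export
format_fraction <- function(k, n) {
  sprintf("%d/%d = %d%%", as.integer(k), as.integer(n), round(100 * k / n))
}

#' Format a p-value to two significant figures
#' @param p Numeric p-value(s).
#' @return Character.
#' @export
format_pvalue <- function(p) formatC(signif(p, 2), format = "g")

# ---- summary tables ---------------------------------------------------------

#' Group-comparison summary tables
#'
#' Builds the surface-versus-depth characterization table (duration, spike
#' rate, amplitude, trough/peak, symmetry compared by rank-sum; bursting
#' fractions by chi-square) plus pair-analysis and response summaries when
#' available. Both means and medians are reported for each feature.
#'
#' @param features Per-unit table from [unit_features()].
#' @param pairs Optional `pair_table`.
#' @param responses Optional table from [response_summary()].
#' @return A list with `unit_table` (one row per statistic), `pair_summary`
#'   and `response_summary` tibbles. Missing required columns raise an
#'   error naming the column; an empty unit set yields empty tables with
#'   headers.
#' @export
summary_tables <- function(features, pairs = NULL, responses = NULL) {
  needed <- c("group", "duration_s", "rate_hz", "amplitude_uV",
              "trough_peak_ratio", "symmetry", "bursting")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0)
    abort(sprintf("`features` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  empty <- tibble(statistic = character(), surface_mean = numeric(),
                  surface_median = numeric(), depth_mean = numeric(),
                  depth_median = numeric(), surface = character(),
                  depth = character(), p_value = numeric(), test = character())
  unit_table <- if (nrow(features) == 0) empty else {
    sur <- features[features$group == "surface", ]
    dep <- features[features$group == "depth", ]
    cont <- tibble(
      statistic = c("Duration (ms)", "Spike Rate (Hz)", "Amplitude (uV)",
                    "Trough/Peak", "Symmetry"),
      column = c("duration_s", "rate_hz", "amplitude_uV",
                 "trough_peak_ratio", "symmetry"),
      scale = c(1000, 1, 1, 1, 1)
    )
    rows <- purrr::pmap_dfr(cont, function(statistic, column, scale) {
      xs <- sur[[column]] * scale
      xd <- dep[[column]] * scale
      xs <- xs[!is.na(xs)]; xd <- xd[!is.na(xd)]
      p <- if (length(xs) > 0 && length(xd) > 0) group_compare_ranksum(xs, xd)
           else NA_real_
      tibble(statistic = statistic,
             surface_mean = mean(xs), surface_median = median(xs),
             depth_mean = mean(xd), depth_median = median(xd),
             surface = NA_character_, depth = NA_character_,
             p_value = p, test = "Rank sum")
    })
    ks <- sum(sur$bursting, na.rm = TRUE); ns <- nrow(sur)
    kd <- sum(dep$bursting, na.rm = TRUE); nd <- nrow(dep)
    tab <- matrix(c(ks, ns - ks, kd, nd - kd), 2, byrow = TRUE)
    p_chi <- tryCatch(group_compare_chisquare(tab), error = function(e) NA_real_)
    bind_rows(rows, tibble(
      statistic = "Bursts or Not",
      surface_mean = NA_real_, surface_median = NA_real_,
      depth_mean = NA_real_, depth_median = NA_real_,
      surface = format_fraction(ks, ns), depth = format_fraction(kd, nd),
      p_value = p_chi, test = "Chi-square"
    ))
  }
  pair_summary <- if (is.null(pairs)) NULL else glance(pairs)
  resp_summary <- if (is.null(responses) || nrow(responses) == 0) NULL else {
    responses %>%
      group_by(.data$group) %>%
      summarise(n_units = n(),
                n_significant = sum(.data$significant, na.rm = TRUE),
                median_r = median(.data$pearson_r[.data$significant], na.rm = TRUE),
                median_lag_ms = median(.data$lag_ms[.data$significant], na.rm = TRUE),
                median_effect = median(.data$effect_size[.data$significant], na.rm = TRUE),
                .groups = "drop")
  }
  list(unit_table = unit_table, pair_summary = pair_summary,
       response_summary = resp_summary)
}

# ---- plots ------------------------------------------------------------------

#' Diagnostic plots
#'
#' `plot_correlogram()` draws a cross-correlogram as a bar histogram;
#' `plot_psth()` shows the trial-averaged (smoothed) spike-count series;
#' `plot_distance_scatter()` plots SPIKE-distance against physical distance
#' across unit pairs with a linear trend. `autoplot()` methods dispatch to
#' these for `correlogram` and `pair_table` objects.
#'
#' @param cc A `correlogram`.
#' @return A ggplot object.
#' @export
plot_correlogram <- function(cc) {
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$lag_ms, y = .data$count)) +
    ggplot2::geom_col(width = diff(cc$lag_ms[1:2]) * 0.9, fill = "grey30") +
    ggplot2::labs(x = "Lag (ms), surface after depth", y = "Count") +
    ggplot2::theme_minimal()
}

#' @rdname plot_correlogram
#' @param avg Output of [trial_average_smooth()].
#' @export
plot_psth <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$raw), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from onset (s)", y = "Mean spike count / bin") +
    ggplot2::theme_minimal()
}

#' @rdname plot_correlogram
#' @param pairs A `pair_table`.
#' @export
plot_distance_scatter <- function(pairs) {
  ggplot2::ggplot(tidy(pairs),
                  ggplot2::aes(x = .data$physical_dist_um, y = .data$spike_dist)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Physical distance (um)", y = "SPIKE-distance") +
    ggplot2::theme_minimal()
}

#' @rdname plot_correlogram
#' @param object Object to plot.
#' @param ... Unused.
#' @method autoplot correlogram
#' @export
autoplot.correlogram <- function(object, ...) plot_correlogram(object)

#' @rdname plot_correlogram
#' @method autoplot pair_table
#' @export
autoplot.pair_table <- function(object, ...) plot_distance_scatter(object)
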