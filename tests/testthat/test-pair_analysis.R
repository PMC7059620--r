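test_that("cross-correlogram counts pairs into the correct half-open bins", {
  expect_true(all(cross_correlogram(numeric(0), c(1, 2))$count == 0))

  cc <- cross_correlogram(c(0, 1), c(0.002, 1.002))
  expect_equal(sum(cc$count), 2)
  expect_equal(cc$count[cc$lag_ms == 2.5], 2)
  expect_equal(correlogram_peak_lag(cc), 2.5)

  expect_error(cross_correlogram(1, 2, bin_ms = 0), "bin_ms")
  expect_error(correlogram_peak_lag(cross_correlogram(numeric(0), 1)), "undefined")
})

test_that("cross-correlogram equals the brute-force pair enumeration", {
  set.seed(33)
  for (k in 1:30) {
    x <- sort(runif(sample(1:60, 1), 0, 2))
    y <- sort(runif(sample(1:60, 1), 0, 2))
    expect_equal(cross_correlogram(x, y)$count, oracle_ccg(x, y)$count)
    # antisymmetry: ccg(x, y) at lag l = ccg(y, x) at -l
    expect_equal(cross_correlogram(x, y)$count,
                 rev(cross_correlogram(y, x)$count))
    # conservation: total counts = number of pairs with |dt| in range
    d <- as.vector(outer(y, x, "-")) * 1000
    expect_equal(sum(cross_correlogram(x, y)$count),
                 sum(d >= -100 & d < 100))
  }
})

test_that("peak-lag ties break toward zero, negative first", {
  cc <- cross_correlogram(c(0.5), c(0.5 - 0.002, 0.5 + 0.002))
  expect_equal(sort(cc$lag_ms[cc$count == 1]), c(-2.5, 2.5))
  expect_equal(correlogram_peak_lag(cc), -2.5)
})

test_that("correlogram respects analysis periods", {
  x <- c(0.5, 5.5)
  y <- c(0.52, 5.52)
  per <- tibble::tibble(start = 0, end = 1)
  cc <- cross_correlogram(x, y, periods = per)
  expect_equal(sum(cc$count), 1)
})

test_that("SPIKE-distance is zero for identical trains, symmetric and bounded", {
  expect_equal(spike_distance(c(1, 2, 3), c(1, 2, 3), c(0, 4)), 0)
  set.seed(44)
  for (k in 1:50) {
    x <- rpoisson_train(runif(1, 0.5, 10), 5)
    y <- rpoisson_train(runif(1, 0.5, 10), 5)
    d1 <- spike_distance(x, y, c(0, 5))
    expect_equal(d1, spike_distance(y, x, c(0, 5)), tolerance = 1e-12)
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
  # edge conventions for empty trains
  expect_equal(spike_distance(numeric(0), numeric(0), c(0, 1)), 0)
  expect_equal(spike_distance(numeric(0), c(0.5), c(0, 1)), 1)
  expect_error(spike_distance(1, 2, c(1, 1)), "interval")
})

test_that("SPIKE-distance matches the dense-grid numerical oracle", {
  set.seed(55)
  for (k in 1:12) {
    x <- rpoisson_train(runif(1, 2, 8), 4)
    y <- rpoisson_train(runif(1, 2, 8), 4)
    if (length(x) == 0 || length(y) == 0) next
    expect_equal(spike_distance(x, y, c(0, 4)),
                 oracle_spike_distance(x, y, c(0, 4)),
                 tolerance = 1e-3)
  }
})

test_that("physical distance is 3D Euclidean on the electrode table", {
  g <- default_geometry()
  expect_equal(physical_distance(g, "s01", "s01"), 0)
  expect_equal(physical_distance(g, "s01", "s02"), 200) # adjacent contacts
  g2 <- tibble::tibble(electrode_id = c("a", "b"), probe = c("surface", "depth"),
                       x_um = c(0, 300), y_um = c(0, 0), z_um = c(0, 520))
  expect_equal(physical_distance(g2, "a", "b"), sqrt(300^2 + 520^2))
  expect_equal(round(physical_distance(g2, "a", "b"), 1), 600.3)
  expect_error(physical_distance(g, "s01", "nope"), "Unknown")
})

test_that("pair_table emits one record per surface-depth pair with summary", {
  ses <- small_session()
  pt <- pair_table(ses)
  n_sur <- sum(ses$units$group == "surface")
  n_dep <- sum(ses$units$group == "depth")
  expect_equal(nrow(pt), n_sur * n_dep)
  expect_true(all(pt$spike_dist >= 0 & pt$spike_dist <= 1))
  expect_true(all(pt$physical_dist_um >= 600)) # closest pairs >= insertion depth
  g <- glance(pt)
  expect_true(is.numeric(g$pearson_r))
  expect_equal(g$n_pairs, nrow(pt))
  expect_equal(nrow(tidy(pt)), nrow(pt))

  # single pair: record emitted, correlation undefined
  pop1 <- ses$units[c(which(ses$units$group == "depth")[1],
                      which(ses$units$group == "surface")[1]), ]
  ses1 <- ses
  ses1$units <- pop1
  pt1 <- pair_table(ses1)
  expect_equal(nrow(pt1), 1)
  expect_true(is.na(glance(pt1)$pearson_r))
})

test_that("identical trains across all pairs flag an undefined correlation", {
  ses <- small_session()
  base <- sort(runif(50, 0, ses$duration_s))
  ses2 <- ses
  ses2$spikes <- dplyr::bind_rows(lapply(ses$units$unit_id, function(u)
    tibble::tibble(unit_id = u, time_s = base,
                   label = "SUA",
                   electrode_id = ses$units$electrode_id[ses$units$unit_id == u],
                   group = ses$units$group[ses$units$unit_id == u])))
  expect_message(pt <- pair_table(ses2), "Zero variance")
  expect_true(all(pt$spike_dist == 0))
  expect_true(is.na(glance(pt)$pearson_r))
})
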