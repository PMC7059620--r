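# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / dense-grid formulations so they share no code path with the
# package implementations they check.

# brute-force cross-correlogram: enumerate every spike pair
oracle_ccg <- function(x, y, bin_ms = 5, max_lag_ms = 100) {
  edges <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  centers <- edges[-length(edges)] + bin_ms / 2
  counts <- integer(length(centers))
  for (tx in x) for (ty in y) {
    d <- (ty - tx) * 1000
    if (d >= -max_lag_ms && d < max_lag_ms) {
      b <- findInterval(d, edges)
      counts[b] <- counts[b] + 1L
    }
  }
  tibble::tibble(lag_ms = centers, count = counts)
}

# dense-grid SPIKE-distance: evaluate the dissimilarity profile pointwise on
# a 0.1 ms grid (offset half a step so grid points never hit spikes) and
# average by the trapezoid rule
oracle_spike_distance <- function(x, y, interval, dt = 1e-4) {
  t0 <- interval[1]; t1 <- interval[2]
  xa <- unique(sort(c(t0, x[x >= t0 & x <= t1], t1)))
  ya <- unique(sort(c(t0, y[y >= t0 & y <= t1], t1)))
  tg <- seq(t0 + dt / 2, t1 - dt / 2, by = dt)
  nn <- function(v, z) {
    j <- findInterval(v, z)
    pmin(ifelse(j >= 1, v - z[pmax(j, 1)], Inf),
         ifelse(j < length(z), z[pmin(j + 1, length(z))] - v, Inf))
  }
  term <- function(spk, other, tt) {
    iP <- findInterval(tt, spk)
    tP <- spk[pmax(iP, 1)]
    iF <- ifelse(tP == tt, iP, iP + 1L)
    tF <- spk[pmin(iF, length(spk))]
    isi <- tF - tP
    list(isi = isi, S = (nn(tP, other) * (tF - tt) + nn(tF, other) * (tt - tP)) / isi)
  }
  a <- term(xa, ya, tg)
  b <- term(ya, xa, tg)
  S <- (a$S * b$isi + b$S * a$isi) / (2 * ((a$isi + b$isi) / 2)^2)
  mean(S)
}

# homogeneous Poisson train on [0, T]
rpoisson_train <- function(rate, T) {
  n <- rpois(1, rate * T)
  sort(runif(n, 0, T))
}

# bursty train: Poisson burst onsets, geometric(0.5) extra spikes at a
# jittered intra-burst interval (mirrors the generator's burst model)
rburst_train <- function(burst_rate, T, intra = 0.003) {
  on <- rpoisson_train(burst_rate, T)
  if (length(on) == 0) return(numeric(0))
  extra <- rgeom(length(on), 0.5)
  sort(unlist(lapply(seq_along(on), function(k) {
    if (extra[k] == 0) return(on[k])
    on[k] + c(0, cumsum(intra * runif(extra[k], 0.8, 1.2)))
  })))
}

# small default-conditions session shared by several tests (built once)
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- simulate_unit_population(4, 4, seed = 101)
      cache <<- simulate_session(pop, session_config(n_trials = 10, seed = 101))
    }
    cache
  }
})
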