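# Shared fixtures and independent brute-force oracles.

# A series with chosen MAP values and innocuous pressure channels.
map_series <- function(map, dt = 2.4) {
  n <- length(map)
  hemo_series(data.frame(time_s = dt * (seq_len(n) - 1),
                         ibp_sys = map + 25, ibp_dia = map - 12,
                         ibp_mean = map, spo2 = rep(95, n),
                         pulse = rep(75, n)),
              nominal_dt_s = dt)
}

# Random series for property tests (clean pressures, irregular gaps).
random_series <- function(n, seed, dt = 2.4) {
  set.seed(seed)
  m <- runif(n, 30, 110)
  hemo_series(data.frame(time_s = cumsum(runif(n, 1.5, 3.5)),
                         ibp_sys = m + runif(n, 10, 40),
                         ibp_dia = m - runif(n, 8, 22),
                         ibp_mean = m,
                         spo2 = runif(n, 70, 100),
                         pulse = runif(n, 50, 120)),
              nominal_dt_s = dt)
}

# Cohort configuration with short surgeries; used wherever the test only
# needs the cohort's statistical structure, not two-hour recordings.
light_config <- function(seed, n_patients = 28L, ...) {
  synth_config(n_patients = n_patients,
               bypass_duration_min = c(35, 8),
               cross_duration_min = c(15, 4),
               pre_bypass_min = 5, post_bypass_min = 5,
               seed = seed, ...)
}

# Brute-force artifact oracle: O(n^2) pairwise re-statement of all five
# criteria, independent of the package's windowed single-pass code.
brute_flags <- function(s) {
  n <- nrow(s)
  out <- logical(n)
  for (i in seq_len(n)) {
    sys <- s$ibp_sys[i]
    dia <- s$ibp_dia[i]
    if (sys <= 20 || sys >= 300) out[i] <- TRUE
    if (sys <= dia + 5) out[i] <- TRUE
    if (dia <= 5 || dia >= 225) out[i] <- TRUE
    if (i > 1) for (j in 1:(i - 1)) {
      gap <- s$time_s[i] - s$time_s[j]
      d <- abs(sys - s$ibp_sys[j])
      if (gap <= 60 && d >= 80) out[i] <- TRUE
      if (gap <= 120 && d >= 40) out[i] <- TRUE
    }
  }
  which(out)
}

# Brute-force burden-metric oracle: direct loops over the definition.
brute_metrics <- function(map, threshold, dt) {
  amd <- 0
  tu <- 0
  area <- 0
  for (m in map) {
    if (threshold - m > amd) amd <- threshold - m
    if (m < threshold) {
      tu <- tu + dt
      area <- area + (threshold - m) * dt
    }
  }
  list(amd = amd, time_under = tu, area = area,
       twa = area / (length(map) * dt))
}

# Independent maximum-likelihood oracle: zooming grid search over the
# two-parameter logistic log-likelihood surface.
grid_mle <- function(x, y, rounds = 4) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- 0; c1 <- 0; span <- 4
  for (r in seq_len(rounds)) {
    b0s <- seq(c0 - span, c0 + span, length.out = 41)
    b1s <- seq(c1 - span, c1 + span, length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    c0 <- b0s[best[1]]; c1 <- b1s[best[2]]
    span <- span / 12
  }
  c(b0 = c0, b1 = c1)
}
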