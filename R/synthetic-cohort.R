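#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the cohort simulator. The defaults emulate the study
#' conditions the package targets: 28 patients undergoing on-pump coronary
#' surgery, of whom 10/28 show a MoCA drop of two or more points; invasive
#' pressures sampled at a nominal 2.4 s cadence with timing jitter; a bypass
#' period of roughly two hours containing a nested aortic cross-clamp window;
#' and sporadic monitor artifacts matching the five removal criteria applied
#' by [flag_artifacts()].
#'
#' @param n_patients Number of patients in the cohort.
#' @param group2_fraction Expected fraction of patients with neurocognitive
#'   impairment (MoCA drop >= 2); used as the marginal outcome probability.
#' @param sampling_interval_s Nominal inter-sample gap in seconds.
#' @param jitter_frac Uniform timestamp jitter as a fraction of the nominal
#'   gap (gap ~ dt * (1 + U(-jitter, +jitter))).
#' @param baseline_map_mean,baseline_map_sd Patient-level mean arterial
#'   pressure setpoint distribution, mmHg.
#' @param map_walk_sd Innovation SD of the mean-reverting MAP walk, mmHg per
#'   step.
#' @param map_revert Mean-reversion rate per step of the MAP walk (0 gives a
#'   pure random walk).
#' @param map_bounds Hard physiological clip range for MAP, mmHg.
#' @param dip_rate_per_hour Expected number of transient hypotensive
#'   episodes per hour of recording; these smooth (half-cosine) dips are
#'   what carries MAP below the 55 mmHg threshold and give the deep-burden
#'   metrics realistic between-patient spread.
#' @param dip_depth_mmHg Length-2 range of episode depths, mmHg.
#' @param dip_duration_s Length-2 range of episode durations, seconds;
#'   episodes are slow enough that their flanks do not trip the
#'   rapid-variation artifact criteria.
#' @param bypass_duration_min,cross_duration_min Length-2 numeric
#'   `c(mean, sd)` for bypass and cross-clamp durations, minutes. The
#'   cross-clamp window is always nested inside the bypass window.
#' @param pre_bypass_min,post_bypass_min Recorded surgery time before and
#'   after the bypass window, minutes.
#' @param artifact_rates Named numeric vector of per-sample injection
#'   probabilities for the five artifact criteria (see
#'   [inject_artifacts()]); all in `[0, 1]`.
#' @param effect_feature Name of a feature-table column that drives the
#'   outcome, or `"none"` for an effect-free cohort.
#' @param effect_beta Log-odds of outcome per standard deviation of the
#'   effect feature.
#' @param seed Master seed; identical configurations generate identical
#'   cohorts.
#'
#' @return A list of class `"synth_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_patients = 4, bypass_duration_min = c(30, 5),
#'                     cross_duration_min = c(15, 4))
#' cohort <- generate_cohort(cfg)
#' length(cohort)
synth_config <- function(n_patients = 28L,
                         group2_fraction = 10 / 28,
                         sampling_interval_s = 2.4,
                         jitter_frac = 0.2,
                         baseline_map_mean = 72,
                         baseline_map_sd = 8,
                         map_walk_sd = 1.2,
                         map_revert = 0.03,
                         map_bounds = c(20, 130),
                         dip_rate_per_hour = 1.2,
                         dip_depth_mmHg = c(10, 40),
                         dip_duration_s = c(600, 1200),
                         bypass_duration_min = c(115, 30),
                         cross_duration_min = c(72, 25),
                         pre_bypass_min = 15,
                         post_bypass_min = 10,
                         artifact_rates = c(sys_range = 0.002,
                                            pulse_pressure = 0.002,
                                            dia_range = 0.002,
                                            sys_jump_60 = 0.001,
                                            sys_jump_120 = 0.001),
                         effect_feature = "none",
                         effect_beta = 0,
                         seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              group2_fraction = group2_fraction,
              sampling_interval_s = sampling_interval_s,
              jitter_frac = jitter_frac,
              baseline_map_mean = baseline_map_mean,
              baseline_map_sd = baseline_map_sd,
              map_walk_sd = map_walk_sd,
              map_revert = map_revert,
              map_bounds = map_bounds,
              dip_rate_per_hour = dip_rate_per_hour,
              dip_depth_mmHg = dip_depth_mmHg,
              dip_duration_s = dip_duration_s,
              bypass_duration_min = bypass_duration_min,
              cross_duration_min = cross_duration_min,
              pre_bypass_min = pre_bypass_min,
              post_bypass_min = post_bypass_min,
              artifact_rates = artifact_rates,
              effect_feature = effect_feature,
              effect_beta = effect_beta,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L)
  if (cfg$group2_fraction < 0 || cfg$group2_fraction > 1)
    stop("group2_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$sampling_interval_s <= 0)
    stop("sampling_interval_s must be positive", call. = FALSE)
  if (cfg$jitter_frac < 0 || cfg$jitter_frac >= 1)
    stop("jitter_frac must lie in [0, 1)", call. = FALSE)
  if (cfg$bypass_duration_min[1] <= 0 || cfg$bypass_duration_min[2] < 0 ||
      cfg$cross_duration_min[1] < 0 || cfg$cross_duration_min[2] < 0)
    stop("durations must be positive", call. = FALSE)
  if (cfg$pre_bypass_min < 0 || cfg$post_bypass_min < 0)
    stop("durations must be positive", call. = FALSE)
  if (any(cfg$artifact_rates < 0) || any(cfg$artifact_rates > 1))
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  if (cfg$dip_rate_per_hour < 0 || any(cfg$dip_depth_mmHg < 0) ||
      any(cfg$dip_duration_s <= 0))
    stop("dip parameters must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Construct a hemodynamic series object
#'
#' A `hemo_series` is a data frame with columns `time_s`, `ibp_sys`,
#' `ibp_dia`, `ibp_mean`, `spo2`, `pulse` and a `nominal_dt_s` attribute
#' (the assumed per-sample duration used by the burden metrics).
#'
#' @param df Data frame with the columns above (missing channels are filled
#'   with `NA`); timestamps must be strictly increasing.
#' @param nominal_dt_s Nominal inter-sample duration, seconds.
#' @return The data frame with class `hemo_series`.
#' @export
hemo_series <- function(df, nominal_dt_s = 2.4) {
  cols <- c("time_s", "ibp_sys", "ibp_dia", "ibp_mean", "spo2", "pulse")
  for (cl in cols) if (is.null(df[[cl]])) df[[cl]] <- rep(NA_real_, nrow(df))
  df <- as.data.frame(df)[cols]
  if (nrow(df) && any(diff(df$time_s) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (nrow(df) && any(df$time_s < 0))
    stop("timestamps must be non-negative", call. = FALSE)
  attr(df, "nominal_dt_s") <- nominal_dt_s
  class(df) <- c("hemo_series", "data.frame")
  df
}

nominal_dt <- function(series) {
  dt <- attr(series, "nominal_dt_s")
  if (is.null(dt)) 2.4 else dt
}

# subset rows while keeping the nominal_dt_s attribute and class
hs_subset <- function(series, keep) {
  out <- as.data.frame(series)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nominal_dt_s") <- nominal_dt(series)
  class(out) <- c("hemo_series", "data.frame")
  out
}

# deterministic per-patient seed derived from the master seed
spawn_seed <- function(seed, k) {
  as.integer((as.double(seed) * 10007 + as.double(k) * 7919) %% 2147483629)
}

draw_windows <- function(cfg) {
  bp_dur <- max(rnorm(1, cfg$bypass_duration_min[1], cfg$bypass_duration_min[2]), 20) * 60
  cr_dur <- rnorm(1, cfg$cross_duration_min[1], cfg$cross_duration_min[2]) * 60
  cr_dur <- min(max(cr_dur, 5 * 60), 0.85 * bp_dur)
  bp_start <- cfg$pre_bypass_min * 60
  bp_end <- bp_start + bp_dur
  cr_start <- bp_start + runif(1, 0.05, 0.95) * (bp_dur - cr_dur)
  list(bypass = c(bp_start, bp_end), cross = c(cr_start, cr_start + cr_dur))
}

#' Generate one patient's hemodynamic time series
#'
#' Simulates the channels an anesthesia monitor exports during on-pump
#' surgery: systolic/diastolic/mean invasive blood pressure, SpO2 and pulse,
#' at a jittered ~2.4 s cadence. The mean arterial pressure follows a
#' mean-reverting bounded random walk; systolic and diastolic are offset from
#' it by a noisy pulse pressure so that `sys > mean > dia` holds at every
#' clean sample. The pulse channel is absent (NA) inside the cross-clamp
#' window, where there is no heartbeat.
#'
#' @param config A [synth_config()].
#' @param patient_seed Integer seed for this patient.
#' @param windows Optional list with `bypass` and `cross` `c(start, end)`
#'   windows in seconds; drawn from the config when `NULL`.
#' @return A [hemo_series()] spanning the whole recorded surgery, with
#'   attributes `bypass_window` and `cross_window`.
#' @export
#' @examples
#' cfg <- synth_config(bypass_duration_min = c(30, 0), cross_duration_min = c(10, 0))
#' s <- generate_hemo_series(cfg, patient_seed = 42)
#' head(s)
generate_hemo_series <- function(config, patient_seed, windows = NULL) {
  validate_synth_config(config)
  set.seed(patient_seed)
  if (is.null(windows)) windows <- draw_windows(config)
  stopifnot(windows$cross[1] >= windows$bypass[1],
            windows$cross[2] <= windows$bypass[2])
  total <- windows$bypass[2] + config$post_bypass_min * 60
  dt <- config$sampling_interval_s
  n_max <- ceiling(total / dt) + 10L
  gaps <- dt * (1 + config$jitter_frac * runif(n_max, -1, 1))
  t <- c(0, cumsum(gaps))
  t <- t[t <= total]
  n <- length(t)

  mu <- config$baseline_map_mean + config$baseline_map_sd * rnorm(1)
  innov <- rnorm(n, 0, config$map_walk_sd)
  dev <- as.numeric(stats::filter(innov, 1 - config$map_revert,
                                  method = "recursive"))
  # transient hypotensive episodes: smooth half-cosine dips
  dip <- numeric(n)
  n_dips <- stats::rpois(1, config$dip_rate_per_hour * total / 3600)
  for (k in seq_len(n_dips)) {
    depth <- runif(1, config$dip_depth_mmHg[1], config$dip_depth_mmHg[2])
    dur <- runif(1, config$dip_duration_s[1], config$dip_duration_s[2])
    start <- runif(1, 0, max(total - dur, 0))
    inside <- t >= start & t <= start + dur
    dip[inside] <- dip[inside] +
      depth * 0.5 * (1 - cos(2 * pi * (t[inside] - start) / dur))
  }
  map <- pmin(pmax(mu + dev - dip, config$map_bounds[1]),
              config$map_bounds[2])

  pp_up <- pmax(rnorm(n, 22, 4), 4)   # keeps sys > mean
  pp_dn <- pmax(rnorm(n, 12, 3), 2)   # keeps dia < mean and sys - dia > 5
  sys <- map + pp_up
  dia <- map - pp_dn

  in_bp <- t >= windows$bypass[1] & t < windows$bypass[2]
  in_cr <- t >= windows$cross[1] & t < windows$cross[2]
  spo2 <- rnorm(n, 97, 1)
  spo2[in_bp & !in_cr] <- rnorm(sum(in_bp & !in_cr), 89, 4)
  spo2[in_cr] <- rnorm(sum(in_cr), 73, 8)
  spo2 <- pmin(pmax(spo2, 40), 100)
  pulse <- pmin(pmax(rnorm(n, 75, 10), 30), 160)
  pulse[in_cr] <- NA_real_

  out <- hemo_series(data.frame(time_s = t, ibp_sys = sys, ibp_dia = dia,
                                ibp_mean = map, spo2 = spo2, pulse = pulse),
                     nominal_dt_s = dt)
  attr(out, "bypass_window") <- windows$bypass
  attr(out, "cross_window") <- windows$cross
  out
}

#' Inject monitor artifacts into a clean series
#'
#' Corrupts randomly chosen samples so that each violates one of the five
#' artifact-removal criteria checked by [flag_artifacts()]: (1) systolic out
#' of the 20--300 mmHg range, (2) pulse pressure collapse
#' (`sys <= dia + 5`), (3) diastolic out of the 5--225 mmHg range,
#' (4) systolic jump >= 80 mmHg within 60 s, (5) systolic jump >= 40 mmHg
#' within 120 s. Jump artifacts are only planted at samples that have an
#' earlier neighbour inside the window. A sample is corrupted by at most one
#' criterion.
#'
#' @param series A clean [hemo_series()].
#' @param rates Named numeric vector of per-sample injection probabilities
#'   with names `sys_range`, `pulse_pressure`, `dia_range`, `sys_jump_60`,
#'   `sys_jump_120`; all in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `series` (corrupted copy), `injected` (sorted indices
#'   of all corrupted samples) and `by_criterion` (list of index vectors).
#' @export
inject_artifacts <- function(series, rates, seed) {
  crit <- c("sys_range", "pulse_pressure", "dia_range",
            "sys_jump_60", "sys_jump_120")
  if (is.null(names(rates)) || !all(crit %in% names(rates)))
    stop("rates must be named: ", paste(crit, collapse = ", "), call. = FALSE)
  if (any(rates < 0) || any(rates > 1))
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n <- nrow(series)
  out <- as.data.frame(series)
  taken <- logical(n)
  by_criterion <- list()

  pick <- function(rate, eligible) {
    idx <- which(eligible & !taken & runif(n) < rate)
    taken[idx] <<- TRUE
    idx
  }
  window_max <- function(i, w) {
    j <- which(out$time_s < out$time_s[i] & out$time_s[i] - out$time_s <= w)
    if (!length(j)) return(NA_real_)
    max(out$ibp_sys[j])
  }

  i1 <- pick(rates[["sys_range"]], rep(TRUE, n))
  out$ibp_sys[i1] <- 310
  i2 <- pick(rates[["pulse_pressure"]], rep(TRUE, n))
  out$ibp_sys[i2] <- out$ibp_dia[i2] + 2
  i3 <- pick(rates[["dia_range"]], rep(TRUE, n))
  out$ibp_dia[i3] <- 2
  has_prev60 <- c(FALSE, diff(out$time_s) <= 60)[seq_len(max(n, 1))]
  i4 <- pick(rates[["sys_jump_60"]], seq_len(n) > 1 & has_prev60)
  for (i in i4) out$ibp_sys[i] <- window_max(i, 60) + 85
  i5 <- pick(rates[["sys_jump_120"]], seq_len(n) > 1)
  for (i in i5) out$ibp_sys[i] <- window_max(i, 120) + 45

  by_criterion <- list(sys_range = i1, pulse_pressure = i2, dia_range = i3,
                       sys_jump_60 = i4, sys_jump_120 = i5)
  res <- hs_subset(series, seq_len(n))
  res$ibp_sys <- out$ibp_sys
  res$ibp_dia <- out$ibp_dia
  attr(res, "bypass_window") <- attr(series, "bypass_window")
  attr(res, "cross_window") <- attr(series, "cross_window")
  list(series = res,
       injected = sort(unique(unlist(by_criterion))),
       by_criterion = by_criterion)
}

#' Generate a synthetic surgical cohort
#'
#' Builds `n_patients` patient records: demographics (age, pump flow, body
#' surface area), bypass and cross-clamp windows, a full artifact-contaminated
#' hemodynamic series, pre/post MoCA scores and a binary outcome label
#' (1 = MoCA drop of two points or more). With `effect_feature = "none"` the
#' label is Bernoulli(`group2_fraction`) independent of all recorded
#' features; otherwise the label follows a logistic model on the named
#' feature-table column, standardized across the cohort, with slope
#' `effect_beta` log-odds per SD.
#'
#' @param config A [synth_config()].
#' @return A list of patient records (class `"hemo_cohort"`). Each record has
#'   fields `patient_id`, `age`, `flow`, `bsa`, `bypass_window`,
#'   `cross_window`, `moca_pre`, `moca_post`, `group_label`, `series`,
#'   `injected_artifacts`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  n <- config$n_patients
  records <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- spawn_seed(config$seed, i)
    series <- generate_hemo_series(config, patient_seed = ps)
    inj <- inject_artifacts(series, config$artifact_rates,
                            seed = spawn_seed(config$seed, i + 100000L))
    set.seed(spawn_seed(config$seed, i + 200000L))
    records[[i]] <- list(
      patient_id = sprintf("P%03d", i),
      age = round(min(max(rnorm(1, 57.5, 10), 40), 79)),
      flow = round(rnorm(1, 4650, 350)),
      bsa = round(min(max(rnorm(1, 1.94, 0.15), 1.5), 2.4), 2),
      bypass_window = attr(series, "bypass_window"),
      cross_window = attr(series, "cross_window"),
      moca_pre = NA_integer_, moca_post = NA_integer_,
      group_label = NA_integer_,
      series = inj$series,
      injected_artifacts = inj$injected)
    class(records[[i]]) <- "patient_record"
  }
  class(records) <- "hemo_cohort"
  attr(records, "config") <- config

  # outcome labels: marginal Bernoulli, or logistic in a standardized feature
  set.seed(spawn_seed(config$seed, 999983L))
  if (identical(config$effect_feature, "none")) {
    labels <- rbinom(n, 1, config$group2_fraction)
  } else {
    feats <- build_feature_table(records)
    if (!config$effect_feature %in% names(feats))
      stop("unknown effect_feature: ", config$effect_feature, call. = FALSE)
    x <- feats[[config$effect_feature]][match(vapply(records, `[[`, "",
                                                     "patient_id"),
                                              feats$patient_id)]
    z <- as.numeric(scale(x))
    z[is.na(z)] <- 0
    p <- plogis(qlogis(config$group2_fraction) + config$effect_beta * z)
    labels <- rbinom(n, 1, p)
  }
  for (i in seq_len(n)) {
    pre <- sample(24:30, 1)
    drop <- if (labels[i] == 1) sample(2:4, 1) else sample(-1:1, 1)
    records[[i]]$moca_pre <- pre
    records[[i]]$moca_post <- max(min(pre - drop, 30L), 0L)
    records[[i]]$group_label <- as.integer(labels[i])
  }
  records
}

#' Write / read a cohort as plain CSV files
#'
#' `write_cohort()` writes one per-patient series CSV (`<patient_id>.csv`,
#' columns `time_s, ibp_sys, ibp_dia, ibp_mean, spo2, pulse`) plus a cohort
#' metadata CSV (`cohort.csv`). `read_cohort()` reads the same layout back;
#' real monitor exports in the same schema are accepted.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output / input directory.
#' @param nominal_dt_s Assumed per-sample duration when reading, seconds.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `hemo_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id, age = r$age, flow = r$flow,
               bsa = r$bsa,
               bypass_start_s = r$bypass_window[1],
               bypass_end_s = r$bypass_window[2],
               cross_start_s = r$cross_window[1],
               cross_end_s = r$cross_window[2],
               moca_pre = r$moca_pre, moca_post = r$moca_post,
               group = r$group_label)
  }))
  write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (r in cohort)
    write.csv(as.data.frame(r$series),
              file.path(dir, paste0(r$patient_id, ".csv")), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, nominal_dt_s = 2.4) {
  meta <- read.csv(file.path(dir, "cohort.csv"))
  records <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    ser <- hemo_series(read.csv(file.path(dir, paste0(m$patient_id, ".csv"))),
                       nominal_dt_s = nominal_dt_s)
    r <- list(patient_id = m$patient_id, age = m$age, flow = m$flow,
              bsa = m$bsa,
              bypass_window = c(m$bypass_start_s, m$bypass_end_s),
              cross_window = c(m$cross_start_s, m$cross_end_s),
              moca_pre = m$moca_pre, moca_post = m$moca_post,
              group_label = m$group, series = ser,
              injected_artifacts = integer(0))
    class(r) <- "patient_record"
    r
  })
  class(records) <- "hemo_cohort"
  records
}
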