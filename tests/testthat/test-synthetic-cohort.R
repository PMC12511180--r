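test_that("series generation is deterministic and respects the cadence", {
  cfg <- light_config(1)
  a <- generate_hemo_series(cfg, patient_seed = 42)
  b <- generate_hemo_series(cfg, patient_seed = 42)
  expect_identical(a, b)
  expect_true(all(diff(a$time_s) > 0))
  expect_lt(abs(mean(diff(a$time_s)) - cfg$sampling_interval_s),
            0.1 * cfg$sampling_interval_s)
  # pressure ordering on clean samples
  ok <- !is.na(a$ibp_sys)
  expect_true(all(a$ibp_sys[ok] > a$ibp_mean[ok]))
  expect_true(all(a$ibp_mean[ok] > a$ibp_dia[ok]))
})

test_that("zero-noise configuration degenerates to a constant MAP on an exact grid", {
  cfg <- light_config(1, map_walk_sd = 0, jitter_frac = 0,
                      baseline_map_sd = 0, dip_rate_per_hour = 0)
  s <- generate_hemo_series(cfg, patient_seed = 5)
  expect_true(all(s$ibp_mean == cfg$baseline_map_mean))
  expect_equal(diff(s$time_s), rep(2.4, nrow(s) - 1))
})

test_that("sample count matches the cadence arithmetic for a 60-min recording", {
  cfg <- synth_config(bypass_duration_min = c(50, 0),
                      cross_duration_min = c(15, 0),
                      pre_bypass_min = 5, post_bypass_min = 5, seed = 1)
  s <- generate_hemo_series(cfg, patient_seed = 9)
  expect_lt(abs(nrow(s) - 60 * 60 / 2.4), 0.1 * 1500)
})

test_that("cross-clamp window is nested in the bypass window for every patient", {
  co <- generate_cohort(light_config(2, n_patients = 10))
  for (r in co) {
    expect_gte(r$cross_window[1], r$bypass_window[1])
    expect_lte(r$cross_window[2], r$bypass_window[2])
    # pulse absent exactly where the clamp is on
    cr <- segment_period(r, "cross")
    expect_null(cr$pulse)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(group2_fraction = 1.2), "group2_fraction")
  expect_error(synth_config(sampling_interval_s = 0), "sampling_interval_s")
  expect_error(synth_config(bypass_duration_min = c(-5, 1)), "durations")
  expect_error(synth_config(artifact_rates = c(sys_range = 2,
                                               pulse_pressure = 0,
                                               dia_range = 0,
                                               sys_jump_60 = 0,
                                               sys_jump_120 = 0)), "rates")
})

test_that("artifact injection marks exactly the corrupted samples", {
  cfg <- light_config(3)
  s <- generate_hemo_series(cfg, patient_seed = 7)
  zero <- c(sys_range = 0, pulse_pressure = 0, dia_range = 0,
            sys_jump_60 = 0, sys_jump_120 = 0)

  noop <- inject_artifacts(s, zero, seed = 1)
  expect_equal(noop$series$ibp_sys, s$ibp_sys)
  expect_equal(noop$series$ibp_dia, s$ibp_dia)
  expect_length(noop$injected, 0)

  sat <- inject_artifacts(hs_small <- map_series(rep(80, 10)),
                          replace(zero, "sys_range", 1), seed = 1)
  expect_true(all(sat$series$ibp_sys >= 300))
  expect_length(sat$injected, 10)

  mixed <- inject_artifacts(s, c(sys_range = 0.02, pulse_pressure = 0.02,
                                 dia_range = 0.02, sys_jump_60 = 0.01,
                                 sys_jump_120 = 0.01), seed = 2)
  flagged <- flag_artifacts(mixed$series)
  static <- unlist(mixed$by_criterion[c("sys_range", "pulse_pressure",
                                        "dia_range")])
  expect_gt(length(static), 0)
  expect_true(all(static %in% flagged))
  # each static injection violates its own criterion in isolation
  by <- mixed$by_criterion
  expect_true(all(mixed$series$ibp_sys[by$sys_range] >= 300 |
                    mixed$series$ibp_sys[by$sys_range] <= 20))
  expect_true(all(mixed$series$ibp_sys[by$pulse_pressure] <=
                    mixed$series$ibp_dia[by$pulse_pressure] + 5))
  expect_true(all(mixed$series$ibp_dia[by$dia_range] <= 5))
})

test_that("effect-free cohorts draw labels at the configured marginal rate", {
  labs <- unlist(lapply(1:25, function(s) {
    vapply(generate_cohort(light_config(s, n_patients = 20)),
           `[[`, 1L, "group_label")
  }))
  expect_lt(abs(mean(labs) - 10 / 28),
            3 * sqrt((10 / 28) * (18 / 28) / length(labs)))
})

test_that("cohorts are reproducible and MoCA scores agree with the label", {
  cfg <- light_config(4, n_patients = 8)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  for (r in a) {
    drop <- r$moca_pre - r$moca_post
    expect_identical(r$group_label == 1L, drop >= 2)
    expect_true(r$moca_pre >= 24 && r$moca_pre <= 30)
  }
})

test_that("a planted effect produces outcome-feature association; a zero effect does not", {
  cfg <- light_config(5, n_patients = 150, effect_feature = "Bypass_AMD_55",
                      effect_beta = 0)
  ft <- build_feature_table(generate_cohort(cfg))
  expect_lt(abs(cor(ft$Bypass_AMD_55, ft$group)), 0.25)

  cfg2 <- light_config(5, n_patients = 150, effect_feature = "Bypass_AMD_55",
                       effect_beta = 1.5)
  ft2 <- build_feature_table(generate_cohort(cfg2))
  expect_gt(cor(ft2$Bypass_AMD_55, ft2$group), 0.3)

  expect_error(generate_cohort(light_config(1, n_patients = 4,
                                            effect_feature = "No_Such")),
               "unknown effect_feature")
})

test_that("cohort CSV round-trip preserves metadata and series values", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(light_config(6, n_patients = 3))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_length(back, 3)
  expect_identical(back[[2]]$patient_id, co[[2]]$patient_id)
  expect_equal(back[[2]]$bypass_window, co[[2]]$bypass_window)
  expect_equal(back[[2]]$series$ibp_mean, co[[2]]$series$ibp_mean)
  expect_equal(back[[3]]$group_label, co[[3]]$group_label)
})
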