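test_that("intercept-only fits match the closed-form MLE", {
  y <- c(rep(1, 5), rep(0, 5))
  f <- fit_logistic(matrix(numeric(0), nrow = 10, ncol = 0), y)
  expect_equal(unname(f$coefficients[1]), 0, tolerance = 1e-8)
  expect_equal(unname(f$fitted[1]), 0.5, tolerance = 1e-8)

  y2 <- c(rep(1, 3), rep(0, 7))
  f2 <- fit_logistic(matrix(numeric(0), nrow = 10, ncol = 0), y2)
  expect_equal(unname(f2$coefficients[1]), log(3 / 7), tolerance = 1e-7)
  expect_equal(f2$loglik, f2$loglik0, tolerance = 1e-8)
})

test_that("the MLE agrees with an independent likelihood grid search", {
  set.seed(7)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 1 * x))
  f <- fit_logistic(cbind(x = x), y)
  o <- grid_mle(x, y)
  expect_lt(abs(unname(f$coefficients["(Intercept)"]) - o["b0"]), 1e-3)
  expect_lt(abs(unname(f$coefficients["x"]) - o["b1"]), 1e-3)
  expect_true(f$converged)
  expect_false(f$separated)
  expect_gte(f$loglik, f$loglik0)
})

test_that("perfect separation is flagged, not silently accepted", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- fit_logistic(cbind(x = x), y)
  expect_true(f$separated)
  expect_gt(nagelkerke_r2(f), 0.99)
})

test_that("omnibus likelihood-ratio test matches the chi-square reference", {
  f0 <- list(loglik = -10, loglik0 = -10, n = 30, df = 2)
  expect_equal(omnibus_test(f0)$p_value, 1)
  f1 <- list(loglik = -10 + 3.84 / 2, loglik0 = -10, n = 30, df = 1)
  expect_equal(omnibus_test(f1)$p_value, pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(omnibus_test(f1)$p_value, 0.05, tolerance = 0.002)
  expect_error(omnibus_test(list(loglik = 0, loglik0 = 0, df = 0)),
               "predictor")
})

test_that("pseudo-R2 formulas evaluate exactly on closed-form cases", {
  perfect <- list(loglik = 0, loglik0 = 10 * log(0.5), n = 10)
  expect_equal(cox_snell_r2(perfect), 0.75)
  expect_equal(nagelkerke_r2(perfect), 1)
  null <- list(loglik = 10 * log(0.5), loglik0 = 10 * log(0.5), n = 10)
  expect_equal(cox_snell_r2(null), 0)
  expect_equal(nagelkerke_r2(null), 0)
  # degenerate outcome: undefined, flagged
  deg <- list(loglik = 0, loglik0 = 0, n = 10)
  expect_warning(expect_true(is.na(nagelkerke_r2(deg))), "degenerate")
})

test_that("pseudo-R2 identities hold on fitted models", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.8 * x))
    if (length(unique(y)) < 2) next
    f <- fit_logistic(cbind(x = x), y)
    cs <- cox_snell_r2(f)
    nk <- nagelkerke_r2(f)
    expect_gte(cs, 0)
    expect_lt(cs, 1 - exp(2 * f$loglik0 / f$n) + 1e-12)
    expect_gte(nk + 1e-12, cs)
    expect_lte(nk, 1 + 1e-12)
  }
})

test_that("Wald statistics, odds ratios and intervals are correct", {
  w <- wald_from_estimates(0.058, 0.067)
  expect_equal(w$exp_beta, 1.060, tolerance = 5e-4)
  expect_lt(abs(w$ci_low - 0.930), 2e-3)
  expect_lt(abs(w$ci_high - 1.207), 2e-3)
  z <- wald_from_estimates(0, 0.5)
  expect_equal(z$exp_beta, 1)
  expect_equal(z$ci_low * z$ci_high, 1, tolerance = 1e-12)  # symmetric in log
  expect_equal(z$p_value, 1)
  # per-fit table carries one row per term
  set.seed(1)
  x <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("a", "b")))
  f <- fit_logistic(x, rbinom(40, 1, 0.4))
  tab <- wald_stats(f)
  expect_equal(tab$term, c("(Intercept)", "a", "b"))
  expect_true(all(tab$ci_low <= tab$exp_beta & tab$exp_beta <= tab$ci_high))
})

test_that("the screen reproduces a direct single-combination fit", {
  co <- generate_cohort(light_config(31))
  ft <- build_feature_table(co)
  mf <- build_manifest("bypass")
  pick <- mf[mf$parameters == "Age;Bypass_AMD_55", , drop = FALSE]
  expect_equal(nrow(pick), 1)
  sc <- run_lr_screen(ft, pick)
  direct <- lr_fit_combination(ft, mf, pick$combination_id)
  expect_equal(sc$results$omnibus_p, direct$omnibus$p_value)
  expect_equal(sc$results$cox_snell_r2, direct$cox_snell_r2)
  expect_equal(sc$results$nagelkerke_r2, direct$nagelkerke_r2)
  expect_equal(sc$summary$n_combinations, 1)
})

test_that("screen flags overparameterized fits and supports corrections", {
  co <- generate_cohort(light_config(32))
  ft <- build_feature_table(co)
  mf <- build_manifest("bypass")
  mf_big <- mf[mf$n_params >= 10, ][1:5, ]
  sc <- run_lr_screen(ft, mf_big, correction = "bonferroni")
  expect_true(all(sc$results$overparameterized))
  expect_true(all(sc$results$p_adjusted >= sc$results$omnibus_p,
                  na.rm = TRUE))
  expect_error(run_lr_screen(ft[, 1:4], mf_big), "lacks columns")
})

test_that("group comparison has the expected panels and calibrated p-values", {
  co <- generate_cohort(light_config(33))
  ft <- build_feature_table(co)
  gb <- group_compare(ft, "bypass")
  gc <- group_compare(ft, "cross")
  expect_true(all(c("Age", "Flow", "BSA", "Bypass_min") %in% gb$variable))
  expect_false(any(c("Age", "Flow", "BSA", "Bypass_min") %in% gc$variable))
  expect_false("Cross_Av_PLS" %in% gc$variable)
  expect_true("Cross_min" %in% gc$variable)
  expect_true(all(gb$p_value >= 0 & gb$p_value <= 1, na.rm = TRUE))

  # identical groups: p = 1 up to numerical tolerance
  twin <- ft[c(1:4, 1:4), ]
  twin$group <- rep(c(0, 1), each = 4)
  gtwin <- group_compare(twin, "bypass")
  expect_true(all(abs(gtwin$p_value - 1) < 1e-9 | is.na(gtwin$p_value)))

  # same-distribution groups give roughly uniform p-values
  set.seed(5)
  ps <- replicate(60, {
    fake <- ft[sample(nrow(ft), 20, replace = TRUE), ]
    fake$group <- rep(c(0, 1), 10)
    group_compare(fake, "bypass")$p_value[1]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
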