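make_toy <- function(n = 60, seed = 2) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(a = rnorm(n, mean = 3 * y), b = rnorm(n))
  list(X = X, y = y)
}

test_that("forest training is deterministic and separates separable classes", {
  d <- make_toy()
  cfg <- forest_config(n_trees = 60, seed = 9)
  m1 <- train_forest(d$X, d$y, cfg)
  m2 <- train_forest(d$X, d$y, cfg)
  expect_identical(predict(m1, d$X), predict(m2, d$X))
  expect_equal(mean(predict(m1, d$X) == d$y), 1)
  expect_error(train_forest(d$X, rep(0, nrow(d$X)), cfg), "single class")
})

test_that("stratified split preserves the class ratio within one sample", {
  y <- c(rep(0, 18), rep(1, 10))
  for (seed in 1:10) {
    sp <- stratified_split(y, 0.3, seed)
    expect_equal(length(sp$test) + length(sp$train), 28)
    expect_lte(abs(sum(y[sp$test] == 1) - 0.3 * 10), 1)
    expect_lte(abs(sum(y[sp$test] == 0) - 0.3 * 18), 1)
  }
})

test_that("classification report handles degenerate and perfect predictors", {
  # all-majority predictions on a 5/4 test split
  r <- classification_report(c(rep(0, 5), rep(1, 4)), rep(0, 9))
  pc <- r$per_class
  expect_equal(round(pc$precision[pc$class == 0], 2), 0.56)
  expect_equal(pc$recall[pc$class == 0], 1.00)
  expect_equal(round(pc$f1[pc$class == 0], 2), 0.71)
  expect_equal(pc$precision[pc$class == 1], 0)
  expect_equal(pc$recall[pc$class == 1], 0)
  expect_equal(pc$support, c(5, 4))
  expect_equal(round(r$macro_avg[["precision"]], 2), 0.28)
  expect_equal(r$macro_avg[["recall"]], 0.5)
  expect_equal(round(r$accuracy, 2), 0.56)
  expect_equal(round(r$weighted_avg[["precision"]], 2), 0.31)

  perf <- classification_report(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perf$accuracy, 1)
  expect_true(all(perf$per_class[c("precision", "recall", "f1")] == 1))

  # F1 is the harmonic mean of precision and recall
  expect_equal(pc$f1, ifelse(pc$precision + pc$recall == 0, 0,
                             2 * pc$precision * pc$recall /
                               (pc$precision + pc$recall)))
})

test_that("evaluation reports accuracies in range and supports sum to test size", {
  d <- make_toy(n = 40, seed = 4)
  res <- evaluate_forest(d$X, d$y, forest_config(n_trees = 40, seed = 3))
  expect_equal(sum(res$report$per_class$support), length(res$split$test))
  expect_gte(res$test_accuracy, 0)
  expect_lte(res$test_accuracy, 1)
  expect_gte(res$cv_accuracy, 0)
  expect_lte(res$cv_accuracy, 1)
  # separable toy: clearly better than chance held-out performance
  expect_gte(res$test_accuracy, 0.8)
})

test_that("pure-noise labels give held-out accuracy near the majority rate", {
  accs <- vapply(1:8, function(seed) {
    set.seed(seed)
    X <- data.frame(a = rnorm(40), b = rnorm(40))
    y <- rep(c(0, 1), each = 20)
    evaluate_forest(X, y, forest_config(n_trees = 30, seed = seed))$test_accuracy
  }, 1)
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.8)
})

test_that("feature importance normalizes, finds planted signal, splits duplicates", {
  set.seed(11)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- as.numeric(X$x1 > median(X$x1))
  m <- train_forest(X, y, forest_config(n_trees = 80, seed = 2))
  imp <- feature_importance(m)
  expect_equal(sum(imp), 1)
  expect_equal(names(which.max(imp)), "x1")

  Xdup <- cbind(X, x1b = X$x1)
  mdup <- train_forest(Xdup, y, forest_config(n_trees = 80, seed = 2))
  idup <- feature_importance(mdup)
  expect_gt(idup[["x1"]] + idup[["x1b"]], 0.6)
})

test_that("partial dependence matches closed-form behaviour of simple models", {
  set.seed(8)
  X <- data.frame(a = runif(80, -2, 2), b = runif(80, -2, 2))

  # model ignoring the feature: flat curve
  flat <- partial_dependence(NULL, X, "a",
                             predict_fun = function(m, nd) 0.4 + 0 * nd$a)
  expect_true(all(abs(flat$pd - 0.4) < 1e-12))

  # additive model: PDP equals the component function up to a constant
  fun_a <- function(a) 0.25 * sin(a)
  add_pred <- function(m, nd) 0.4 + fun_a(nd$a) + 0.1 * (nd$b > 0)
  pd <- partial_dependence(NULL, X, "a", grid_size = 15,
                           predict_fun = add_pred)
  expect_equal(pd$pd - mean(pd$pd),
               fun_a(pd$grid) - mean(fun_a(pd$grid)), tolerance = 1e-12)

  # monotone single-feature stump ensemble: PDP reproduces the response
  stump <- function(m, nd) plogis(1.5 * nd$a)
  pd2 <- partial_dependence(NULL, X, "a", grid_size = 10,
                            predict_fun = stump)
  expect_equal(pd2$pd, plogis(1.5 * pd2$grid), tolerance = 1e-12)

  # averaging the PDP over the observed feature values recovers the mean
  # prediction for an additive model
  pd3 <- partial_dependence(NULL, X, "a", grid = X$a,
                            predict_fun = add_pred)
  expect_equal(mean(pd3$pd), mean(add_pred(NULL, X)), tolerance = 1e-12)

  # constant feature collapses to a single grid point
  Xc <- data.frame(a = rep(1, 10), b = rnorm(10))
  pdc <- partial_dependence(NULL, Xc, "a",
                            predict_fun = function(m, nd) 0.2 + 0 * nd$a)
  expect_length(pdc$grid, 1)
  expect_error(partial_dependence(NULL, X, "zz",
                                  predict_fun = stump), "unknown feature")
})

test_that("partial dependence of a trained forest stays within probability range", {
  d <- make_toy(n = 50, seed = 6)
  m <- train_forest(d$X, d$y, forest_config(n_trees = 40, seed = 1))
  pd <- partial_dependence(m, d$X, "a", grid_size = 8)
  expect_true(all(pd$pd >= 0 & pd$pd <= 1))
  expect_true(all(pd$grid >= min(d$X$a) & pd$grid <= max(d$X$a)))
  # class-1 probability rises with the separating feature
  expect_gt(pd$pd[8], pd$pd[1])
})

test_that("the forest screen equals the direct train/evaluate path", {
  co <- generate_cohort(light_config(41))
  ft <- build_feature_table(co)
  mf <- build_manifest("bypass")
  pick <- mf[mf$parameters %in% c("Age;Bypass_AMD_55",
                                  "Age;Bypass_Time_Under_55;Bypass_Area_55"), ]
  cfg <- forest_config(n_trees = 40, seed = 5)
  sc <- run_rf_screen(ft, pick, cfg)
  direct <- evaluate_forest(ft[strsplit(pick$parameters[1], ";")[[1]]],
                            ft$group, cfg)
  expect_equal(sc$results$test_accuracy[1], direct$test_accuracy)
  expect_equal(sc$results$cv_accuracy[1], direct$cv_accuracy)
  expect_equal(sc$summary$max_accuracy, max(sc$results$test_accuracy))
  expect_false(any(sc$results$failed))
})
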