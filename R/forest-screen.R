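#' Random-forest screen configuration
#'
#' @param n_trees Number of trees `K` in the ensemble (the forest prediction
#'   is the majority vote over the `K` trees, each grown on a bootstrap
#'   sample with a random feature subset per split).
#' @param test_fraction Held-out fraction for the stratified train/test
#'   split.
#' @param cv_folds Folds for the stratified cross-validation accuracy.
#' @param mtry Features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param seed Integer seed; identical seed and data give identical models.
#' @return List of class `"forest_config"`.
#' @export
forest_config <- function(n_trees = 100L, test_fraction = 0.3,
                          cv_folds = 5L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1, test_fraction > 0, test_fraction < 1,
            cv_folds >= 2)
  structure(list(n_trees = as.integer(n_trees),
                 test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds), mtry = mtry,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Train a random-forest classifier
#'
#' Breiman-style bagged ensemble: each of the `K` trees is grown on a
#' bootstrap sample of the rows with a random subset of features considered
#' at each split, and classification is by majority vote. The learner is
#' `randomForest::randomForest`; evaluation metrics and partial dependence
#' are computed in this package.
#'
#' @param X Numeric predictor matrix or data frame.
#' @param y Binary 0/1 outcomes (coerced to factor).
#' @param config A [forest_config()].
#' @return A `randomForest` model object.
#' @export
train_forest <- function(X, y, config = forest_config()) {
  y <- factor(y, levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2)
    stop("training data contains a single class", call. = FALSE)
  X <- as.data.frame(X)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X)))) else
    config$mtry
  set.seed(config$seed)
  randomForest::randomForest(x = X, y = y, ntree = config$n_trees,
                             mtry = mtry)
}

#' Stratified train/test split
#'
#' Splits indices so the class ratio of the test set matches the full data
#' within one sample per class.
#'
#' @param y Binary outcomes.
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.3, seed = 1L) {
  set.seed(seed)
  test <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(length(idx) * test_fraction))
  }))
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Classification report
#'
#' Per-class precision, recall, F1 and support, plus overall accuracy, the
#' macro average (unweighted mean over classes) and the support-weighted
#' average of the per-class scores. Precision for a class never predicted is
#' reported as 0.
#'
#' @param y_true,y_pred True and predicted labels.
#' @param classes Class labels in report order.
#' @return List of class `"classification_report"`: `per_class` (data
#'   frame), `accuracy`, `macro_avg`, `weighted_avg`.
#' @export
#' @examples
#' # 9 test patients (5 unimpaired, 4 impaired), all predicted unimpaired
#' r <- classification_report(c(rep(0, 5), rep(1, 4)), rep(0, 9))
#' r$per_class          # class 0: precision 0.56, recall 1.00, F1 0.71
#' r$macro_avg["precision"]  # 0.28
classification_report <- function(y_true, y_pred, classes = c(0, 1)) {
  stopifnot(length(y_true) == length(y_pred))
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               support = tp + fn)
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  structure(list(
    per_class = per,
    accuracy = mean(y_true == y_pred),
    macro_avg = c(precision = mean(per$precision), recall = mean(per$recall),
                  f1 = mean(per$f1)),
    weighted_avg = c(precision = sum(w * per$precision),
                     recall = sum(w * per$recall), f1 = sum(w * per$f1))),
    class = "classification_report")
}

#' Train and evaluate a forest on one predictor combination
#'
#' Performs the stratified 70/30 train/test evaluation and a stratified
#' k-fold cross-validation accuracy on the full data, and extracts the
#' normalized impurity-decrease feature importances.
#'
#' @param X Predictor matrix or data frame.
#' @param y Binary 0/1 outcomes.
#' @param config A [forest_config()].
#' @return List of class `"forest_result"`: `model`, `report`
#'   (a [classification_report()] on the test set), `test_accuracy`,
#'   `cv_accuracy`, `importance` (named, sums to 1), `split`.
#' @export
evaluate_forest <- function(X, y, config = forest_config()) {
  X <- as.data.frame(X)
  sp <- stratified_split(y, config$test_fraction, config$seed)
  model <- train_forest(X[sp$train, , drop = FALSE], y[sp$train], config)
  pred <- predict(model, X[sp$test, , drop = FALSE])
  rep <- classification_report(y[sp$test],
                               as.numeric(as.character(pred)))
  structure(list(model = model, report = rep,
                 test_accuracy = rep$accuracy,
                 cv_accuracy = cv_accuracy(X, y, config),
                 importance = feature_importance(model),
                 split = sp),
            class = "forest_result")
}

#' Stratified k-fold cross-validation accuracy
#'
#' @inheritParams evaluate_forest
#' @return Mean held-out-fold accuracy.
#' @export
cv_accuracy <- function(X, y, config = forest_config()) {
  X <- as.data.frame(X)
  set.seed(config$seed + 1L)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(config$cv_folds), length(idx))
  }
  acc <- vapply(seq_len(config$cv_folds), function(k) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) return(NA_real_)
    m <- train_forest(X[tr, , drop = FALSE], y[tr], config)
    p <- predict(m, X[!tr, , drop = FALSE])
    mean(as.numeric(as.character(p)) == y[!tr])
  }, 1)
  mean(acc, na.rm = TRUE)
}

#' Normalized impurity-decrease feature importance
#'
#' @param model A trained `randomForest` model.
#' @return Named numeric vector summing to 1 (uniform if the forest recorded
#'   no impurity decrease).
#' @export
feature_importance <- function(model) {
  imp <- model$importance[, "MeanDecreaseGini"]
  if (sum(imp) == 0) return(setNames(rep(1 / length(imp), length(imp)),
                                     names(imp)))
  imp / sum(imp)
}

#' Partial dependence of a classifier on one feature
#'
#' Empirical Monte-Carlo partial dependence: for each grid value `g` of the
#' target feature, the feature is set to `g` in *every* row of `X` (all
#' other features keep their observed joint values) and the model's
#' predicted class-1 probabilities are averaged. This is the empirical
#' counterpart of integrating the prediction function over the marginal
#' distribution of the remaining features, and is computed here from first
#' principles rather than delegated to a plotting helper.
#'
#' @param model A fitted model (any object `predict_fun` understands).
#' @param X Data frame of the feature values to average over (typically the
#'   training data).
#' @param feature Name of the target feature.
#' @param grid_size Number of grid points spanning the observed range.
#' @param predict_fun Function `(model, newdata) -> P(class 1)`; defaults to
#'   `randomForest` probability votes.
#' @param grid Optional explicit grid values (must lie within the observed
#'   feature range); overrides `grid_size`.
#' @return List of class `"pdp_curve"`: `feature`, `grid`, `pd` (average
#'   predicted probabilities, in `[0, 1]` for probabilistic models).
#' @export
partial_dependence <- function(model, X, feature, grid_size = 20L,
                               predict_fun = NULL, grid = NULL) {
  X <- as.data.frame(X)
  if (!feature %in% names(X)) stop("unknown feature: ", feature,
                                   call. = FALSE)
  if (is.null(predict_fun))
    predict_fun <- function(m, nd) predict(m, nd, type = "prob")[, "1"]
  rng <- range(X[[feature]])
  if (is.null(grid)) {
    grid <- if (diff(rng) == 0) rng[1] else
      seq(rng[1], rng[2], length.out = grid_size)
  } else if (any(grid < rng[1]) || any(grid > rng[2])) {
    stop("grid values must lie within the observed feature range",
         call. = FALSE)
  }
  pd <- vapply(grid, function(g) {
    Xg <- X
    Xg[[feature]] <- g
    mean(predict_fun(model, Xg))
  }, 1)
  structure(list(feature = feature, grid = grid, pd = pd),
            class = "pdp_curve")
}

#' Random-forest screen over a combination manifest
#'
#' Trains and evaluates one forest per combination (stratified 70/30 test
#' evaluation plus stratified cross-validation) and reports the screen-level
#' accuracy extrema. Per-combination failures are flagged, never abort the
#' screen.
#'
#' @inheritParams run_lr_screen
#' @param config A [forest_config()].
#' @return List of class `"rf_screen"`: `results` (one row per combination:
#'   accuracies and flags) and `summary` (`max_accuracy`, `min_accuracy`,
#'   `cv_range`).
#' @export
run_rf_screen <- function(features, manifest, config = forest_config()) {
  y <- features$group
  param_lists <- manifest_params(manifest$parameters)
  m <- nrow(manifest)
  test_acc <- cv_acc <- rep(NA_real_, m)
  failed <- logical(m)
  for (i in seq_len(m)) {
    res <- tryCatch(
      evaluate_forest(features[param_lists[[i]]], y, config),
      error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE
      next
    }
    test_acc[i] <- res$test_accuracy
    cv_acc[i] <- res$cv_accuracy
  }
  results <- data.frame(combination_id = manifest$combination_id,
                        period = manifest$period,
                        n_params = manifest$n_params,
                        test_accuracy = test_acc, cv_accuracy = cv_acc,
                        failed = failed)
  structure(list(
    results = results,
    summary = list(max_accuracy = suppressWarnings(max(test_acc, na.rm = TRUE)),
                   min_accuracy = suppressWarnings(min(test_acc, na.rm = TRUE)),
                   cv_range = suppressWarnings(range(cv_acc, na.rm = TRUE)))),
    class = "rf_screen")
}
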