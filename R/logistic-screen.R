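#' Fit a binary logistic regression by maximum likelihood
#'
#' Thin, fast wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`, convergence tolerance 1e-8, at most 100 iterations)
#' for the model
#' \deqn{P(Y = 1 | X) = \frac{e^{\beta_0 + \beta_1 X_1 + \dots + \beta_n X_n}}
#'                           {1 + e^{\beta_0 + \beta_1 X_1 + \dots + \beta_n X_n}}.}
#' Alongside the fit it records the log-likelihood of the intercept-only
#' model (closed form \eqn{k \log(k/n) + (n-k)\log(1 - k/n)} for `k` ones),
#' which the omnibus test and pseudo-R-squared measures are built from.
#' Quasi-complete separation is detected (fitted probabilities numerically 0
#' or 1) and flagged rather than silently accepted; such fits are reported
#' as unstable downstream, never dropped.
#'
#' @param X Numeric predictor matrix or data frame (no intercept column).
#' @param y Binary 0/1 outcome vector.
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return A list of class `"logit_fit"`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `loglik0`, `n`, `df` (number of non-aliased predictors),
#'   `converged`, `separated`, `fitted`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- rbinom(50, 1, plogis(-0.3 + x))
#' f <- fit_logistic(cbind(x = x), y)
#' f$coefficients
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  n <- length(y)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w), fixed = TRUE))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  eps <- 1e-12
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  k <- sum(y)
  loglik0 <- if (k == 0 || k == n) 0 else
    k * log(k / n) + (n - k) * log(1 - k / n)
  # IRLS can stop a hair short of the optimum; the LR statistic is >= 0
  loglik <- max(loglik, loglik0)

  p <- fit$rank
  vc <- matrix(NA_real_, ncol(Xd), ncol(Xd),
               dimnames = list(colnames(Xd), colnames(Xd)))
  vc_ok <- tryCatch({
    vc[seq_len(p), seq_len(p)] <-
      chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    TRUE
  }, error = function(e) FALSE)
  se <- if (vc_ok) sqrt(diag(vc)) else rep(NA_real_, ncol(Xd))
  names(se) <- colnames(Xd)
  if (!separated && any(!is.na(se)) && max(se, na.rm = TRUE) > 1e4)
    separated <- TRUE

  structure(list(coefficients = fit$coefficients, se = se, vcov = vc,
                 loglik = loglik, loglik0 = loglik0, n = n,
                 df = p - 1L, converged = fit$converged,
                 separated = separated, fitted = mu),
            class = "logit_fit")
}

#' Omnibus likelihood-ratio test of a logistic model
#'
#' Compares the fitted model against the intercept-only model:
#' the statistic \eqn{2(\ln L_M - \ln L_0)} is referred to a chi-square
#' distribution with as many degrees of freedom as there are predictors,
#' giving the upper-tail p-value. This is the "omnibus test of model
#' coefficients" assessing whether the predictors are collectively
#' associated with the outcome.
#'
#' @param fit A [fit_logistic()] object.
#' @param df Degrees of freedom (defaults to the fit's predictor count).
#' @return Named list: `statistic`, `df`, `p_value`.
#' @export
omnibus_test <- function(fit, df = fit$df) {
  if (df <= 0) stop("omnibus test needs at least one predictor", call. = FALSE)
  stat <- max(2 * (fit$loglik - fit$loglik0), 0)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Cox & Snell and Nagelkerke pseudo-R-squared
#'
#' Likelihood-based explanatory-power measures for logistic models. Cox &
#' Snell: \eqn{R^2_{CS} = 1 - (L_0 / L_M)^{2/n}}, computed on the
#' log-likelihood scale (the exponentiation is deferred to the ratio so
#' small likelihoods at large `n` cannot underflow); it cannot reach 1 even
#' for a perfect model. Nagelkerke rescales it by its attainable maximum,
#' \eqn{R^2_N = R^2_{CS} / (1 - L_0^{2/n})}, so a perfect model scores
#' exactly 1.
#'
#' @param fit A [fit_logistic()] object, or any list with `loglik`,
#'   `loglik0` and `n`.
#' @return A value in `[0, 1)` for Cox & Snell, `[0, 1]` for Nagelkerke
#'   (`NA` with a warning when the outcome is degenerate, i.e. one class).
#' @export
#' @examples
#' # 10 observations, chance-level null, perfect model
#' f <- list(loglik = 0, loglik0 = 10 * log(0.5), n = 10)
#' cox_snell_r2(f)   # 0.75
#' nagelkerke_r2(f)  # 1
cox_snell_r2 <- function(fit) {
  1 - exp(2 / fit$n * (fit$loglik0 - fit$loglik))
}

#' @rdname cox_snell_r2
#' @export
nagelkerke_r2 <- function(fit) {
  denom <- 1 - exp(2 * fit$loglik0 / fit$n)
  if (denom <= 0) {
    warning("degenerate outcome (single class): Nagelkerke R2 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cox_snell_r2(fit) / denom
}

#' Wald statistics, odds ratios and confidence intervals
#'
#' Per-coefficient table in the conventional logistic-regression report
#' layout: estimate, standard error, two-sided Wald p-value from the normal
#' reference, odds ratio `Exp(beta) = exp(beta)` (the multiplicative effect
#' of a one-unit increase on the odds of the outcome), and the 95% interval
#' `exp(beta +/- 1.96 * SE)`.
#'
#' @param fit A [fit_logistic()] object.
#' @param z_crit Normal critical value for the interval (1.96 for 95%).
#' @return Data frame with rows for the intercept and each predictor:
#'   `term`, `beta`, `se`, `p_value`, `exp_beta`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' # beta = 0.058, SE = 0.067 gives OR 1.060 (0.930 - 1.207)
#' wald_from_estimates(0.058, 0.067)
wald_stats <- function(fit, z_crit = 1.96) {
  b <- fit$coefficients
  se <- fit$se
  out <- wald_from_estimates(b, se, z_crit)
  out$term <- names(b)
  out[c("term", "beta", "se", "p_value", "exp_beta", "ci_low", "ci_high")]
}

#' @rdname wald_stats
#' @param beta,se Coefficient estimate(s) and standard error(s).
#' @export
wald_from_estimates <- function(beta, se, z_crit = 1.96) {
  z <- beta / se
  data.frame(beta = beta, se = se,
             p_value = 2 * pnorm(-abs(z)),
             exp_beta = exp(beta),
             ci_low = exp(beta - z_crit * se),
             ci_high = exp(beta + z_crit * se))
}

#' Exhaustive logistic-regression screen over a combination manifest
#'
#' Fits one logistic model per combination in the manifest and collects the
#' omnibus likelihood-ratio p-value, both pseudo-R-squared measures and fit
#' diagnostics. No multiple-testing correction is applied by default (the
#' screen is interpreted as a sensitivity sweep, not a family of confirmatory
#' tests); Bonferroni or Benjamini-Hochberg adjusted p-values can be added.
#' Fits with at least `n/3` predictors are flagged overparameterized but
#' still attempted; per-combination failures are caught and flagged, never
#' abort the screen.
#'
#' @param features Feature table from [build_feature_table()] (must contain
#'   a binary `group` column and every manifest parameter).
#' @param manifest Combination manifest from [build_manifest()].
#' @param standardize Center and scale predictors before fitting (default
#'   raw units, so odds ratios are per unit of each predictor).
#' @param alpha Significance level used in the summary counts.
#' @param correction `"none"`, `"bonferroni"` or `"bh"`.
#' @return List of class `"lr_screen"`: `results` (one row per combination:
#'   `combination_id`, `period`, `n_params`, `omnibus_stat`, `omnibus_p`,
#'   `cox_snell_r2`, `nagelkerke_r2`, flags, optionally `p_adjusted`) and
#'   `summary` (`n_combinations`, `n_stable`, `n_significant`, `min_p`,
#'   `alpha`).
#' @export
run_lr_screen <- function(features, manifest, standardize = FALSE,
                          alpha = 0.05, correction = c("none", "bonferroni",
                                                       "bh")) {
  correction <- match.arg(correction)
  param_lists <- manifest_params(manifest$parameters)
  all_params <- unique(unlist(param_lists))
  missing <- setdiff(c(all_params, "group"), names(features))
  if (length(missing))
    stop("features table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  y <- features$group
  stopifnot(all(y %in% c(0, 1)))
  Xall <- as.matrix(features[all_params])
  if (standardize) Xall <- scale(Xall)

  m <- nrow(manifest)
  omnibus_stat <- omnibus_p <- cs <- nk <- rep(NA_real_, m)
  converged <- separated <- failed <- logical(m)
  overparam <- lengths(param_lists) >= length(y) / 3
  for (i in seq_len(m)) {
    Xi <- Xall[, param_lists[[i]], drop = FALSE]
    fit <- tryCatch(fit_logistic(Xi, y), error = function(e) NULL)
    if (is.null(fit)) {
      failed[i] <- TRUE
      next
    }
    ot <- omnibus_test(fit)
    omnibus_stat[i] <- ot$statistic
    omnibus_p[i] <- ot$p_value
    cs[i] <- cox_snell_r2(fit)
    nk[i] <- nagelkerke_r2(fit)
    converged[i] <- fit$converged
    separated[i] <- fit$separated
  }
  results <- data.frame(combination_id = manifest$combination_id,
                        period = manifest$period,
                        n_params = manifest$n_params,
                        omnibus_stat = omnibus_stat,
                        omnibus_p = omnibus_p,
                        cox_snell_r2 = cs, nagelkerke_r2 = nk,
                        converged = converged, separated = separated,
                        overparameterized = overparam, failed = failed)
  if (correction != "none") {
    method <- if (correction == "bh") "BH" else "bonferroni"
    results$p_adjusted <- stats::p.adjust(results$omnibus_p, method = method)
  }
  stable <- converged & !separated & !failed
  p_eval <- if (correction == "none") results$omnibus_p else results$p_adjusted
  structure(list(
    results = results,
    summary = list(n_combinations = m,
                   n_stable = sum(stable),
                   n_significant = sum(p_eval[stable] < alpha, na.rm = TRUE),
                   min_p = suppressWarnings(min(p_eval[stable], na.rm = TRUE)),
                   alpha = alpha)),
    class = "lr_screen")
}

#' Fit one manifest combination and return its full report
#'
#' Convenience path for inspecting a single combination the way the screen
#' summarises it, plus the per-variable Wald table.
#'
#' @inheritParams run_lr_screen
#' @param combination_id One `combination_id` from the manifest, or a
#'   character vector of predictor names.
#' @return List: `fit`, `omnibus`, `cox_snell_r2`, `nagelkerke_r2`,
#'   `wald` (data frame).
#' @export
lr_fit_combination <- function(features, manifest = NULL,
                               combination_id) {
  params <- if (!is.null(manifest) &&
                combination_id[1] %in% manifest$combination_id) {
    manifest_params(manifest$parameters[manifest$combination_id ==
                                          combination_id[1]])[[1]]
  } else {
    combination_id
  }
  fit <- fit_logistic(as.matrix(features[params]), features$group)
  list(fit = fit, omnibus = omnibus_test(fit),
       cox_snell_r2 = cox_snell_r2(fit),
       nagelkerke_r2 = nagelkerke_r2(fit),
       wald = wald_stats(fit))
}

#' Group comparison of feature-table variables
#'
#' Per-variable mean and SD by outcome group with a Welch two-sample t-test
#' p-value, in the layout of a baseline-characteristics table. The bypass
#' panel covers demographics, bypass burden metrics, bypass averages and the
#' bypass duration; the cross-clamp panel covers the cross-clamp metrics,
#' averages and duration only (demographics are not repeated).
#'
#' @param features Feature table with a binary `group` column.
#' @param period `"bypass"` or `"cross"` variable panel.
#' @param thresholds Thresholds used when the table was built.
#' @return Data frame: `variable`, `mean_g1`, `sd_g1`, `mean_g2`, `sd_g2`,
#'   `p_value` (`NA` with a flag when both groups have zero variance).
#' @export
group_compare <- function(features, period = c("bypass", "cross"),
                          thresholds = c(75, 65, 55)) {
  period <- match.arg(period)
  stopifnot(all(features$group %in% c(0, 1)))
  if (length(unique(features$group)) < 2)
    stop("both outcome groups must be non-empty", call. = FALSE)
  metric <- function(pre) as.vector(vapply(thresholds, function(th)
    sprintf("%s_%s_%d", pre, c("AMD", "Time_Under", "Area"), th),
    character(3)))
  vars <- if (period == "bypass") {
    c("Age", "Flow", "BSA", metric("Bypass"),
      "Bypass_Av_Sys", "Bypass_Av_Dia", "Bypass_Av_PLS", "Bypass_Av_SpO2",
      "Bypass_min")
  } else {
    c(metric("Cross"), "Cross_Av_Sys", "Cross_Av_Dia", "Cross_Av_SpO2",
      "Cross_min")
  }
  vars <- intersect(vars, names(features))
  g1 <- features[features$group == 0, , drop = FALSE]
  g2 <- features[features$group == 1, , drop = FALSE]
  rows <- lapply(vars, function(v) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    p <- if (sd(x1) == 0 && sd(x2) == 0) NA_real_ else
      tryCatch(t.test(x1, x2)$p.value, error = function(e) NA_real_)
    data.frame(variable = v, mean_g1 = mean(x1), sd_g1 = sd(x1),
               mean_g2 = mean(x2), sd_g2 = sd(x2), p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
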