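#' Required sample size for a two-group comparison
#'
#' Solves the exact noncentral-t power function of the two-sided two-sample
#' t-test (equal group sizes, common SD) for the per-group size needed to
#' detect a standardized mean difference `effect_d` (Cohen's d), rounds up,
#' and doubles it for the total. At d = 0.5, 80% power and alpha = 0.05 this
#' gives 64 per group, 128 patients in total.
#'
#' @param effect_d Standardized mean difference to detect (> 0).
#' @param power Target power, in `(0, 1)`.
#' @param alpha Two-sided significance level, in `(0, 1)`; must be below
#'   `power`.
#' @return List: `n_total`, `n_per_group`, `achieved_power` (power at the
#'   rounded-up per-group size).
#' @export
#' @examples
#' power_sample_size(0.5, 0.80, 0.05)$n_total  # 128
power_sample_size <- function(effect_d, power = 0.80, alpha = 0.05) {
  stopifnot(effect_d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha)
    stop("requested power must exceed the significance level", call. = FALSE)
  sol <- power.t.test(delta = effect_d, sd = 1, sig.level = alpha,
                      power = power, type = "two.sample",
                      alternative = "two.sided")
  n_per_group <- ceiling(sol$n)
  achieved <- power.t.test(n = n_per_group, delta = effect_d, sd = 1,
                           sig.level = alpha, type = "two.sample",
                           alternative = "two.sided")$power
  list(n_total = 2L * n_per_group, n_per_group = n_per_group,
       achieved_power = achieved)
}

format_mean_sd <- function(m, s, digits = 2) {
  sprintf("%s ± %s", signif(m, digits + 2), signif(s, digits + 2))
}

#' Render screen outputs as report tables
#'
#' Produces the conventional report layouts: baseline group-comparison
#' tables (mean +/- SD per group with the Welch p-value), a logistic model
#' summary (beta, SE, p, odds ratio and 95% CI per term), a pseudo-R-squared
#' table, and the classification report. Each `*_table()` returns a plain
#' data frame; `write_report()` writes whichever components are supplied as
#' CSV files and warns about the rest.
#'
#' @param gc Output of [group_compare()].
#' @return A data frame.
#' @export
group_table <- function(gc) {
  data.frame(variable = gc$variable,
             group1 = format_mean_sd(gc$mean_g1, gc$sd_g1),
             group2 = format_mean_sd(gc$mean_g2, gc$sd_g2),
             p = round(gc$p_value, 2))
}

#' @rdname group_table
#' @param fits Named list of [lr_fit_combination()] outputs (e.g. one per
#'   threshold).
#' @export
lr_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    w <- fits[[nm]]$wald
    w$model <- nm
    w
  })
  out <- do.call(rbind, rows)
  out[c("model", "term", "beta", "se", "p_value", "exp_beta",
        "ci_low", "ci_high")]
}

#' @rdname group_table
#' @export
r2_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    data.frame(model = nm,
               cox_snell_r2 = fits[[nm]]$cox_snell_r2,
               nagelkerke_r2 = fits[[nm]]$nagelkerke_r2)
  }))
}

#' @rdname group_table
#' @param report A [classification_report()].
#' @export
classification_table <- function(report) {
  pc <- report$per_class
  rbind(data.frame(row = as.character(pc$class), precision = pc$precision,
                   recall = pc$recall, f1 = pc$f1, support = pc$support),
        data.frame(row = "accuracy", precision = NA, recall = NA,
                   f1 = report$accuracy, support = sum(pc$support)),
        data.frame(row = "macro avg", precision = report$macro_avg["precision"],
                   recall = report$macro_avg["recall"],
                   f1 = report$macro_avg["f1"], support = sum(pc$support)),
        data.frame(row = "weighted avg",
                   precision = report$weighted_avg["precision"],
                   recall = report$weighted_avg["recall"],
                   f1 = report$weighted_avg["f1"], support = sum(pc$support)))
}

#' @rdname group_table
#' @param results Named list of report components; recognized names:
#'   `group_bypass`, `group_cross` (from [group_compare()]), `lr_fits`
#'   (named list for [lr_table()] / [r2_table()]), `lr_screen`, `rf_screen`,
#'   `classification` (a [classification_report()]), `pdp` (list of
#'   `pdp_curve`s).
#' @param dir Output directory.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(df, name) write.csv(df, file.path(dir, name),
                                      row.names = FALSE)
  if (!is.null(results$group_bypass))
    put(group_table(results$group_bypass), "group_compare_bypass.csv")
  if (!is.null(results$group_cross))
    put(group_table(results$group_cross), "group_compare_cross.csv")
  if (!is.null(results$lr_fits)) {
    put(lr_table(results$lr_fits), "lr_models.csv")
    put(r2_table(results$lr_fits), "lr_pseudo_r2.csv")
  }
  if (!is.null(results$lr_screen))
    put(results$lr_screen$results, "lr_screen.csv")
  if (!is.null(results$rf_screen))
    put(results$rf_screen$results, "rf_screen.csv")
  if (!is.null(results$classification))
    put(classification_table(results$classification),
        "classification_report.csv")
  if (!is.null(results$pdp)) {
    pd <- do.call(rbind, lapply(results$pdp, function(cv)
      data.frame(feature = cv$feature, grid_value = cv$grid,
                 pdp_value = cv$pd)))
    put(pd, "pdp_curves.csv")
  }
  known <- c("group_bypass", "group_cross", "lr_fits", "lr_screen",
             "rf_screen", "classification", "pdp")
  extra <- setdiff(names(results), known)
  if (length(extra))
    warning("unrecognized report components skipped: ",
            paste(extra, collapse = ", "), call. = FALSE)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: (optional) cohort simulation, artifact
#' filtering and segmentation, feature derivation, combination enumeration,
#' and the logistic and/or random-forest screens. A run manifest recording
#' the seed, thresholds and stage row counts accompanies the outputs so a
#' rerun with the same configuration reproduces them exactly.
#'
#' @param cohort A `hemo_cohort`; when `NULL`, one is simulated from
#'   `synth`.
#' @param synth A [synth_config()] used when `cohort` is `NULL`.
#' @param thresholds MAP thresholds, strictly decreasing.
#' @param lr,rf Toggles for the two screens.
#' @param rf_config A [forest_config()] for the forest screen.
#' @param rf_max_combos Cap on the number of (randomly thinned,
#'   seed-determined) combinations sent to the forest screen, which is far
#'   costlier per fit than the logistic screen; `Inf` screens all.
#' @param out_dir Optional directory; when given, the cohort CSVs, feature
#'   table, manifest, screen results and run manifest are persisted there.
#' @param seed Seed for the screens' randomness.
#' @return List of class `"hemoscreen_run"`: `features`, `manifest`,
#'   `group_bypass`, `group_cross`, `lr_screen`, `rf_screen`, `run_manifest`.
#' @export
run_pipeline <- function(cohort = NULL, synth = synth_config(),
                         thresholds = c(75, 65, 55), lr = TRUE, rf = FALSE,
                         rf_config = forest_config(),
                         rf_max_combos = 200, out_dir = NULL, seed = 1L) {
  stopifnot(all(diff(thresholds) < 0), all(thresholds > 0))
  if (is.null(cohort)) cohort <- generate_cohort(synth)
  features <- build_feature_table(cohort, thresholds)
  manifest <- build_manifest("both", thresholds)
  out <- list(features = features, manifest = manifest,
              group_bypass = group_compare(features, "bypass", thresholds),
              group_cross = group_compare(features, "cross", thresholds),
              lr_screen = NULL, rf_screen = NULL)
  if (lr) out$lr_screen <- run_lr_screen(features, manifest)
  if (rf) {
    mf <- manifest
    if (nrow(mf) > rf_max_combos) {
      set.seed(seed)
      mf <- mf[sort(sample(nrow(mf), rf_max_combos)), , drop = FALSE]
    }
    out$rf_screen <- run_rf_screen(features, mf, rf_config)
  }
  out$run_manifest <- list(
    seed = seed, thresholds = thresholds,
    n_patients = length(cohort), n_features = nrow(features),
    n_combinations = nrow(manifest),
    lr = lr, rf = rf,
    package_version = as.character(utils::packageVersion("hemoscreen")))
  class(out) <- "hemoscreen_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    write_report(out[c("group_bypass", "group_cross", "lr_screen",
                       "rf_screen")][
                         !vapply(out[c("group_bypass", "group_cross",
                                       "lr_screen", "rf_screen")],
                                 is.null, TRUE)],
                 out_dir)
    rm_df <- data.frame(field = names(out$run_manifest),
                        value = vapply(out$run_manifest, function(v)
                          paste(v, collapse = ","), ""))
    write.csv(rm_df, file.path(out_dir, "run_manifest.csv"),
              row.names = FALSE)
  }
  out
}
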