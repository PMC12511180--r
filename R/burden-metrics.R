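#' Hypotension burden metrics for one period segment
#'
#' Four threshold-based summaries of a mean-arterial-pressure (MAP) trace,
#' computed on the filtered samples of one surgical period. Each retained
#' sample is credited a fixed nominal duration (2.4 s by default), so for a
#' threshold \eqn{T} and MAP samples \eqn{m_i}:
#'
#' * **AMD** (absolute maximum decrease): \eqn{\max(0, T - \min_i m_i)}, the
#'   deepest excursion below the threshold, mmHg;
#' * **Time_Under**: \eqn{\#\{i : m_i < T\} \times dt}, seconds;
#' * **Area**: \eqn{\sum_i \max(0, T - m_i) \times dt}, the Riemann-sum MAP
#'   deficit, mmHg*s (above-threshold samples contribute zero);
#' * **TWA**: Area divided by the full segment duration
#'   \eqn{n \times dt}, mmHg.
#'
#' Samples at exactly the threshold count as *not* under it (strict `<`);
#' they contribute zero area either way.
#'
#' @param series A filtered [hemo_series()] segment.
#' @param threshold MAP threshold, mmHg (the screens use 75, 65, 55).
#' @return A single numeric value.
#' @name burden_metrics
#' @examples
#' s <- hemo_series(data.frame(time_s = c(0, 2.4, 4.8, 7.2),
#'                             ibp_sys = 100, ibp_dia = 50,
#'                             ibp_mean = c(70, 60, 50, 80)))
#' compute_amd(s, 65)         # 15
#' compute_time_under(s, 65)  # 4.8
#' compute_area(s, 65)        # 48
#' compute_twa(s, 65)         # 5
NULL

#' @rdname burden_metrics
#' @export
compute_amd <- function(series, threshold) {
  m <- series$ibp_mean
  m <- m[!is.na(m)]
  if (!length(m)) return(0)
  max(0, threshold - min(m))
}

#' @rdname burden_metrics
#' @export
compute_time_under <- function(series, threshold) {
  m <- series$ibp_mean
  sum(m < threshold, na.rm = TRUE) * nominal_dt(series)
}

#' @rdname burden_metrics
#' @export
compute_area <- function(series, threshold) {
  m <- series$ibp_mean
  m <- m[!is.na(m)]
  sum(pmax(threshold - m, 0)) * nominal_dt(series)
}

#' @rdname burden_metrics
#' @export
compute_twa <- function(series, threshold) {
  m <- series$ibp_mean
  m <- m[!is.na(m)]
  if (!length(m)) return(NA_real_)
  compute_area(series, threshold) / (length(m) * nominal_dt(series))
}

#' Period-average hemodynamic channels
#'
#' Arithmetic means of the retained samples' systolic, diastolic and SpO2
#' channels, plus pulse for the bypass period only (the pulse channel does
#' not exist during cross-clamp).
#'
#' @param series A filtered [hemo_series()] segment.
#' @param period `"bypass"` or `"cross"`.
#' @return Named list of means (`NA` for an empty segment).
#' @export
compute_period_averages <- function(series, period = c("bypass", "cross")) {
  period <- match.arg(period)
  avg <- function(x) if (is.null(x) || !any(!is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  out <- list(av_sys = avg(series$ibp_sys), av_dia = avg(series$ibp_dia),
              av_spo2 = avg(series$spo2))
  if (period == "bypass") out$av_pls <- avg(series$pulse)
  out
}

#' Build the per-patient feature table
#'
#' Runs artifact removal and period segmentation for every patient, then
#' derives the full predictor set of the combination screens: demographics
#' (`Age`, `Flow`, `BSA`), the nine bypass and nine cross-clamp burden
#' metrics (`*_AMD_T`, `*_Time_Under_T`, `*_Area_T` at each threshold), the
#' period-average channels, and the window durations `Bypass_min` /
#' `Cross_min` in minutes (taken from the recorded windows, not from sample
#' counts). Bypass metrics include the nested cross-clamp interval.
#'
#' @param cohort A `hemo_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param thresholds MAP thresholds in mmHg, strictly decreasing.
#' @return A data frame, one row per patient, columns `patient_id`, the 30
#'   predictors, and `group` (the outcome label; `NA` if unlabeled).
#'   Patients with an empty bypass segment after filtering are excluded with
#'   a warning.
#' @export
build_feature_table <- function(cohort, thresholds = c(75, 65, 55)) {
  stopifnot(all(diff(thresholds) < 0), all(thresholds > 0))
  rows <- lapply(cohort, function(r) {
    clean <- remove_artifacts(r$series)
    bp <- segment_period(r, "bypass", series = clean)
    cr <- segment_period(r, "cross", series = clean)
    if (nrow(bp) == 0) {
      warning("patient ", r$patient_id,
              " has an empty bypass segment after filtering; excluded",
              call. = FALSE)
      return(NULL)
    }
    row <- list(patient_id = r$patient_id,
                Age = r$age, Flow = r$flow, BSA = r$bsa)
    for (th in thresholds) {
      row[[sprintf("Bypass_AMD_%d", th)]] <- compute_amd(bp, th)
      row[[sprintf("Bypass_Time_Under_%d", th)]] <- compute_time_under(bp, th)
      row[[sprintf("Bypass_Area_%d", th)]] <- compute_area(bp, th)
    }
    av <- compute_period_averages(bp, "bypass")
    row$Bypass_Av_Sys <- av$av_sys
    row$Bypass_Av_Dia <- av$av_dia
    row$Bypass_Av_PLS <- av$av_pls
    row$Bypass_Av_SpO2 <- av$av_spo2
    for (th in thresholds) {
      row[[sprintf("Cross_AMD_%d", th)]] <- compute_amd(cr, th)
      row[[sprintf("Cross_Time_Under_%d", th)]] <- compute_time_under(cr, th)
      row[[sprintf("Cross_Area_%d", th)]] <- compute_area(cr, th)
    }
    avc <- compute_period_averages(cr, "cross")
    row$Cross_Av_Sys <- avc$av_sys
    row$Cross_Av_Dia <- avc$av_dia
    row$Cross_Av_SpO2 <- avc$av_spo2
    row$Bypass_min <- diff(r$bypass_window) / 60
    row$Cross_min <- diff(r$cross_window) / 60
    row$group <- r$group_label
    as.data.frame(row)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no patients with usable bypass data", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
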