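#' Flag artifactual samples in an arterial-pressure series
#'
#' Applies the five artifact criteria used for invasive blood-pressure
#' recordings:
#'
#' 1. IBP Systolic <= 20 mmHg or >= 300 mmHg;
#' 2. IBP Systolic <= IBP Diastolic + 5 mmHg;
#' 3. IBP Diastolic <= 5 mmHg or >= 225 mmHg;
#' 4. IBP Systolic variation within 1 min (either direction) >= 80 mmHg;
#' 5. IBP Systolic variation within 2 min (either direction) >= 40 mmHg.
#'
#' The windowed criteria 4--5 are evaluated on the raw input in a single
#' pass: sample *i* is flagged when its systolic value differs by at least
#' the stated amount from *any* earlier sample within the trailing 60 s /
#' 120 s window (the later reading of an offending pair is treated as the
#' artifact). The returned set is the union over all five criteria.
#'
#' @param series A [hemo_series()]; samples with missing pressure values are
#'   ignored by the criteria (see [remove_artifacts()]).
#' @param bounds Optional overrides for the static thresholds, a list with
#'   elements `sys_range = c(low, high)`, `pp_margin`, `dia_range`,
#'   `jump_60`, `jump_120`.
#' @return Sorted integer vector of flagged sample indices (1-based), with a
#'   `"by_criterion"` attribute giving the per-criterion index sets.
#' @export
#' @examples
#' s <- hemo_series(data.frame(time_s = c(0, 30), ibp_sys = c(100, 185),
#'                             ibp_dia = c(60, 70), ibp_mean = c(75, 100)))
#' flag_artifacts(s)  # the t = 30 sample jumps by 85 mmHg within 60 s
flag_artifacts <- function(series, bounds = list()) {
  b <- utils::modifyList(list(sys_range = c(20, 300), pp_margin = 5,
                              dia_range = c(5, 225),
                              jump_60 = 80, jump_120 = 40), bounds)
  n <- nrow(series)
  if (n == 0) {
    out <- integer(0)
    attr(out, "by_criterion") <- list()
    return(out)
  }
  sys <- series$ibp_sys
  dia <- series$ibp_dia
  t <- series$time_s
  ok <- !is.na(sys) & !is.na(dia)

  c1 <- ok & (sys <= b$sys_range[1] | sys >= b$sys_range[2])
  c2 <- ok & (sys <= dia + b$pp_margin)
  c3 <- ok & (dia <= b$dia_range[1] | dia >= b$dia_range[2])
  c4 <- jump_flags(t, sys, ok, window = 60, delta = b$jump_60)
  c5 <- jump_flags(t, sys, ok, window = 120, delta = b$jump_120)

  by_crit <- list(sys_range = which(c1), pulse_pressure = which(c2),
                  dia_range = which(c3), sys_jump_60 = which(c4),
                  sys_jump_120 = which(c5))
  out <- sort(unique(unlist(by_crit)))
  attr(out, "by_criterion") <- by_crit
  out
}

# trailing-window excursion check: flag i when some earlier valid sample j
# with t[i] - t[j] <= window has |sys[i] - sys[j]| >= delta
jump_flags <- function(t, sys, ok, window, delta) {
  n <- length(t)
  out <- logical(n)
  lo <- 1L
  for (i in seq_len(n)) {
    if (!ok[i]) next
    while (t[i] - t[lo] > window) lo <- lo + 1L
    if (lo < i) {
      w <- sys[lo:(i - 1L)]
      w <- w[ok[lo:(i - 1L)]]
      if (length(w) &&
          (max(w) - sys[i] >= delta || sys[i] - min(w) >= delta))
        out[i] <- TRUE
    }
  }
  out
}

#' Remove artifactual and incomplete samples from a series
#'
#' Drops samples with missing pressure channels, then removes every sample
#' flagged by [flag_artifacts()]. Flags are computed once on the raw input
#' (a single pass, not iterated to a fixed point), and retained samples are
#' returned unchanged and in their original order.
#'
#' @inheritParams flag_artifacts
#' @return A [hemo_series()] of the retained samples, with attribute
#'   `"filter_report"` (counts of removed samples: incomplete, per criterion,
#'   total removed, retained).
#' @export
remove_artifacts <- function(series, bounds = list()) {
  complete <- !is.na(series$ibp_sys) & !is.na(series$ibp_dia) &
    !is.na(series$ibp_mean)
  kept <- hs_subset(series, which(complete))
  flags <- flag_artifacts(kept, bounds)
  out <- hs_subset(kept, setdiff(seq_len(nrow(kept)), flags))
  attr(out, "bypass_window") <- attr(series, "bypass_window")
  attr(out, "cross_window") <- attr(series, "cross_window")
  by_crit <- attr(flags, "by_criterion")
  attr(out, "filter_report") <- c(
    n_input = nrow(series),
    n_incomplete = sum(!complete),
    vapply(by_crit, length, 1L),
    n_flagged = length(flags),
    n_retained = nrow(out))
  out
}

#' Extract the bypass or cross-clamp segment of a patient record
#'
#' Returns the samples whose timestamps fall in the half-open window
#' `[start_s, end_s)` of the requested period. The cross-clamp segment drops
#' the pulse channel (there is no heartbeat while the aorta is clamped).
#'
#' @param record A patient record (element of a `hemo_cohort`), or a
#'   `hemo_series` carrying `bypass_window` / `cross_window` attributes.
#' @param period `"bypass"` or `"cross"`.
#' @param series Optional replacement series (e.g. the filtered series) to
#'   segment using `record`'s windows.
#' @return A [hemo_series()]; empty windows give an empty series.
#' @export
segment_period <- function(record, period = c("bypass", "cross"),
                           series = NULL) {
  period <- match.arg(period)
  if (is.null(series)) {
    series <- if (inherits(record, "hemo_series")) record else record$series
  }
  win <- if (inherits(record, "hemo_series")) {
    attr(record, if (period == "bypass") "bypass_window" else "cross_window")
  } else {
    record[[if (period == "bypass") "bypass_window" else "cross_window"]]
  }
  if (is.null(win)) stop("record carries no ", period, " window", call. = FALSE)
  out <- hs_subset(series, which(series$time_s >= win[1] &
                                   series$time_s < win[2]))
  if (period == "cross") out$pulse <- NULL
  out
}
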