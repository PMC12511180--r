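#' Per-threshold combination groups
#'
#' The screens draw predictor subsets from one roster per MAP threshold and
#' period. A bypass-period group has 12 parameters: the three demographics,
#' the three threshold-specific burden metrics, four period averages and the
#' two window durations; nine of these (everything except the burden
#' metrics) are common to all three thresholds. A cross-clamp group has 11
#' parameters (no pulse average) with eight common.
#'
#' @param period `"bypass"` or `"cross"`.
#' @param threshold MAP threshold, mmHg.
#' @return `threshold_group()`: a list of class `"combination_group"` with
#'   `period`, `threshold`, `params` (ordered roster) and `common`
#'   (threshold-independent subset). `build_groups()`: a list of the three
#'   groups at 75, 65 and 55 mmHg.
#' @export
#' @examples
#' g <- threshold_group("bypass", 55)
#' length(g$params)  # 12
#' length(g$common)  # 9
threshold_group <- function(period = c("bypass", "cross"), threshold) {
  period <- match.arg(period)
  if (period == "bypass") {
    params <- c("Age", "Flow", "BSA",
                sprintf("Bypass_AMD_%d", threshold),
                sprintf("Bypass_Time_Under_%d", threshold),
                sprintf("Bypass_Area_%d", threshold),
                "Bypass_Av_Sys", "Bypass_Av_Dia", "Bypass_Av_PLS",
                "Bypass_Av_SpO2", "Bypass_min", "Cross_min")
  } else {
    params <- c("Age", "Flow", "BSA",
                sprintf("Cross_AMD_%d", threshold),
                sprintf("Cross_Time_Under_%d", threshold),
                sprintf("Cross_Area_%d", threshold),
                "Cross_Av_Sys", "Cross_Av_Dia", "Cross_Av_SpO2",
                "Bypass_min", "Cross_min")
  }
  common <- params[!grepl(sprintf("_%d$", threshold), params)]
  structure(list(period = period, threshold = threshold,
                 params = params, common = common),
            class = "combination_group")
}

#' @rdname threshold_group
#' @param thresholds MAP thresholds for the three groups.
#' @export
build_groups <- function(period = c("bypass", "cross"),
                         thresholds = c(75, 65, 55)) {
  period <- match.arg(period)
  lapply(thresholds, function(th) threshold_group(period, th))
}

#' Enumerate every non-empty predictor subset of a group
#'
#' Walks all `2^n - 1` non-empty subsets of the group roster in
#' deterministic order (lexicographic by bitmask, bit k = roster position
#' k + 1). Each subset becomes a combination key: its period, a threshold
#' tag (dropped when the subset uses only threshold-independent parameters,
#' since such subsets are identical across the three groups), and the
#' parameter list.
#'
#' @param group A [threshold_group()].
#' @return Data frame with columns `period`, `threshold_tag` (`NA` for
#'   common-only subsets), `n_params`, `parameters` (`;`-joined in roster
#'   order) and `key` (the deduplication identity: period plus the sorted
#'   name-set).
#' @export
enumerate_subsets <- function(group) {
  stopifnot(inherits(group, "combination_group"))
  p <- group$params
  n <- length(p)
  if (n > 25) stop("group too large to enumerate", call. = FALSE)
  masks <- seq_len(2^n - 1)
  bits <- bitwShiftL(1L, 0:(n - 1))
  subsets <- lapply(masks, function(m) p[bitwAnd(m, bits) != 0])
  common_only <- vapply(subsets, function(s) all(s %in% group$common), TRUE)
  data.frame(
    period = group$period,
    threshold_tag = ifelse(common_only, NA_real_, group$threshold),
    n_params = vapply(subsets, length, 1L),
    parameters = vapply(subsets, paste, "", collapse = ";"),
    key = paste0(group$period, "|",
                 vapply(subsets, function(s) paste(sort(s), collapse = ";"),
                        "")))
}

#' Deduplicate combination keys across threshold groups
#'
#' Subsets built only from the common (threshold-independent) parameters
#' appear once per threshold group; counting them three times would repeat
#' the identical analysis. Two keys are duplicates when their period and
#' name-set coincide, so for one period with group size `n` and `c` common
#' parameters the unique count is `3 * (2^n - 1) - 2 * (2^c - 1)`.
#'
#' @param keys Row-bound output of [enumerate_subsets()] for the three
#'   threshold groups of a single period.
#' @return The unique rows (first occurrence kept, order preserved).
#' @export
#' @examples
#' keys <- do.call(rbind, lapply(build_groups("cross"), enumerate_subsets))
#' nrow(deduplicate(keys))  # 5631
deduplicate <- function(keys) {
  if (length(unique(keys$period)) > 1)
    stop("deduplicate expects keys from a single period", call. = FALSE)
  out <- keys[!duplicated(keys$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total number of unique analyses across both periods
#'
#' The bypass and cross-clamp screens are reported as one total; subsets
#' common to both periods (demographics and durations) are intentionally
#' *not* merged across periods, the two per-period counts are summed.
#'
#' @param bypass_unique,cross_unique Deduplicated key data frames (or bare
#'   counts).
#' @param global_dedup If `TRUE`, additionally merge subsets whose name-sets
#'   coincide across the two periods before counting.
#' @return Integer count.
#' @export
total_analyses <- function(bypass_unique, cross_unique,
                           global_dedup = FALSE) {
  cnt <- function(x) if (is.data.frame(x)) nrow(x) else as.integer(x)
  if (global_dedup && is.data.frame(bypass_unique) &&
      is.data.frame(cross_unique)) {
    strip <- function(k) sub("^[a-z]+\\|", "", k)
    return(length(unique(c(strip(bypass_unique$key),
                           strip(cross_unique$key)))))
  }
  cnt(bypass_unique) + cnt(cross_unique)
}

#' Build the full deduplicated combination manifest
#'
#' Enumerates and deduplicates the predictor subsets of the requested
#' period(s) and assigns stable combination identifiers. With the default
#' thresholds this yields 11,263 bypass, 5,631 cross-clamp and 16,894 total
#' combinations.
#'
#' @param period `"bypass"`, `"cross"` or `"both"`.
#' @param thresholds MAP thresholds of the three groups per period.
#' @return Data frame with `combination_id`, `period`, `threshold_tag`,
#'   `n_params`, `parameters` (`;`-joined).
#' @export
build_manifest <- function(period = c("both", "bypass", "cross"),
                           thresholds = c(75, 65, 55)) {
  period <- match.arg(period)
  periods <- if (period == "both") c("bypass", "cross") else period
  parts <- lapply(periods, function(p) {
    keys <- do.call(rbind, lapply(build_groups(p, thresholds),
                                  enumerate_subsets))
    u <- deduplicate(keys)
    u$combination_id <- sprintf("%s_%05d", p, seq_len(nrow(u)))
    u
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[c("combination_id", "period", "threshold_tag", "n_params",
        "parameters")]
}

manifest_params <- function(parameters) strsplit(parameters, ";", fixed = TRUE)
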