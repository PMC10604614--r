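#' Construct a tacrolimus trough series
#'
#' @param day Sampling days post-transplant (strictly increasing after
#'   sorting; duplicates are an error).
#' @param level Trough whole-blood levels, ng/mL, strictly positive.
#' @param dose Daily dose in mg at each sampling day (recycled).
#' @return A `data.frame` of class `tacro_series`, sorted by day.
#' @export
tacrolimus_series <- function(day, level, dose = NA_real_) {
  if (length(day) == 0L) {
    stop("series must contain at least one observation", call. = FALSE)
  }
  if (length(level) != length(day)) {
    stop("`day` and `level` lengths differ", call. = FALSE)
  }
  if (any(is.na(level)) || any(level <= 0)) {
    stop("trough levels must be positive", call. = FALSE)
  }
  if (anyDuplicated(day)) {
    stop("sampling days must be unique", call. = FALSE)
  }
  o <- order(day)
  out <- data.frame(
    day = as.numeric(day)[o],
    level = as.numeric(level)[o],
    dose = rep_len(as.numeric(dose), length(day))[o]
  )
  class(out) <- c("tacro_series", "data.frame")
  out
}

#' @noRd
as_series <- function(series) {
  if (inherits(series, "tacro_series")) {
    return(series)
  }
  if (is.data.frame(series)) {
    return(tacrolimus_series(series$day, series$level,
                             if ("dose" %in% names(series)) series$dose
                             else NA_real_))
  }
  stop("`series` must be a tacro_series or a data.frame", call. = FALSE)
}

# Time (in days) spent <= c on the linear segment (t1,y1)-(t2,y2).
#' @noRd
segment_time_le <- function(t1, t2, y1, y2, c) {
  dt <- t2 - t1
  if (y1 == y2) {
    return(if (y1 <= c) dt else 0)
  }
  lo <- min(y1, y2)
  hi <- max(y1, y2)
  dt * clamp((c - lo) / (hi - lo), 0, 1)
}

#' Time in therapeutic range by the Rosendaal method
#'
#' The trough trajectory is taken as piecewise linear between consecutive
#' observations; range-crossing times are solved exactly on each segment
#' and the time in range and time above range are expressed as percentages
#' of the observation span (first to last day). Boundary levels (exactly
#' `low` or `high`) count as in range; "above" is strict.
#'
#' @param series A [tacrolimus_series()] (or data.frame with `day`,
#'   `level`); at least two observations.
#' @param low,high Therapeutic range bounds in ng/mL (default 8-12).
#' @return List with `percent_in_range`, `percent_above`, `percent_below`
#'   (the three sum to 100).
#' @examples
#' s <- tacrolimus_series(day = c(0, 8), level = c(6, 14))
#' rosendaal_ttr(s)  # 50% in range, 25% above
#' @export
rosendaal_ttr <- function(series, low = 8, high = 12) {
  s <- as_series(series)
  if (nrow(s) < 2L) {
    stop("Rosendaal interpolation needs at least two observations",
         call. = FALSE)
  }
  if (low >= high) {
    stop("`low` must be below `high`", call. = FALSE)
  }
  t_in <- 0
  t_above <- 0
  for (i in seq_len(nrow(s) - 1L)) {
    t1 <- s$day[i]; t2 <- s$day[i + 1L]
    y1 <- s$level[i]; y2 <- s$level[i + 1L]
    le_high <- segment_time_le(t1, t2, y1, y2, high)
    le_low <- segment_time_le(t1, t2, y1, y2, low)
    in_seg <- le_high - le_low
    # constant segments sitting exactly on `low` belong in range
    if (y1 == y2 && y1 == low) {
      in_seg <- t2 - t1
    }
    t_in <- t_in + in_seg
    t_above <- t_above + (t2 - t1) - le_high
  }
  span <- s$day[nrow(s)] - s$day[1L]
  list(
    percent_in_range = 100 * t_in / span,
    percent_above = 100 * t_above / span,
    percent_below = 100 - 100 * (t_in + t_above) / span
  )
}

#' Intra-patient variability of tacrolimus levels
#'
#' CV% = 100 * sd / mean over all trough levels, using the sample (n - 1)
#' standard deviation.
#'
#' @param series A [tacrolimus_series()] or numeric vector of levels
#'   (at least two values).
#' @return CV in percent.
#' @export
cv_percent <- function(series) {
  levels <- if (is.numeric(series)) series else as_series(series)$level
  if (length(levels) < 2L) {
    stop("CV needs at least two observations", call. = FALSE)
  }
  100 * stats::sd(levels) / mean(levels)
}

#' Concentration/dose ratio and fast-metabolizer flag
#'
#' @param trough_level Trough level, ng/mL.
#' @param daily_dose Total daily dose, mg (> 0).
#' @param fast_threshold Ratio below which a patient is labelled a fast
#'   metabolizer (default 1.05; strict comparison, a ratio of exactly 1.05
#'   is not fast).
#' @return List with `ratio` and `fast_metabolizer`.
#' @export
cd_ratio <- function(trough_level, daily_dose, fast_threshold = 1.05) {
  if (any(is.na(daily_dose)) || any(daily_dose <= 0)) {
    stop("`daily_dose` must be positive", call. = FALSE)
  }
  ratio <- trough_level / daily_dose
  list(ratio = ratio, fast_metabolizer = ratio < fast_threshold)
}

#' Low-exposure flags
#'
#' Flags whether any trough level falls strictly below each threshold at
#' any time in the series (a level of exactly 5.0 does not trip the
#' 5 ng/mL flag).
#'
#' @param series A [tacrolimus_series()] or numeric levels.
#' @param thresholds Numeric thresholds, default `c(5, 6)` ng/mL.
#' @return Named logical vector (`any_below_5`, `any_below_6`, ...).
#' @export
below_threshold_flags <- function(series, thresholds = c(5, 6)) {
  levels <- if (is.numeric(series)) series else as_series(series)$level
  if (length(levels) == 0L) {
    stop("series is empty", call. = FALSE)
  }
  out <- vapply(thresholds, function(t) any(levels < t), logical(1))
  names(out) <- sprintf("any_below_%g", thresholds)
  out
}

#' Summarize immunosuppressive exposure over the first month
#'
#' Assembles all tacrolimus exposure metrics for one patient: Rosendaal
#' time in (and above) the 8-12 ng/mL range, mean/SD/CV of levels, the
#' month-1 trough (observation nearest day 30, later day on ties), the
#' concentration/dose ratio at that observation with the fast-metabolizer
#' flag, low-exposure flags, and the mycophenolic acid trough passed
#' through unchanged.
#'
#' @param series A [tacrolimus_series()] with at least two observations
#'   and doses recorded.
#' @param mpa_trough Mycophenolic acid trough, mg/L (pass-through).
#' @return A list of class `exposure_metrics`.
#' @export
summarize_exposure <- function(series, mpa_trough = NA_real_) {
  s <- as_series(series)
  ttr <- rosendaal_ttr(s)
  i_m1 <- which.min(abs(s$day - 30) - 1e-9 * s$day)  # nearest day 30, later wins ties
  trough_m1 <- s$level[i_m1]
  cd <- if (is.na(s$dose[i_m1])) {
    list(ratio = NA_real_, fast_metabolizer = NA)
  } else {
    cd_ratio(trough_m1, s$dose[i_m1])
  }
  flags <- below_threshold_flags(s)
  structure(
    list(
      ttr_8_12 = ttr$percent_in_range,
      ttr_above_12 = ttr$percent_above,
      mean_level = mean(s$level),
      sd_level = stats::sd(s$level),
      cv_percent = cv_percent(s),
      trough_month1 = trough_m1,
      cd_ratio = cd$ratio,
      fast_metabolizer = cd$fast_metabolizer,
      any_below_5 = unname(flags["any_below_5"]),
      any_below_6 = unname(flags["any_below_6"]),
      mpa_trough = mpa_trough
    ),
    class = "exposure_metrics"
  )
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<exposure_metrics> TTR 8-12: %.1f%%, above 12: %.1f%% | ",
           "CV %.1f%% | month-1 trough %.1f ng/mL (C/D %.2f%s)\n"),
    x$ttr_8_12, x$ttr_above_12, x$cv_percent, x$trough_month1,
    x$cd_ratio, if (isTRUE(x$fast_metabolizer)) ", fast metabolizer" else ""
  ))
  invisible(x)
}
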