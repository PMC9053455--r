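#' @keywords internal
activity_classes <- function() {
  c("non_active", "below_healthy", "healthy", "extra_healthy")
}

check_minutes <- function(records) {
  cols <- c("vigorous_min", "moderate_min", "walking_min")
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0L) {
    stop("microdata is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in cols) {
    x <- records[[col]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      stop("column '", col, "' must be finite and numeric")
    }
    if (any(x < 0)) {
      stop("column '", col, "' contains negative minutes")
    }
  }
  invisible(records)
}

#' Moderate-equivalent weekly activity minutes
#'
#' Aggregates weekly minutes of activity at three intensities onto a single
#' moderate-intensity scale: one vigorous minute counts as two moderate
#' minutes and one walking minute as half a moderate minute, following the
#' WHO intensity-equivalence convention used for adults aged 18-64.
#'
#' @param records A data frame with numeric columns `vigorous_min`,
#'   `moderate_min` and `walking_min` (all non-negative, minutes per week).
#' @return A numeric vector of moderate-equivalent minutes per week, one
#'   element per row of `records`.
#' @examples
#' moderate_equivalent_minutes(
#'   data.frame(vigorous_min = 75, moderate_min = 0, walking_min = 0)
#' ) # 150
#' @export
moderate_equivalent_minutes <- function(records) {
  check_minutes(records)
  2 * records$vigorous_min + records$moderate_min + 0.5 * records$walking_min
}

#' Classify respondents into the four activity health categories
#'
#' Applies the WHO-guideline classification: respondents reporting zero
#' minutes in all three intensities are `non_active`; otherwise the
#' moderate-equivalent total places them `below_healthy` (< 150 min/week),
#' `healthy` (150 to < 300) or `extra_healthy` (>= 300). Both guideline
#' thresholds are inclusive at the lower end, matching the phrases
#' "below 150" and "300 or more".
#'
#' @inheritParams moderate_equivalent_minutes
#' @param thresholds Numeric length-2 vector `c(lower, upper)` of
#'   moderate-equivalent thresholds in minutes/week; default `c(150, 300)`.
#' @return A factor with levels `non_active`, `below_healthy`, `healthy`,
#'   `extra_healthy`, ordered from least to most active.
#' @export
classify_activity <- function(records, thresholds = c(150, 300)) {
  stopifnot(is.numeric(thresholds), length(thresholds) == 2L,
            thresholds[1] > 0, thresholds[2] > thresholds[1])
  mem <- moderate_equivalent_minutes(records)
  none <- records$vigorous_min == 0 & records$moderate_min == 0 &
    records$walking_min == 0
  cls <- ifelse(none, "non_active",
         ifelse(mem < thresholds[1], "below_healthy",
         ifelse(mem < thresholds[2], "healthy", "extra_healthy")))
  factor(cls, levels = activity_classes(), ordered = TRUE)
}

#' Restrict microdata to the working-age population
#'
#' Keeps respondents inside the WHO adult guideline bracket (default 18-64,
#' inclusive on both ends) and records the sample reduction, mirroring the
#' restriction applied before any regional rate is estimated.
#'
#' @param records Microdata data frame with an integer-valued `age` column.
#' @param age_range Numeric length-2 inclusive age bracket; default `c(18, 64)`.
#' @return The filtered data frame, with attributes `n_before` and `n_after`.
#' @export
filter_working_age <- function(records, age_range = c(18, 64)) {
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
  if (!"age" %in% names(records)) stop("microdata is missing column 'age'")
  keep <- records$age >= age_range[1] & records$age <= age_range[2]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_before") <- nrow(records)
  attr(out, "n_after") <- nrow(out)
  message("age filter [", age_range[1], ", ", age_range[2], "]: ",
          nrow(records), " -> ", nrow(out), " respondents")
  out
}

#' Aggregate individual classifications into regional rate profiles
#'
#' Computes, for every region, the unweighted percentage of eligible
#' respondents in each of the four activity categories. Rates sum to 100 by
#' construction. Regions listed in `all_regions` but absent from the
#' (already age-filtered) microdata are dropped with a warning rather than
#' emitted as NaN rows.
#'
#' @param records Age-filtered microdata with `region_id` plus the three
#'   minute columns.
#' @param thresholds Passed to [classify_activity()].
#' @param all_regions Optional character vector of region ids expected in the
#'   output; regions with no eligible respondents are reported and dropped.
#' @return A data frame of class `pa_profile` with columns `region_id`,
#'   `rate_non_active`, `rate_below_healthy`, `rate_healthy`,
#'   `rate_extra_healthy` and `n_eligible`, sorted by `region_id`.
#' @export
regionalize <- function(records, thresholds = c(150, 300), all_regions = NULL) {
  if (!"region_id" %in% names(records)) {
    stop("microdata is missing column 'region_id'")
  }
  if (nrow(records) == 0L) stop("no respondents to regionalize")
  cls <- classify_activity(records, thresholds)
  tab <- table(region_id = records$region_id, class = cls)
  n <- rowSums(tab)
  rates <- sweep(unclass(tab), 1, n, "/") * 100
  out <- data.frame(
    region_id = rownames(tab),
    rate_non_active = rates[, "non_active"],
    rate_below_healthy = rates[, "below_healthy"],
    rate_healthy = rates[, "healthy"],
    rate_extra_healthy = rates[, "extra_healthy"],
    n_eligible = as.integer(n),
    stringsAsFactors = FALSE
  )
  if (!is.null(all_regions)) {
    empty <- setdiff(all_regions, out$region_id)
    if (length(empty) > 0L) {
      warning("dropping region(s) with no eligible respondents: ",
              paste(empty, collapse = ", "))
    }
  }
  out <- out[order(out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pa_profile", "data.frame")
  out
}
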