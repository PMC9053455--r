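require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("'", path, "' is missing column(s): ", paste(missing, collapse = ", "))
  }
}

bad_rows <- function(df, col, bad, path, why) {
  if (any(bad)) {
    # +1 for the header line
    lines <- which(bad) + 1L
    stop("'", path, "' column '", col, "' ", why, " at line(s) ",
         paste(utils::head(lines, 10), collapse = ", "))
  }
}

#' Read survey microdata from CSV
#'
#' Expects the header `respondent_id,region_id,age,vigorous_min,moderate_min,
#' walking_min` (extra columns are kept). Non-numeric or negative minute or
#' age cells are rejected with their line numbers.
#'
#' @param path Path to a UTF-8, decimal-point CSV file.
#' @return A validated microdata data frame.
#' @export
read_microdata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("respondent_id", "region_id", "age", "vigorous_min",
                        "moderate_min", "walking_min"), path)
  for (col in c("age", "vigorous_min", "moderate_min", "walking_min")) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad_rows(df, col, is.na(x) | !is.finite(x), path, "is non-numeric")
    bad_rows(df, col, x < 0, path, "is negative")
    df[[col]] <- x
  }
  df
}

#' Write survey microdata to CSV
#' @param records Microdata data frame.
#' @param path Output path.
#' @export
write_microdata <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read regional covariates from CSV
#'
#' Expects `region_id` plus the 14 indicator columns of [covariate_names()].
#' Sector employment shares and population age shares must each sum to 100
#' within `closure_slack` per region (default 0.5, real-data slack).
#'
#' @param path Path to a CSV file.
#' @param closure_slack Allowed deviation of compositional sums from 100.
#' @return A validated covariates data frame.
#' @export
read_covariates <- function(path, closure_slack = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("region_id", covariate_names()), path)
  for (col in covariate_names()) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad_rows(df, col, is.na(x) | !is.finite(x), path, "is non-numeric")
    df[[col]] <- x
  }
  for (col in share_cols()) {
    bad_rows(df, col, df[[col]] < 0 | df[[col]] > 100, path,
             "is outside [0, 100]")
  }
  sec <- rowSums(df[, sector_cols()])
  bad_rows(df, "sector shares", abs(sec - 100) > closure_slack, path,
           paste0("do not sum to 100 (±", closure_slack, ")"))
  pop <- rowSums(df[, pop_cols()])
  bad_rows(df, "population shares", abs(pop - 100) > closure_slack, path,
           paste0("do not sum to 100 (±", closure_slack, ")"))
  df
}

#' Write regional covariates to CSV
#' @param covariates Covariates data frame.
#' @param path Output path.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read regional activity profiles from CSV
#' @param path Path to a profile CSV written by [write_profiles()].
#' @return A `pa_profile` data frame.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("region_id", rate_cols(), "n_eligible"), path)
  sums <- rowSums(df[, rate_cols()])
  bad_rows(df, "rates", abs(sums - 100) > 1e-6, path, "do not sum to 100")
  class(df) <- c("pa_profile", "data.frame")
  df
}

#' Write regional activity profiles to CSV
#' @param profiles A `pa_profile` data frame.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics table
#'
#' Minimum, maximum, mean, median and standard deviation (n-1 denominator)
#' per numeric column.
#'
#' @param table A data frame with >= 2 rows.
#' @return Data frame `variable`, `min`, `max`, `mean`, `median`, `sd`.
#' @export
descriptive_stats <- function(table) {
  stopifnot(nrow(table) >= 2)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  rows <- lapply(num, function(v) {
    x <- table[[v]]
    data.frame(variable = v, min = min(x), max = max(x), mean = mean(x),
               median = stats::median(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
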