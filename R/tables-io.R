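# CSV ingest for the three tabular inputs.  Dialect: comma-separated,
# UTF-8, header row required, no index column.  All readers enforce the
# table invariants and report offending row numbers (1-based, excluding
# the header) in their errors.

.read_table <- function(path, required) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

.row_err <- function(path, rows, what) {
  stop("format error in ", path, ": ", what, " at row(s) ",
       paste(utils::head(rows, 10L), collapse = ", "),
       if (length(rows) > 10L) " ...", call. = FALSE)
}

#' Read a visit edge list
#'
#' Expects columns `origin_id`, `destination_id`, `period`,
#' `mean_daily_visits`.  Counts must be non-negative and
#' (origin, destination, period) triples unique.
#'
#' @param path CSV file path.
#' @return Data frame with the four columns, ids as character.
#' @export
read_visits <- function(path) {
  df <- .read_table(path, c("origin_id", "destination_id", "period",
                            "mean_daily_visits"))
  df$origin_id <- as.character(df$origin_id)
  df$destination_id <- as.character(df$destination_id)
  df$period <- as.character(df$period)
  df$mean_daily_visits <- as.numeric(df$mean_daily_visits)
  bad <- which(!is.finite(df$mean_daily_visits) | df$mean_daily_visits < 0)
  if (length(bad)) .row_err(path, bad, "negative or non-numeric mean_daily_visits")
  key <- paste(df$origin_id, df$destination_id, df$period, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) .row_err(path, dup, "duplicate (origin, destination, period)")
  df
}

#' Read a sample-coverage table
#'
#' Expects columns `origin_id`, `period`, `coverage`.  Coverage must be
#' strictly positive where present; an absent row means the origin's
#' coverage is undefined for that period (and the origin is treated as
#' undefined everywhere by [compute_lambda()]).
#'
#' @param path CSV file path.
#' @return Data frame with the three columns.
#' @export
read_coverage <- function(path) {
  df <- .read_table(path, c("origin_id", "period", "coverage"))
  df$origin_id <- as.character(df$origin_id)
  df$period <- as.character(df$period)
  df$coverage <- as.numeric(df$coverage)
  bad <- which(!is.finite(df$coverage) | df$coverage <= 0)
  if (length(bad)) .row_err(path, bad, "non-positive coverage")
  dup <- which(duplicated(paste(df$origin_id, df$period, sep = "\r")))
  if (length(dup)) .row_err(path, dup, "duplicate (origin, period)")
  df
}

#' Read an SES score table
#'
#' Expects columns `origin_id`, `er_score`, `eo_score` and optionally
#' `city` (defaulting to a single city).  Scores must be finite and each
#' origin must appear once.
#'
#' @param path CSV file path.
#' @return Data frame: `origin_id`, `er_score`, `eo_score`, `city`.
#' @export
read_ses <- function(path) {
  df <- .read_table(path, c("origin_id", "er_score", "eo_score"))
  df$origin_id <- as.character(df$origin_id)
  df$er_score <- as.numeric(df$er_score)
  df$eo_score <- as.numeric(df$eo_score)
  if (is.null(df$city)) df$city <- "city"
  df$city <- as.character(df$city)
  bad <- which(!is.finite(df$er_score) | !is.finite(df$eo_score))
  if (length(bad)) .row_err(path, bad, "non-finite score")
  dup <- which(duplicated(df$origin_id))
  if (length(dup)) .row_err(path, dup, "duplicate origin_id")
  df[, c("origin_id", "er_score", "eo_score", "city")]
}
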