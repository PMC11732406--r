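#' Aggregate mean daily outflow per origin
#'
#' Sums `mean_daily_visits` over all destination zones that are *not* in
#' the exclusion set for each origin, for one period.  Origins present in
#' the edge list whose every edge is excluded map to 0.
#'
#' @param visits visit edge list (see [read_visits()]).
#' @param excluded exclusion set from [find_excluded_pairs()] (or any
#'   data frame with `origin_id`, `destination_id`), or `NULL` for none.
#' @param period period label to aggregate.
#' @return Named numeric vector of total mean daily visits per origin id.
#' @export
aggregate_outflow <- function(visits, excluded, period) {
  if (!period %in% visits$period) {
    stop("input error: period '", period, "' absent from edge list",
         call. = FALSE)
  }
  v <- visits[visits$period == period, , drop = FALSE]
  all_origins <- unique(v$origin_id)
  if (!is.null(excluded) && nrow(excluded)) {
    key <- paste(v$origin_id, v$destination_id, sep = "\r")
    exkey <- paste(excluded$origin_id, excluded$destination_id, sep = "\r")
    v <- v[!key %in% exkey, , drop = FALSE]
  }
  out <- setNames(numeric(length(all_origins)), all_origins)
  if (nrow(v)) {
    sums <- rowsum(v$mean_daily_visits, group = v$origin_id)
    out[rownames(sums)] <- sums[, 1L]
  }
  out
}

#' Coverage-normalised log-ratio mobility change
#'
#' For each origin i with defined coverage in both periods,
#' `A = outflow_test(i) / C(i, test)`, `B = outflow_base(i) / C(i, base)`
#' and `lambda_mob = ln(A / B)` — the natural-log ratio of mean daily
#' outbound visits expressed as proportions of the sample coverage.
#' Coverage proxies the (fluctuating) device-panel size of the origin, so
#' the ratio is invariant to panel-size changes between periods.
#'
#' Origins that cannot be computed are omitted, never imputed, and
#' reported with a reason code: `no_coverage` (undefined in either
#' period — an origin undefined in one period is treated as undefined in
#' all), `zero_coverage`, `zero_outflow_test`, `zero_outflow_base`.
#'
#' @param outflow_test,outflow_base named vectors from
#'   [aggregate_outflow()], computed with the same exclusion set.
#' @param coverage coverage table (see [read_coverage()]).
#' @param period_test,period_base period labels to read coverage for.
#' @return List of class `mobility_change`: `lambda` (data frame
#'   `origin_id`, `A`, `B`, `lambda_mob`) and `exclusions` (data frame
#'   `origin_id`, `reason`).
#' @export
compute_lambda <- function(outflow_test, outflow_base, coverage,
                           period_test = "test", period_base = "baseline") {
  ids <- union(names(outflow_test), names(outflow_base))
  ct <- coverage[coverage$period == period_test, , drop = FALSE]
  cb <- coverage[coverage$period == period_base, , drop = FALSE]
  c_test <- setNames(ct$coverage, ct$origin_id)[ids]
  c_base <- setNames(cb$coverage, cb$origin_id)[ids]
  o_test <- outflow_test[ids]
  o_base <- outflow_base[ids]
  o_test[is.na(o_test)] <- 0
  o_base[is.na(o_base)] <- 0

  reason <- rep(NA_character_, length(ids))
  reason[is.na(c_test) | is.na(c_base)] <- "no_coverage"
  sel <- is.na(reason) & (c_test == 0 | c_base == 0)
  reason[sel] <- "zero_coverage"
  sel <- is.na(reason) & o_test == 0
  reason[sel] <- "zero_outflow_test"
  sel <- is.na(reason) & o_base == 0
  reason[sel] <- "zero_outflow_base"

  keep <- is.na(reason)
  A <- o_test[keep] / c_test[keep]
  B <- o_base[keep] / c_base[keep]
  lambda <- data.frame(
    origin_id = ids[keep],
    A = as.numeric(A),
    B = as.numeric(B),
    lambda_mob = as.numeric(log(A) - log(B)),
    stringsAsFactors = FALSE
  )
  exclusions <- data.frame(
    origin_id = ids[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  structure(list(lambda = lambda, exclusions = exclusions),
            class = "mobility_change")
}

#' @exportS3Method base::print
print.mobility_change <- function(x, ...) {
  cat("<mobility_change>", nrow(x$lambda), "origins,",
      nrow(x$exclusions), "omitted\n")
  if (nrow(x$lambda)) {
    cat(sprintf("  median lambda_mob: %.4f\n", median(x$lambda$lambda_mob)))
  }
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    cat("  omissions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summary of a mobility-change field
#'
#' Median, count and fixed-width histogram bin counts of `lambda_mob`
#' over the origins for which it is defined.
#'
#' @param x a `mobility_change` (from [compute_lambda()]) or a numeric
#'   vector of lambda values.
#' @param bin_width histogram bin width on the lambda scale.
#' @return List: `median`, `n`, `breaks`, `counts`.
#' @export
lambda_summary <- function(x, bin_width = 0.1) {
  v <- if (inherits(x, "mobility_change")) x$lambda$lambda_mob else as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("input error: no defined lambda values", call. = FALSE)
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi - 1e-12) breaks <- c(breaks, hi)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  list(median = median(v), n = length(v), breaks = breaks, counts = counts)
}
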