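#' Assign local decile bands
#'
#' Within each city, scores are ranked (average rank for ties) and cut at
#' the 10%, 20%, ..., 90% empirical quantiles of the ranks; decile 1
#' holds the lowest scores.  The assignment depends only on the ordering,
#' so it is invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores numeric vector of index scores.
#' @param city optional grouping vector (one label per score); a single
#'   city when omitted.
#' @return Integer vector of deciles 1-10.
#' @export
assign_deciles <- function(scores, city = NULL) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("input error: scores must be finite", call. = FALSE)
  }
  if (is.null(city)) city <- rep("city", length(scores))
  out <- integer(length(scores))
  for (ct in unique(city)) {
    sel <- city == ct
    x <- scores[sel]
    if (length(x) < 10L) {
      stop("input error: fewer than 10 origins in city '", ct, "'",
           call. = FALSE)
    }
    r <- rank(x, ties.method = "average")
    br <- quantile(r, probs = seq(0, 1, 0.1), names = FALSE)
    if (length(unique(br)) < 11L) {
      stop("degenerate stratification in city '", ct,
           "': tied scores collapse decile boundaries", call. = FALSE)
    }
    out[sel] <- as.integer(cut(r, breaks = br, include.lowest = TRUE,
                               labels = FALSE))
  }
  out
}

#' Decile table for an SES score table
#'
#' Convenience wrapper assigning local ER and EO deciles per city.
#'
#' @param seifa SES table (see [read_ses()]).
#' @return Data frame: `origin_id`, `city`, `er_decile`, `eo_decile`.
#' @export
seifa_deciles <- function(seifa) {
  data.frame(
    origin_id = seifa$origin_id,
    city = seifa$city,
    er_decile = assign_deciles(seifa$er_score, seifa$city),
    eo_decile = assign_deciles(seifa$eo_score, seifa$city),
    stringsAsFactors = FALSE
  )
}

.lambda_by_origin <- function(lambda) {
  if (inherits(lambda, "mobility_change")) lambda <- lambda$lambda
  setNames(lambda$lambda_mob, lambda$origin_id)
}

#' Median mobility change per decile
#'
#' Medians of `lambda_mob` within each decile band of one index, ordered
#' decile 1 to 10.  Origins without a defined lambda drop out; an empty
#' decile is an error naming the decile.
#'
#' @param lambda a `mobility_change` or its `lambda` data frame.
#' @param deciles decile table from [seifa_deciles()].
#' @param index `"ER"` or `"EO"`.
#' @return Numeric vector of 10 medians.
#' @export
decile_medians <- function(lambda, deciles, index = c("EO", "ER")) {
  index <- match.arg(index)
  lam <- .lambda_by_origin(lambda)
  col <- if (index == "ER") "er_decile" else "eo_decile"
  dec <- setNames(deciles[[col]], deciles$origin_id)[names(lam)]
  ok <- !is.na(dec)
  lam <- lam[ok]
  dec <- dec[ok]
  out <- numeric(10L)
  for (d in 1:10) {
    v <- lam[dec == d]
    if (!length(v)) {
      stop("input error: decile ", d, " of ", index,
           " has no origins with defined lambda", call. = FALSE)
    }
    out[d] <- median(v)
  }
  out
}

#' Joint ER x EO median grid
#'
#' Medians (and counts) of `lambda_mob` over origins jointly stratified
#' by ER decile (rows) and EO decile (columns).  Empty cells are `NA` in
#' the median grid and 0 in the count grid; they are reported as missing,
#' never interpolated.
#'
#' @inheritParams decile_medians
#' @return List with `median` and `count`, both 10 x 10 matrices with
#'   dimnames `er`/`eo` 1-10.
#' @export
joint_median_grid <- function(lambda, deciles) {
  lam <- .lambda_by_origin(lambda)
  er <- setNames(deciles$er_decile, deciles$origin_id)[names(lam)]
  eo <- setNames(deciles$eo_decile, deciles$origin_id)[names(lam)]
  ok <- !is.na(er) & !is.na(eo)
  lam <- lam[ok]; er <- er[ok]; eo <- eo[ok]
  med <- matrix(NA_real_, 10L, 10L, dimnames = list(er = 1:10, eo = 1:10))
  cnt <- matrix(0L, 10L, 10L, dimnames = list(er = 1:10, eo = 1:10))
  for (a in 1:10) {
    for (b in 1:10) {
      v <- lam[er == a & eo == b]
      cnt[a, b] <- length(v)
      if (length(v)) med[a, b] <- median(v)
    }
  }
  list(median = med, count = cnt)
}

#' Letter-value summary
#'
#' The letter-value generalisation of the boxplot: the median (depth
#' `(1 + n) / 2`), then fourths, eighths, sixteenths, ... via the halved
#' depth recursion `d[k+1] = (floor(d[k]) + 1) / 2`, interpolating
#' half-depths as the mean of the two adjacent order statistics.  Levels
#' beyond the fourths are added while the expected tail group at that
#' level (`n / 2^(k-1)` observations) still holds at least `min_group`
#' observations, so letter values are never computed from handfuls of
#' extreme points.
#'
#' @param values numeric vector, `n >= 1`.
#' @param min_group smallest expected tail group for which a level is
#'   still reported.
#' @return Data frame: `level` (M, F, E, D, C, ...), `depth`, `lower`,
#'   `upper` (equal for the median).
#' @export
letter_values <- function(values, min_group = 5L) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 1L) stop("input error: empty input", call. = FALSE)
  at_depth <- function(d) {
    lo <- (x[floor(d)] + x[ceiling(d)]) / 2
    hi <- (x[n + 1L - floor(d)] + x[n + 1L - ceiling(d)]) / 2
    c(lo, hi)
  }
  labels <- c("M", "F", "E", "D", "C", "B", "A", "Z", "Y", "X", "W")
  depths <- numeric(0)
  d <- (1 + n) / 2
  k <- 1L
  repeat {
    include <- if (k <= 2L) n >= 2L || k == 1L else n / 2^(k - 1L) >= min_group
    if (k > 1L && (!include || d < 1)) break
    depths[k] <- d
    if (k >= length(labels)) break
    d <- (floor(d) + 1) / 2
    k <- k + 1L
    if (floor(depths[k - 1L]) <= 1L) break  # depth 1 reached: extremes
  }
  vals <- t(vapply(depths, at_depth, numeric(2L)))
  data.frame(
    level = labels[seq_along(depths)],
    depth = depths,
    lower = vals[, 1L],
    upper = vals[, 2L],
    stringsAsFactors = FALSE
  )
}
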