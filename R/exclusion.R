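#' Excluded origin-destination pairs
#'
#' A visit of any duration inside a destination zone is counted with full
#' weight, so flows between an origin region and a destination zone that
#' touches or overlaps it are dominated by GPS jitter and purely local
#' movement.  Such pairs are excluded from outflow aggregation: a pair is
#' excluded iff the two polygons share any point (overlapping interiors
#' *or* touching boundaries, corner contact included).
#'
#' For axis-aligned rectangular cells (the synthetic grid) the predicate
#' reduces to exact closed-interval overlap of bounding boxes; general
#' polygons fall back to the full geometric test after a bounding-box
#' prefilter.
#'
#' @param origins,destinations [partition_set()]s.
#' @return Data frame of class `exclusion_set` with columns `origin_id`,
#'   `destination_id`, one row per excluded pair.
#' @export
find_excluded_pairs <- function(origins, destinations) {
  stopifnot(inherits(origins, "partition_set"),
            inherits(destinations, "partition_set"))
  ob <- origins$bboxes
  db <- destinations$bboxes
  o_rect <- vapply(origins$geoms, .poly_is_rect, logical(1L))
  d_rect <- vapply(destinations$geoms, .poly_is_rect, logical(1L))
  eps <- .geom_eps
  out_o <- integer(0)
  out_d <- integer(0)
  for (j in seq_along(destinations$ids)) {
    cand <- which(
      ob[, "xmin"] <= db[j, "xmax"] + eps & db[j, "xmin"] <= ob[, "xmax"] + eps &
      ob[, "ymin"] <= db[j, "ymax"] + eps & db[j, "ymin"] <= ob[, "ymax"] + eps
    )
    if (!length(cand)) next
    precise <- cand[!(o_rect[cand] & d_rect[j])]
    if (length(precise)) {
      hit <- vapply(precise, function(i) {
        .poly_intersects(origins$geoms[[i]], destinations$geoms[[j]])
      }, logical(1L))
      cand <- sort(c(setdiff(cand, precise), precise[hit]))
    }
    out_o <- c(out_o, cand)
    out_d <- c(out_d, rep.int(j, length(cand)))
  }
  res <- data.frame(
    origin_id = origins$ids[out_o],
    destination_id = destinations$ids[out_d],
    stringsAsFactors = FALSE
  )
  class(res) <- c("exclusion_set", "data.frame")
  res
}

#' Coverage container of each origin region
#'
#' Sample coverage for an origin is read from the destination zone that
#' *completely* contains it.  Origins contained by no single destination
#' zone (straddling a zone boundary) get `NA`: their coverage is
#' undefined and they drop out of the mobility-change statistic.
#' Destination interiors are pairwise disjoint, so at most one container
#' exists.
#'
#' @param origins,destinations [partition_set()]s.
#' @return Named character vector: for each origin id, the containing
#'   destination id or `NA`.
#' @export
coverage_container <- function(origins, destinations) {
  stopifnot(inherits(origins, "partition_set"),
            inherits(destinations, "partition_set"))
  ob <- origins$bboxes
  db <- destinations$bboxes
  eps <- .geom_eps
  out <- setNames(rep(NA_character_, length(origins$ids)), origins$ids)
  o_rect <- vapply(origins$geoms, .poly_is_rect, logical(1L))
  d_rect <- vapply(destinations$geoms, .poly_is_rect, logical(1L))
  for (i in seq_along(origins$ids)) {
    cand <- which(
      db[, "xmin"] <= ob[i, "xmin"] + eps & db[, "xmax"] >= ob[i, "xmax"] - eps &
      db[, "ymin"] <= ob[i, "ymin"] + eps & db[, "ymax"] >= ob[i, "ymax"] - eps
    )
    for (j in cand) {
      contained <- if (o_rect[i] && d_rect[j]) TRUE else {
        .poly_contains(destinations$geoms[[j]], origins$geoms[[i]])
      }
      if (contained) {
        out[i] <- destinations$ids[j]
        break
      }
    }
  }
  out
}
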