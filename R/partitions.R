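#' Partition sets
#'
#' A partition set holds the polygons tiling a city for one role: origin
#' regions (small, SA1-like, carrying resident population and SES scores)
#' or destination zones (coarser, DZN-like, used for visit counting).
#' Polygons use planar projected coordinates in km.  Within one role the
#' region ids are unique and polygon interiors are pairwise disjoint;
#' touching boundaries are expected (the partitions tile space).
#'
#' @param role `"origin"` or `"destination"`.
#' @param geoms named list of polygon coordinate matrices (n x 2, ring not
#'   closed), names are region ids.
#' @param regions data frame of per-region attributes with a `region_id`
#'   column matching `names(geoms)`; may carry `population`, `straddling`
#'   and SES score columns.
#' @param validate run the (quadratic, bbox-pruned) geometric validity and
#'   disjointness checks.  Construction-by-generator skips them.
#' @return An object of class `partition_set` with elements `role`, `ids`,
#'   `geoms`, `regions`, `centroids` (n x 2 matrix, rownames = ids) and
#'   `bboxes`.
#' @seealso [read_partitions()], [generate_partitions()]
#' @export
partition_set <- function(role, geoms, regions = NULL, validate = TRUE) {
  role <- match.arg(role, c("origin", "destination"))
  if (is.null(names(geoms)) || anyNA(names(geoms)) || any(names(geoms) == "")) {
    stop("every polygon must be named by its region_id", call. = FALSE)
  }
  ids <- names(geoms)
  if (anyDuplicated(ids)) {
    stop("duplicate region_id in ", role, " partitions: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  geoms <- lapply(geoms, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    # drop a repeated closing vertex if present
    if (nrow(p) > 3L && all(abs(p[1L, ] - p[nrow(p), ]) < .geom_eps)) {
      p <- p[-nrow(p), , drop = FALSE]
    }
    p
  })
  if (is.null(regions)) {
    regions <- data.frame(region_id = ids, stringsAsFactors = FALSE)
  }
  if (!"region_id" %in% names(regions)) {
    stop("`regions` must have a region_id column", call. = FALSE)
  }
  regions <- regions[match(ids, regions$region_id), , drop = FALSE]
  rownames(regions) <- NULL
  if (anyNA(regions$region_id)) {
    stop("`regions` is missing attribute rows for some polygons", call. = FALSE)
  }
  if (validate) {
    ok <- vapply(geoms, .poly_is_valid, logical(1L))
    if (!all(ok)) {
      stop("invalid polygon for region(s): ",
           paste(ids[!ok], collapse = ", "), call. = FALSE)
    }
  }
  centroids <- t(vapply(geoms, .poly_centroid, numeric(2L)))
  dimnames(centroids) <- list(ids, c("x", "y"))
  out <- structure(
    list(role = role, ids = ids, geoms = geoms, regions = regions,
         centroids = centroids, bboxes = .bbox_matrix(geoms)),
    class = "partition_set"
  )
  if (validate) .check_disjoint_interiors(out)
  out
}

# Pairwise-disjoint interiors within a role, with a bbox prefilter so grid
# cities only test neighbouring cells.
.check_disjoint_interiors <- function(ps) {
  n <- length(ps$ids)
  if (n < 2L) return(invisible(TRUE))
  bb <- ps$bboxes
  for (i in seq_len(n - 1L)) {
    cand <- which(
      bb[, "xmin"] < bb[i, "xmax"] - .geom_eps &
      bb[, "xmax"] > bb[i, "xmin"] + .geom_eps &
      bb[, "ymin"] < bb[i, "ymax"] - .geom_eps &
      bb[, "ymax"] > bb[i, "ymin"] + .geom_eps
    )
    cand <- cand[cand > i]
    for (j in cand) {
      if (.poly_interiors_overlap(ps$geoms[[i]], ps$geoms[[j]])) {
        stop("overlapping interiors within ", ps$role, " partitions: ",
             ps$ids[i], " and ", ps$ids[j], call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.partition_set <- function(x, ...) {
  cat("<partition_set> role:", x$role, "| regions:", length(x$ids), "\n")
  bb <- apply(x$bboxes, 2L, range)
  cat(sprintf("  extent: x [%.2f, %.2f] km, y [%.2f, %.2f] km\n",
              min(x$bboxes[, "xmin"]), max(x$bboxes[, "xmax"]),
              min(x$bboxes[, "ymin"]), max(x$bboxes[, "ymax"])))
  extra <- setdiff(names(x$regions), "region_id")
  if (length(extra)) cat("  attributes:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Number of regions in a partition set
#' @param x a `partition_set`.
#' @export
n_regions <- function(x) {
  stopifnot(inherits(x, "partition_set"))
  length(x$ids)
}

#' Read and write partition sets as GeoJSON
#'
#' Partitions are exchanged as RFC 7946 FeatureCollections of Polygon
#' features.  The `region_id` property is mandatory; any further scalar
#' properties (population, SES scores, straddling flags) round-trip into
#' the `regions` attribute table.  Coordinates are interpreted as planar
#' km (the pipeline never does geodesic math).
#'
#' @param path file path of a GeoJSON FeatureCollection.
#' @param role `"origin"` or `"destination"`.
#' @param validate check polygon validity and within-role disjointness.
#' @return `read_partitions()` returns a [partition_set()];
#'   `write_partitions()` returns `path` invisibly.
#' @export
read_partitions <- function(path, role, validate = TRUE) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("format error: ", path, " is not a GeoJSON FeatureCollection",
         call. = FALSE)
  }
  feats <- gj$features
  if (!length(feats)) stop("format error: no features in ", path, call. = FALSE)
  geoms <- vector("list", length(feats))
  props <- vector("list", length(feats))
  ids <- character(length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    pr <- f$properties
    if (is.null(pr$region_id)) {
      stop("format error: feature ", k, " has no region_id property",
           call. = FALSE)
    }
    ids[k] <- as.character(pr$region_id)
    if (!identical(f$geometry$type, "Polygon")) {
      stop("format error: feature ", ids[k], " is not a Polygon", call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(xy) c(xy[[1L]], xy[[2L]])))
    geoms[[k]] <- m
    props[[k]] <- pr[setdiff(names(pr), "region_id")]
  }
  if (anyDuplicated(ids)) {
    stop("format error: duplicate region_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(geoms) <- ids
  pnames <- unique(unlist(lapply(props, names)))
  regions <- data.frame(region_id = ids, stringsAsFactors = FALSE)
  for (nm in pnames) {
    regions[[nm]] <- vapply(props, function(p) {
      v <- p[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1L))
  }
  if ("straddling" %in% names(regions)) {
    regions$straddling <- as.logical(regions$straddling)
  }
  ps <- partition_set(role, geoms, regions, validate = validate)
  if (!all(vapply(ps$geoms, .poly_is_valid, logical(1L)))) {
    bad <- ps$ids[!vapply(ps$geoms, .poly_is_valid, logical(1L))]
    stop("format error: invalid polygon for feature(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ps
}

#' @rdname read_partitions
#' @param x a `partition_set` to write.
#' @export
write_partitions <- function(x, path) {
  stopifnot(inherits(x, "partition_set"))
  feats <- lapply(seq_along(x$ids), function(k) {
    p <- x$geoms[[k]]
    ring <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring per RFC 7946
    pr <- as.list(x$regions[k, , drop = FALSE])
    pr <- pr[!vapply(pr, function(v) is.na(v) || is.null(v), logical(1L))]
    list(
      type = "Feature",
      properties = pr,
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}
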