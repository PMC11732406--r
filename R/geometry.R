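# Planar geometry primitives for partition polygons.
#
# Polygons are simple closed rings given as n x 2 coordinate matrices in
# projected km, first vertex NOT repeated.  All predicates treat polygons
# as closed point sets: sharing a single boundary point already counts as
# intersecting (the conservative "adjacent or intersecting" reading used
# for the exclusion rule).  Computations are floating point with a small
# absolute tolerance, far below any meaningful feature size in km.
#
# Containment assumes effectively convex cells (axis-aligned grid cells,
# census-style compact zones): it checks vertex and edge-midpoint
# membership plus the absence of proper edge crossings.

.geom_eps <- 1e-9

.poly_bbox <- function(p) {
  c(min(p[, 1L]), min(p[, 2L]), max(p[, 1L]), max(p[, 2L]))
}

# n x 4 matrix (xmin, ymin, xmax, ymax) for a list of polygons
.bbox_matrix <- function(geoms) {
  out <- t(vapply(geoms, .poly_bbox, numeric(4L)))
  colnames(out) <- c("xmin", "ymin", "xmax", "ymax")
  out
}

.bbox_overlap <- function(a, b, eps = .geom_eps) {
  a[1L] <= b[3L] + eps && b[1L] <= a[3L] + eps &&
    a[2L] <= b[4L] + eps && b[2L] <= a[4L] + eps
}

.cross3 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(px, py, ax, ay, bx, by, eps = .geom_eps) {
  if (abs(.cross3(ax, ay, bx, by, px, py)) > eps * (1 + max(abs(c(ax, ay, bx, by))))) {
    return(FALSE)
  }
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}

# Closed point-in-polygon: TRUE on the boundary as well as the interior.
.point_in_poly <- function(px, py, poly, eps = .geom_eps) {
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    if (.on_segment(px, py, poly[j, 1L], poly[j, 2L], poly[i, 1L], poly[i, 2L], eps)) {
      return(TRUE)
    }
    j <- i
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2L]; yj <- poly[j, 2L]
    if ((yi > py) != (yj > py)) {
      xint <- poly[j, 1L] + (py - yj) * (poly[i, 1L] - poly[j, 1L]) / (yi - yj)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.point_strictly_in_poly <- function(px, py, poly, eps = .geom_eps) {
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    if (.on_segment(px, py, poly[j, 1L], poly[j, 2L], poly[i, 1L], poly[i, 2L], eps)) {
      return(FALSE)
    }
    j <- i
  }
  .point_in_poly(px, py, poly, eps)
}

# Segment intersection including touching endpoints and collinear overlap.
.seg_intersect <- function(a1, a2, b1, b2, eps = .geom_eps) {
  sc <- eps * (1 + max(abs(c(a1, a2, b1, b2))))
  o1 <- .cross3(a1[1L], a1[2L], a2[1L], a2[2L], b1[1L], b1[2L])
  o2 <- .cross3(a1[1L], a1[2L], a2[1L], a2[2L], b2[1L], b2[2L])
  o3 <- .cross3(b1[1L], b1[2L], b2[1L], b2[2L], a1[1L], a1[2L])
  o4 <- .cross3(b1[1L], b1[2L], b2[1L], b2[2L], a2[1L], a2[2L])
  if (o1 * o2 < -sc && o3 * o4 < -sc) return(TRUE)
  .on_segment(b1[1L], b1[2L], a1[1L], a1[2L], a2[1L], a2[2L], eps) ||
    .on_segment(b2[1L], b2[2L], a1[1L], a1[2L], a2[1L], a2[2L], eps) ||
    .on_segment(a1[1L], a1[2L], b1[1L], b1[2L], b2[1L], b2[2L], eps) ||
    .on_segment(a2[1L], a2[2L], b1[1L], b1[2L], b2[1L], b2[2L], eps)
}

# Proper crossing: intersection strictly interior to both, non-collinear.
.seg_proper_cross <- function(a1, a2, b1, b2, eps = .geom_eps) {
  sc <- eps * (1 + max(abs(c(a1, a2, b1, b2))))
  o1 <- .cross3(a1[1L], a1[2L], a2[1L], a2[2L], b1[1L], b1[2L])
  o2 <- .cross3(a1[1L], a1[2L], a2[1L], a2[2L], b2[1L], b2[2L])
  o3 <- .cross3(b1[1L], b1[2L], b2[1L], b2[2L], a1[1L], a1[2L])
  o4 <- .cross3(b1[1L], b1[2L], b2[1L], b2[2L], a2[1L], a2[2L])
  o1 * o2 < -sc && o3 * o4 < -sc
}

.poly_edges <- function(p) {
  n <- nrow(p)
  list(from = p, to = p[c(2:n, 1L), , drop = FALSE])
}

# Share-any-point predicate between two simple polygons (closed sets).
.poly_intersects <- function(a, b, eps = .geom_eps) {
  if (!.bbox_overlap(.poly_bbox(a), .poly_bbox(b), eps)) return(FALSE)
  for (i in seq_len(nrow(a))) {
    if (.point_in_poly(a[i, 1L], a[i, 2L], b, eps)) return(TRUE)
  }
  for (i in seq_len(nrow(b))) {
    if (.point_in_poly(b[i, 1L], b[i, 2L], a, eps)) return(TRUE)
  }
  ea <- .poly_edges(a); eb <- .poly_edges(b)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (.seg_intersect(ea$from[i, ], ea$to[i, ], eb$from[j, ], eb$to[j, ], eps)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# TRUE when the two polygons overlap on a set of positive area (touching
# boundaries alone do not count).  Used for the within-role disjointness
# validity check.
.poly_interiors_overlap <- function(a, b, eps = .geom_eps) {
  if (!.bbox_overlap(.poly_bbox(a), .poly_bbox(b), eps)) return(FALSE)
  ea <- .poly_edges(a); eb <- .poly_edges(b)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (.seg_proper_cross(ea$from[i, ], ea$to[i, ], eb$from[j, ], eb$to[j, ], eps)) {
        return(TRUE)
      }
    }
  }
  for (i in seq_len(nrow(a))) {
    if (.point_strictly_in_poly(a[i, 1L], a[i, 2L], b, eps)) return(TRUE)
  }
  for (i in seq_len(nrow(b))) {
    if (.point_strictly_in_poly(b[i, 1L], b[i, 2L], a, eps)) return(TRUE)
  }
  # edge midpoints catch identical / nested-without-free-vertices layouts
  mida <- (ea$from + ea$to) / 2
  for (i in seq_len(nrow(mida))) {
    if (.point_strictly_in_poly(mida[i, 1L], mida[i, 2L], b, eps)) return(TRUE)
  }
  ca <- .poly_centroid(a)
  .point_strictly_in_poly(ca[1L], ca[2L], b, eps)
}

# Full containment of `inner` in the closed set `outer`.
.poly_contains <- function(outer, inner, eps = .geom_eps) {
  bo <- .poly_bbox(outer); bi <- .poly_bbox(inner)
  if (bi[1L] < bo[1L] - eps || bi[2L] < bo[2L] - eps ||
      bi[3L] > bo[3L] + eps || bi[4L] > bo[4L] + eps) {
    return(FALSE)
  }
  for (i in seq_len(nrow(inner))) {
    if (!.point_in_poly(inner[i, 1L], inner[i, 2L], outer, eps)) return(FALSE)
  }
  ei <- .poly_edges(inner)
  mid <- (ei$from + ei$to) / 2
  for (i in seq_len(nrow(mid))) {
    if (!.point_in_poly(mid[i, 1L], mid[i, 2L], outer, eps)) return(FALSE)
  }
  eo <- .poly_edges(outer)
  for (i in seq_len(nrow(inner))) {
    for (j in seq_len(nrow(outer))) {
      if (.seg_proper_cross(ei$from[i, ], ei$to[i, ], eo$from[j, ], eo$to[j, ], eps)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

.poly_area <- function(p) {
  n <- nrow(p)
  i <- seq_len(n)
  j <- c(2:n, 1L)
  abs(sum(p[i, 1L] * p[j, 2L] - p[j, 1L] * p[i, 2L])) / 2
}

.poly_centroid <- function(p) {
  n <- nrow(p)
  i <- seq_len(n)
  j <- c(2:n, 1L)
  cr <- p[i, 1L] * p[j, 2L] - p[j, 1L] * p[i, 2L]
  a <- sum(cr) / 2
  if (abs(a) < .geom_eps) return(colMeans(p))
  cx <- sum((p[i, 1L] + p[j, 1L]) * cr) / (6 * a)
  cy <- sum((p[i, 2L] + p[j, 2L]) * cr) / (6 * a)
  c(cx, cy)
}

.poly_self_intersects <- function(p, eps = .geom_eps) {
  n <- nrow(p)
  e <- .poly_edges(p)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (.seg_intersect(e$from[i, ], e$to[i, ], e$from[j, ], e$to[j, ], eps)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

.poly_is_valid <- function(p) {
  is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L && all(is.finite(p)) &&
    .poly_area(p) > .geom_eps && !.poly_self_intersects(p)
}

# Axis-aligned rectangle detection enables exact closed-interval fast
# paths for grid cities.
.poly_is_rect <- function(p, eps = .geom_eps) {
  if (nrow(p) != 4L) return(FALSE)
  b <- .poly_bbox(p)
  xs <- p[, 1L]; ys <- p[, 2L]
  all(abs(xs - b[1L]) < eps | abs(xs - b[3L]) < eps) &&
    all(abs(ys - b[2L]) < eps | abs(ys - b[4L]) < eps) &&
    b[3L] - b[1L] > eps && b[4L] - b[2L] > eps
}
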