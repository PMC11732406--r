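#' Euclidean distance to the central business district
#'
#' Planar centroid-to-point distance in km.
#'
#' @param origins an origin [partition_set()] or an n x 2 coordinate
#'   matrix.
#' @param cbd numeric length-2 point (km).
#' @return Named numeric vector of distances.
#' @export
distance_to_cbd <- function(origins, cbd) {
  xy <- if (inherits(origins, "partition_set")) origins$centroids else as.matrix(origins)
  d <- sqrt((xy[, 1L] - cbd[1L])^2 + (xy[, 2L] - cbd[2L])^2)
  if (!is.null(rownames(xy))) names(d) <- rownames(xy)
  d
}

#' k-nearest-neighbour spatial weights
#'
#' Builds the k-nearest-neighbour graph on region centroids, symmetrises
#' it by union (i and j are neighbours if either is among the other's k
#' nearest) and row-standardises, giving the W of the spatial lag and
#' error models.  Distance ties are broken deterministically by region id
#' order; exact duplicate centroids are resolved the same way with a
#' warning.  Row sums are exactly 1; the diagonal is zero.
#'
#' @param origins an origin [partition_set()] or an n x 2 coordinate
#'   matrix with rownames as ids.
#' @param k number of nearest neighbours (>= 1, < n).
#' @param eigenvalues precompute the real spectrum of W (similar to a
#'   symmetric matrix, so all eigenvalues are real); needed by the
#'   lag/error fits, which otherwise compute it lazily per fit.
#' @return Object of class `spatial_weights`: `ids`, `W` (sparse,
#'   row-standardised), `k`, `scheme`, and optionally `eigenvalues`.
#' @export
build_weights <- function(origins, k = 8L, eigenvalues = FALSE) {
  xy <- if (inherits(origins, "partition_set")) origins$centroids else as.matrix(origins)
  n <- nrow(xy)
  ids <- rownames(xy) %||% as.character(seq_len(n))
  k <- as.integer(k)
  if (k < 1L || k >= n) {
    stop("input error: need 1 <= k < number of regions", call. = FALSE)
  }
  if (n > 10000L) {
    stop("capability error: dense spectrum computation limited to n <= 10000",
         call. = FALSE)
  }
  if (anyDuplicated(xy) > 0L) {
    warning("duplicate centroids; k-NN ties resolved by region id order")
  }
  d2 <- outer(xy[, 1L], xy[, 1L], "-")^2 + outer(xy[, 2L], xy[, 2L], "-")^2
  diag(d2) <- Inf
  ii <- integer(n * k)
  jj <- integer(n * k)
  for (i in seq_len(n)) {
    # order by distance then id rank: deterministic tie-breaking
    nb <- order(d2[i, ], seq_len(n))[seq_len(k)]
    ii[((i - 1L) * k + 1L):(i * k)] <- i
    jj[((i - 1L) * k + 1L):(i * k)] <- nb
  }
  A <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- (A + t(A) > 0) * 1  # symmetrise by union
  deg <- rowSums(A)
  if (any(deg == 0)) {
    stop("input error: isolated regions in the weights graph", call. = FALSE)
  }
  W <- Diagonal(x = 1 / deg) %*% A
  dimnames(W) <- list(ids, ids)
  out <- structure(
    list(ids = ids, W = as(W, "generalMatrix"), degree = deg, k = k,
         scheme = "knn-union-row-standardised", eigenvalues = NULL),
    class = "spatial_weights"
  )
  if (eigenvalues) out$eigenvalues <- weights_spectrum(out)
  out
}

#' Real spectrum of a row-standardised symmetric-similar weights matrix
#'
#' W = D^-1 A with A symmetric is similar to the symmetric
#' D^-1/2 A D^-1/2, so its eigenvalues are real; they are computed from
#' the symmetric form.  The largest is 1; the admissible interval for the
#' spatial autoregressive parameter is (1 / min(eigenvalues), 1).
#'
#' @param w a `spatial_weights`.
#' @return Numeric vector of eigenvalues, decreasing.
#' @export
weights_spectrum <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(w$eigenvalues)) return(w$eigenvalues)
  A <- w$W * w$degree          # recover the symmetric adjacency
  dhalf <- 1 / sqrt(w$degree)
  Ws <- Diagonal(x = dhalf) %*% A %*% Diagonal(x = dhalf)
  eigen(as.matrix(Ws), symmetric = TRUE, only.values = TRUE)$values
}

#' @exportS3Method base::print
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights>", length(x$ids), "regions | scheme:", x$scheme,
      "| k =", x$k, "\n")
  invisible(x)
}

#' Standardize regression predictors
#'
#' Centres each predictor and scales it to unit variance within the
#' analysis set, recording means and s.d.s so coefficients can be mapped
#' back to the raw scale.  Effects are then comparable per-s.d. across
#' predictors.
#'
#' @param X numeric matrix or data frame of predictors.
#' @return Numeric matrix with attributes `center` and `scale`.
#' @export
standardize_predictors <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("input error: non-finite predictor", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (any(scl == 0)) {
    stop("input error: zero-variance predictor: ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- scl
  Z
}
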