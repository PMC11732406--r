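#' Mann-Kendall score
#'
#' `S = sum over pairs j > i of sign(x[j] - x[i])`; tied pairs contribute
#' 0.  For 10 distinct values S ranges over odd integers in (-45, 45),
#' with -45 a strictly decreasing and +45 a strictly increasing sequence.
#' The score depends only on the ordering, so it is invariant under any
#' strictly increasing transform of the values.
#'
#' @param x ordered numeric sequence, `n >= 2`.
#' @return Integer score S.
#' @export
mk_score <- function(x) {
  n <- length(x)
  if (n < 2L) stop("input error: need at least 2 values", call. = FALSE)
  d <- outer(x, x, "-")
  as.integer(sum(sign(d[lower.tri(d)])))
}

#' Mann-Kendall null variance
#'
#' Variance of S under the null of a random ordering, with the standard
#' tie correction:
#' `var_S = (n (n-1) (2n+5) - sum_t t (t-1) (2t+5)) / 18`
#' over tie groups of size t.
#'
#' @param n sequence length.
#' @param ties integer vector of tie-group sizes (groups of size 1 may be
#'   omitted).
#' @return `var_S`.
#' @export
mk_variance <- function(n, ties = integer(0)) {
  if (n < 2L) stop("input error: need n >= 2", call. = FALSE)
  ties <- as.integer(ties)
  if (length(ties) && (any(ties > n) || sum(ties) > n)) {
    stop("input error: tie group sizes exceed n", call. = FALSE)
  }
  (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
}

# Null distribution of S for a tie-free sequence of length n, by the
# classical recurrence on discordance (inversion) counts: the number of
# orderings with q inversions has generating function
# prod_{i=1..n} (1 + x + ... + x^{i-1}).  S = n(n-1)/2 - 2q.
#' Exact null distribution of the Mann-Kendall score
#'
#' Counts of orderings attaining each achievable S for a tie-free
#' sequence of length `n`, computed by the inversion-count recurrence
#' (equivalent to full permutation enumeration, feasible well beyond it).
#'
#' @param n sequence length, `2 <= n <= 12`.
#' @return Data frame: `S`, `count`, `prob` (counts sum to `n!`).
#' @export
mk_null_distribution <- function(n) {
  if (n < 2L) stop("input error: need n >= 2", call. = FALSE)
  if (n > 12L) {
    stop("capability error: exact null distribution supported for n <= 12",
         call. = FALSE)
  }
  counts <- 1  # inversion counts for n = 1: one ordering, 0 inversions
  for (i in 2:n) {
    # convolve with the uniform kernel of length i
    new <- numeric(length(counts) + i - 1L)
    for (shift in 0:(i - 1L)) {
      idx <- seq_along(counts) + shift
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  q <- seq_along(counts) - 1L
  M <- n * (n - 1L) / 2L
  data.frame(S = M - 2L * q, count = counts, prob = counts / factorial(n))
}

#' Two-sided Mann-Kendall p-value
#'
#' `normal_approx`: the continuity-corrected normal approximation
#' `z = (|S| - 1) / sqrt(var_S)` (z = 0 when S = 0),
#' `p = min(1, 2 (1 - Phi(z)))`.  `exact`: `P(|S_null| >= |S|)` from the
#' exact tie-free null distribution ([mk_null_distribution()], n <= 12).
#'
#' @param S Mann-Kendall score.
#' @param n sequence length.
#' @param ties tie-group sizes (see [mk_variance()]); the exact method
#'   requires a tie-free sequence.
#' @param method `"normal_approx"` or `"exact"`.
#' @return Two-sided p-value in (0, 1].
#' @export
mk_pvalue <- function(S, n, ties = integer(0),
                      method = c("normal_approx", "exact")) {
  method <- match.arg(method)
  M <- n * (n - 1) / 2
  if (abs(S) > M) {
    stop("input error: |S| exceeds n(n-1)/2", call. = FALSE)
  }
  tied <- length(ties) && any(ties > 1L)
  if (!tied && (S - M) %% 2 != 0) {
    stop("input error: S has impossible parity for a tie-free sequence",
         call. = FALSE)
  }
  if (method == "normal_approx") {
    v <- mk_variance(n, ties)
    if (v <= 0) return(1)
    z <- if (S == 0) 0 else (abs(S) - 1) / sqrt(v)
    return(min(1, 2 * (1 - pnorm(z))))
  }
  if (tied) {
    stop("capability error: exact method requires a tie-free sequence",
         call. = FALSE)
  }
  null <- mk_null_distribution(n)
  sum(null$prob[abs(null$S) >= abs(S)])
}

#' Mann-Kendall monotonic-trend test
#'
#' Composes score, tie-corrected variance (ties detected from the
#' sequence) and two-sided p-value for a short ordered sequence —
#' typically the 10 decile medians of the mobility-change statistic.
#'
#' @param x ordered numeric sequence.
#' @param method `"normal_approx"` (default; reproduces the reported
#'   decile-trend p-values) or `"exact"`.
#' @return Object of class `mk_trend`: `n`, `S`, `var_S`, `z`,
#'   `p_two_sided`, `method`.
#' @export
mk_test <- function(x, method = c("normal_approx", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2L) stop("input error: need at least 2 values", call. = FALSE)
  if (method == "normal_approx" && n < 4L) {
    stop("input error: normal approximation needs n >= 4", call. = FALSE)
  }
  if (method == "normal_approx" && n < 8L) {
    warning("normal approximation is crude below n = 8; consider method = 'exact'")
  }
  tie_sizes <- as.integer(table(x))
  tie_sizes <- tie_sizes[tie_sizes > 1L]
  S <- mk_score(x)
  v <- mk_variance(n, tie_sizes)
  z <- if (S == 0 || v <= 0) 0 else (abs(S) - 1) / sqrt(v) * sign(S)
  p <- mk_pvalue(S, n, tie_sizes, method)
  structure(
    list(n = n, S = S, var_S = v, z = z, p_two_sided = p, method = method),
    class = "mk_trend"
  )
}

#' @exportS3Method base::print
print.mk_trend <- function(x, ...) {
  cat(sprintf("Mann-Kendall trend test (%s)\n", x$method))
  cat(sprintf("  n = %d, S = %d, var_S = %.3f, z = %.3f, p = %.3g\n",
              x$n, x$S, x$var_S, x$z, x$p_two_sided))
  invisible(x)
}
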