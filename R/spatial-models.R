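# The regression suite: non-spatial OLS, OLS with distance to the city
# centre, spatial lag and spatial error models, all by maximum
# likelihood, with AIC on a common footing (k counts intercept, slopes,
# the residual variance, and the spatial parameter where present).
#
# Lag model:   y = rho W y + X beta + eps,      eps ~ N(0, sigma2 I)
# Error model: y = X beta + u, u = lambda W u + eps
#
# Both are fitted by concentrating the log-likelihood on the spatial
# parameter; log|I - a W| = sum(log(1 - a * ev)) from the real spectrum
# of W.  The admissible interval is (1 / min(ev), 1).

.loglik_gaussian <- function(rss, n) {
  -n / 2 * (log(2 * pi) + 1 + log(rss / n))
}

.model_result <- function(model, coefficients, se, n, loglik, k,
                          rho_lag = NULL, lambda_err = NULL) {
  z <- coefficients / se
  structure(
    list(
      model = model,
      coefficients = coefficients,
      se = se,
      p_values = 2 * pnorm(-abs(z)),
      rho_lag = rho_lag,
      lambda_err = lambda_err,
      log_likelihood = loglik,
      k = k,
      aic = 2 * k - 2 * loglik,
      n = n
    ),
    class = "mob_model"
  )
}

#' @exportS3Method base::print
print.mob_model <- function(x, ...) {
  cat(sprintf("<mob_model> %s | n = %d | logLik = %.2f | AIC = %.2f\n",
              x$model, x$n, x$log_likelihood, x$aic))
  tab <- data.frame(coefficient = x$coefficients, se = x$se, p = x$p_values)
  print(round(tab, 4))
  if (!is.null(x$rho_lag)) cat(sprintf("  rho_lag    = %.4f\n", x$rho_lag))
  if (!is.null(x$lambda_err)) cat(sprintf("  lambda_err = %.4f\n", x$lambda_err))
  invisible(x)
}

.design <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Ordinary least squares fit
#'
#' Maximum-likelihood linear regression of the mobility-change statistic
#' on (standardized) predictors, via [stats::lm()].  The intercept is
#' added internally.  AIC counts the residual variance as a free
#' parameter so it is comparable with the spatial fits.
#'
#' @param y response vector (lambda_mob per origin).
#' @param X predictor matrix (no intercept column).
#' @param model label recorded in the result (`"ols"` or `"ols_cbd"`).
#' @return A `mob_model` (see [fit_spatial_lag()] for fields).
#' @export
fit_ols <- function(y, X, model = "ols") {
  X <- .design(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop("input error: need n > p", call. = FALSE)
  fit <- lm(y ~ X)
  if (anyNA(coef(fit))) stop("input error: rank-deficient design", call. = FALSE)
  cf <- coef(fit)
  names(cf) <- c("(Intercept)", colnames(X))
  rss <- sum(fit$residuals^2)
  # classical (finite-sample) standard errors
  se <- sqrt(diag(vcov(fit)))
  names(se) <- names(cf)
  .model_result(model, cf, se, n,
                loglik = .loglik_gaussian(rss, n),
                k = p + 2L)
}

.check_weights <- function(w, n) {
  stopifnot(inherits(w, "spatial_weights"))
  if (length(w$ids) != n) {
    stop("input error: weights and data cover different unit sets",
         call. = FALSE)
  }
}

#' Spatial lag model by maximum likelihood
#'
#' Fits `y = rho W y + X beta + eps` with iid Gaussian errors.  The
#' log-likelihood is concentrated in `rho`; `log|I - rho W|` comes from
#' the real spectrum of the row-standardised W, and `rho` is searched on
#' the admissible interval `(1 / min(eigenvalues), 1)`.  At `rho = 0` the
#' concentrated likelihood equals the OLS likelihood exactly.  Standard
#' errors are asymptotic, from the analytical information matrix of
#' (beta, rho, sigma2).
#'
#' @param y response vector, ordered as `w$ids`.
#' @param X predictor matrix (no intercept).
#' @param w [build_weights()] object over the same units.
#' @param se compute asymptotic standard errors (involves a dense solve;
#'   skip in large simulation loops).
#' @return A `mob_model`: `coefficients`, `se`, `p_values`, `rho_lag`,
#'   `log_likelihood`, `aic`, `n`.
#' @export
fit_spatial_lag <- function(y, X, w, se = TRUE) {
  X <- .design(X)
  n <- length(y)
  .check_weights(w, n)
  Xi <- cbind("(Intercept)" = 1, X)
  W <- w$W
  ev <- weights_spectrum(w)
  Wy <- as.numeric(W %*% y)
  q0 <- qr(Xi)
  if (q0$rank < ncol(Xi)) stop("input error: rank-deficient design", call. = FALSE)
  e0 <- qr.resid(q0, y)
  ed <- qr.resid(q0, Wy)
  lo <- 1 / min(ev) + 1e-8
  hi <- 1 - 1e-8
  cll <- function(rho) {
    e <- e0 - rho * ed
    sum(log(1 - rho * ev)) - n / 2 * log(sum(e * e) / n)
  }
  opt <- optimize(cll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  rho <- opt$maximum
  b0 <- qr.coef(q0, y)
  bd <- qr.coef(q0, Wy)
  beta <- b0 - rho * bd
  names(beta) <- colnames(Xi)
  e <- e0 - rho * ed
  sigma2 <- sum(e * e) / n
  loglik <- -n / 2 * (log(2 * pi) + 1) + opt$objective
  p <- ncol(X)
  k <- p + 3L  # intercept + slopes + rho + sigma2

  se_vec <- rep(NA_real_, length(beta))
  if (se) {
    # information matrix of (beta, rho, sigma2); C = W (I - rho W)^{-1}
    Ainv_xb <- solve(Diagonal(n) - rho * W, as.numeric(Xi %*% beta))
    Cxb <- as.numeric(W %*% Ainv_xb)
    Adense <- diag(n) - rho * as.matrix(W)
    C <- as.matrix(W) %*% solve(Adense)
    trC <- sum(diag(C))
    trC2 <- sum(C * t(C))        # tr(C %*% C)
    trCtC <- sum(C * C)          # tr(t(C) %*% C)
    pI <- ncol(Xi)
    info <- matrix(0, pI + 2L, pI + 2L)
    info[1:pI, 1:pI] <- crossprod(Xi) / sigma2
    info[1:pI, pI + 1L] <- crossprod(Xi, Cxb) / sigma2
    info[pI + 1L, 1:pI] <- info[1:pI, pI + 1L]
    info[pI + 1L, pI + 1L] <- trC2 + trCtC + sum(Cxb^2) / sigma2
    info[pI + 1L, pI + 2L] <- trC / sigma2
    info[pI + 2L, pI + 1L] <- trC / sigma2
    info[pI + 2L, pI + 2L] <- n / (2 * sigma2^2)
    V <- solve(info)
    se_vec <- sqrt(diag(V)[1:pI])
    attr(rho, "se") <- sqrt(V[pI + 1L, pI + 1L])
  }
  names(se_vec) <- names(beta)
  res <- .model_result("lag", beta, se_vec, n, loglik, k,
                       rho_lag = as.numeric(rho))
  if (se) res$rho_se <- attr(rho, "se")
  res
}

#' Spatial error model by maximum likelihood
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`.  For fixed `lambda` the
#' profile is a GLS fit in the spatially filtered variables
#' `(I - lambda W) y` and `(I - lambda W) X`; the log-determinant term
#' again uses the spectrum of W.  At `lambda = 0` the likelihood equals
#' the OLS likelihood exactly.
#'
#' @inheritParams fit_spatial_lag
#' @return A `mob_model` with `lambda_err` in place of `rho_lag`.
#' @export
fit_spatial_error <- function(y, X, w, se = TRUE) {
  X <- .design(X)
  n <- length(y)
  .check_weights(w, n)
  Xi <- cbind("(Intercept)" = 1, X)
  W <- w$W
  ev <- weights_spectrum(w)
  Wy <- as.numeric(W %*% y)
  WX <- as.matrix(W %*% Xi)
  lo <- 1 / min(ev) + 1e-8
  hi <- 1 - 1e-8
  profile <- function(lam) {
    ys <- y - lam * Wy
    Xs <- Xi - lam * WX
    qs <- qr(Xs)
    es <- qr.resid(qs, ys)
    list(rss = sum(es * es), qs = qs, ys = ys)
  }
  cll <- function(lam) {
    sum(log(1 - lam * ev)) - n / 2 * log(profile(lam)$rss / n)
  }
  opt <- optimize(cll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  lam <- opt$maximum
  pr <- profile(lam)
  beta <- qr.coef(pr$qs, pr$ys)
  names(beta) <- colnames(Xi)
  sigma2 <- pr$rss / n
  loglik <- -n / 2 * (log(2 * pi) + 1) + opt$objective
  p <- ncol(X)
  k <- p + 3L

  se_vec <- rep(NA_real_, length(beta))
  lam_se <- NA_real_
  if (se) {
    Xs <- Xi - lam * WX
    se_vec <- sqrt(diag(solve(crossprod(Xs))) * sigma2)
    Adense <- diag(n) - lam * as.matrix(W)
    C <- as.matrix(W) %*% solve(Adense)
    trC <- sum(diag(C))
    trC2 <- sum(C * t(C))
    trCtC <- sum(C * C)
    i22 <- matrix(c(trC2 + trCtC, trC / sigma2,
                    trC / sigma2, n / (2 * sigma2^2)), 2L, 2L)
    lam_se <- sqrt(solve(i22)[1L, 1L])
  }
  names(se_vec) <- names(beta)
  res <- .model_result("error", beta, se_vec, n, loglik, k,
                       lambda_err = as.numeric(lam))
  if (se) res$lambda_se <- lam_se
  res
}

#' Compare fitted models by AIC
#'
#' @param results list of `mob_model`s fitted on the identical response
#'   and unit set.
#' @return Data frame: `model`, `log_likelihood`, `k`, `aic`,
#'   `delta_aic` (vs the best).
#' @export
model_comparison <- function(results) {
  ns <- vapply(results, function(r) r$n, numeric(1L))
  if (length(unique(ns)) != 1L) {
    stop("input error: models fitted on different unit sets", call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(results, function(r) r$model, character(1L)),
    log_likelihood = vapply(results, function(r) r$log_likelihood, numeric(1L)),
    k = vapply(results, function(r) r$k, numeric(1L)),
    aic = vapply(results, function(r) r$aic, numeric(1L)),
    stringsAsFactors = FALSE
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab[order(tab$aic), ]
}
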