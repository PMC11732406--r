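# Spatial weights, predictor standardisation and the regression suite.

grid_coords <- function(g) {
  xy <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g)))
  rownames(xy) <- sprintf("r%03d", seq_len(g * g))
  xy
}

test_that("weights are row-standardised with union symmetrisation", {
  xy <- cbind(c(0, 1, 2), c(0, 0, 0))
  rownames(xy) <- c("a", "b", "c")
  w <- build_weights(xy, k = 1)
  W <- as.matrix(w$W)
  # middle point keeps both neighbours after union symmetrisation
  expect_equal(W["b", c("a", "c")], c(a = 0.5, c = 0.5))
  expect_equal(unname(rowSums(W)), rep(1, 3))
  expect_equal(unname(diag(W)), rep(0, 3))

  xy2 <- grid_coords(7L)
  w2 <- build_weights(xy2, k = 4)
  expect_equal(unname(rowSums(as.matrix(w2$W))), rep(1, 49))
  # interior cell of a grid with k=4: exactly the four rook neighbours
  i <- which(xy2[, 1] == 4 & xy2[, 2] == 4)
  nb <- which(as.matrix(w2$W)[i, ] > 0)
  rook <- which((abs(xy2[, 1] - 4) + abs(xy2[, 2] - 4)) == 1)
  expect_setequal(unname(nb), unname(rook))
})

test_that("the weights spectrum is real with largest eigenvalue 1", {
  w <- build_weights(grid_coords(6L), k = 8, eigenvalues = TRUE)
  ev <- w$eigenvalues
  expect_equal(max(ev), 1, tolerance = 1e-10)
  expect_true(min(ev) > -1.000001 && min(ev) < 0)
  # spectrum equals the dense nonsymmetric eigenvalues
  ev2 <- sort(Re(eigen(as.matrix(w$W))$values))
  expect_equal(sort(ev), ev2, tolerance = 1e-8)
})

test_that("standardisation is exact, invertible and idempotent", {
  set.seed(2)
  X <- cbind(a = rnorm(50, 10, 3), b = runif(50))
  Z <- standardize_predictors(X)
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize_predictors(Z)[, ], Z[, ], tolerance = 1e-12)
  back <- sweep(sweep(Z, 2, attr(Z, "scale"), "*"), 2, attr(Z, "center"), "+")
  expect_equal(back[, ], X[, ], tolerance = 1e-12)
  expect_error(standardize_predictors(cbind(a = rep(1, 10))), "zero-variance")
})

test_that("distance to the CBD is plain Euclidean distance", {
  xy <- rbind(c(0, 0), c(3, 4))
  rownames(xy) <- c("p", "q")
  d <- distance_to_cbd(xy, c(0, 0))
  expect_equal(unname(d), c(0, 5))
  cfg <- city_config(grid_n = 6L, dzn_block = 2L, straddle_frac = 0)
  p <- generate_partitions(cfg)
  cbd <- c(1.3, 2.2)
  got <- distance_to_cbd(p$origins, cbd)
  want <- apply(p$origins$centroids, 1,
                function(r) sqrt(sum((r - cbd)^2)))
  expect_equal(got, want)
})

test_that("OLS equals the normal-equations solution and stats::lm", {
  set.seed(6)
  n <- 120
  X <- cbind(ER = rnorm(n), EO = rnorm(n))
  y <- 0.5 + 2 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.1)
  f <- fit_ols(y, X)
  Xi <- cbind(1, X)
  beta_ne <- solve(t(Xi) %*% Xi, t(Xi) %*% y)  # brute-force normal equations
  expect_equal(unname(f$coefficients), as.numeric(beta_ne), tolerance = 1e-10)
  lmfit <- lm(y ~ X)
  expect_equal(f$log_likelihood, as.numeric(logLik(lmfit)))
  expect_equal(f$aic, AIC(lmfit))
  # near-noiseless fit recovers the slope to machine-level accuracy
  f2 <- fit_ols(2 * X[, 1] + rnorm(n, 0, 1e-8), X[, 1, drop = FALSE])
  expect_equal(unname(f2$coefficients[2]), 2, tolerance = 1e-6)
  expect_error(fit_ols(y, cbind(X, X[, 1])), "rank-deficient")
})

test_that("lag and error likelihoods reduce exactly to OLS at zero", {
  set.seed(7)
  n <- 100
  xy <- grid_coords(10L)
  w <- build_weights(xy, k = 6, eigenvalues = TRUE)
  X <- cbind(ER = rnorm(n), EO = rnorm(n))
  y <- 0.2 - 0.1 * X[, 2] + rnorm(n, 0, 0.3)
  ols <- fit_ols(y, X)
  ev <- w$eigenvalues
  # concentrated log-likelihood of both spatial models evaluated at 0
  Xi <- cbind(1, X)
  rss <- sum(qr.resid(qr(Xi), y)^2)
  cll0 <- -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n)
  expect_equal(cll0, ols$log_likelihood, tolerance = 1e-10)
  # the ML optimum can only be at least as good
  lag <- fit_spatial_lag(y, X, w)
  err <- fit_spatial_error(y, X, w)
  expect_gte(lag$log_likelihood, ols$log_likelihood - 1e-8)
  expect_gte(err$log_likelihood, ols$log_likelihood - 1e-8)
  expect_lt(abs(lag$rho_lag), 1)
  expect_lt(abs(err$lambda_err), 1)
})

test_that("spatial parameters and coefficients are recovered from simulation", {
  set.seed(11)
  g <- 18L
  n <- g * g
  xy <- grid_coords(g)
  w <- build_weights(xy, k = 8, eigenvalues = TRUE)
  X <- cbind(ER = rnorm(n), EO = rnorm(n))
  beta <- c(0.05, -0.1)
  reps <- 5
  rho_hat <- beta_eo_lag <- lam_hat <- beta_eo_err <- numeric(reps)
  for (r in seq_len(reps)) {
    eps <- rnorm(n, 0, 0.2)
    y <- as.numeric(solve(Diagonal(n) - 0.5 * w$W, X %*% beta + 0.1 + eps))
    f <- fit_spatial_lag(y, X, w, se = FALSE)
    rho_hat[r] <- f$rho_lag
    beta_eo_lag[r] <- f$coefficients[["EO"]]
    u <- as.numeric(solve(Diagonal(n) - 0.5 * w$W, eps))
    y2 <- as.numeric(0.1 + X %*% beta + u)
    g2 <- fit_spatial_error(y2, X, w, se = FALSE)
    lam_hat[r] <- g2$lambda_err
    beta_eo_err[r] <- g2$coefficients[["EO"]]
  }
  expect_equal(mean(rho_hat), 0.5, tolerance = 0.1)
  expect_equal(mean(lam_hat), 0.5, tolerance = 0.15)
  expect_equal(mean(beta_eo_lag), -0.1, tolerance = 0.02)
  expect_equal(mean(beta_eo_err), -0.1, tolerance = 0.02)
})

test_that("model comparison ranks by AIC over a common unit set", {
  set.seed(12)
  n <- 100
  xy <- grid_coords(10L)
  w <- build_weights(xy, k = 6, eigenvalues = TRUE)
  X <- cbind(ER = rnorm(n), EO = rnorm(n))
  y <- 0.2 - 0.1 * X[, 2] + rnorm(n, 0, 0.3)
  f1 <- fit_ols(y, X)
  cmp0 <- model_comparison(list(f1, f1))
  expect_equal(cmp0$delta_aic, c(0, 0))
  fits <- list(f1, fit_spatial_lag(y, X, w), fit_spatial_error(y, X, w))
  cmp <- model_comparison(fits)
  expect_equal(cmp$delta_aic[1], 0)
  expect_true(all(diff(cmp$aic) >= 0))
  # no spatial signal: the spatial terms cannot beat OLS by much
  expect_lt(max(cmp$aic) - min(cmp$aic), 4.1)
  short <- fit_ols(y[1:50], X[1:50, ])
  expect_error(model_comparison(list(f1, short)), "different unit sets")
})
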