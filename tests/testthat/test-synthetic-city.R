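# The synthetic-city generator: geometry counts, score correlations,
# ground-truth construction, visit properties, determinism.

test_that("grid partition counts and containment follow the configuration", {
  cfg <- city_config(grid_n = 4L, dzn_block = 2L, straddle_frac = 0)
  p <- generate_partitions(cfg)
  expect_equal(n_regions(p$origins), 16L)
  expect_equal(n_regions(p$destinations), 4L)
  cc <- coverage_container(p$origins, p$destinations)
  expect_false(anyNA(cc))  # straddle fraction 0: everyone contained

  expect_error(city_config(grid_n = 6L, dzn_block = 4L), "divisible")
  expect_error(city_config(grid_n = 3L), "grid_n")
})

test_that("the requested fraction of origins straddles a destination boundary", {
  cfg <- city_config(grid_n = 6L, dzn_block = 2L, straddle_frac = 1 / 6)
  p <- generate_partitions(cfg)
  expect_equal(sum(p$origins$regions$straddling), 6L)
  # straddlers (and only straddlers) have no containing destination
  cc <- coverage_container(p$origins, p$destinations)
  expect_equal(is.na(cc), setNames(p$origins$regions$straddling, p$origins$ids))
  # the deformation keeps origins pairwise disjoint and tiling
  expect_silent(mobishift:::.check_disjoint_interiors(p$origins))
  areas <- vapply(p$origins$geoms, mobishift:::.poly_area, numeric(1))
  expect_equal(sum(areas), 36)
})

test_that("SES scores have the configured correlation structure", {
  cfg <- city_config(grid_n = 100L, dzn_block = 2L, rho_er_eo = 0.9,
                     gamma_eo_dist = 0, straddle_frac = 0)
  p <- generate_partitions(cfg)
  s <- generate_ses_scores(p$origins, cfg, seed = 5)
  r <- cor(s$er_score, s$eo_score)
  expect_gt(r, 0.85)
  expect_lt(r, 0.95)
  expect_equal(mean(s$er_score), 1000, tolerance = 0.01)

  cfg2 <- city_config(grid_n = 100L, dzn_block = 2L, rho_er_eo = 0,
                      gamma_eo_dist = -0.5, straddle_frac = 0)
  s2 <- generate_ses_scores(p$origins, cfg2, seed = 5)
  ctr <- mobishift:::.city_centre(cfg2)
  d <- sqrt((p$origins$centroids[, 1] - ctr[1])^2 +
            (p$origins$centroids[, 2] - ctr[2])^2)
  expect_lt(cor(s2$eo_score, d), -0.3)

  cfg3 <- city_config(grid_n = 100L, dzn_block = 2L, rho_er_eo = 0,
                      gamma_eo_dist = 0, straddle_frac = 0)
  s3 <- generate_ses_scores(p$origins, cfg3, seed = 5)
  expect_lt(abs(cor(s3$er_score, s3$eo_score)), 0.05)
})

test_that("ground truth is the stated linear field in standardized covariates", {
  cfg <- city_config(grid_n = 10L, dzn_block = 2L, beta_eo = 0, beta_er = 0,
                     beta_dist = 0, sigma_noise = 0, straddle_frac = 0)
  p <- generate_partitions(cfg)
  s <- generate_ses_scores(p$origins, cfg)
  tr <- make_ground_truth(s, p$origins, cfg)
  expect_true(all(tr$lambda_true == 0))

  cfg2 <- city_config(grid_n = 10L, dzn_block = 2L, beta_eo = -0.1,
                      beta_er = 0, beta_dist = 0, sigma_noise = 0,
                      straddle_frac = 0)
  tr2 <- make_ground_truth(s, p$origins, cfg2)
  expect_equal(cor(tr2$lambda_true, s$eo_score), -1)

  # with noise, OLS on the generated field recovers beta_eo
  cfg3 <- city_config(grid_n = 50L, dzn_block = 2L, beta_eo = -0.1,
                      beta_er = 0, beta_dist = 0, sigma_noise = 0.05,
                      rho_er_eo = 0, gamma_eo_dist = 0, straddle_frac = 0)
  p3 <- generate_partitions(cfg3)
  s3 <- generate_ses_scores(p3$origins, cfg3)
  tr3 <- make_ground_truth(s3, p3$origins, cfg3)
  b <- coef(lm(tr3$lambda_true ~ tr3$z_eo + tr3$z_er + tr3$z_dist))
  expect_equal(unname(b[2]), -0.1, tolerance = 0.01)
  expect_equal(unname(b[3]), 0, tolerance = 0.01)
})

test_that("visit generation truncates at the radius and respects ground truth", {
  cfg <- city_config(grid_n = 20L, dzn_block = 2L, max_radius_km = 5,
                     sigma_noise = 0, beta_eo = 0, beta_er = 0,
                     beta_dist = 0, straddle_frac = 0, trip_rate = 5)
  p <- generate_partitions(cfg)
  s <- generate_ses_scores(p$origins, cfg)
  tr <- make_ground_truth(s, p$origins, cfg)
  vc <- generate_visits(p$origins, p$destinations, tr,
                        period_spec("baseline"), cfg, seed = 1)
  d <- sqrt((p$origins$centroids[vc$visits$origin_id, 1] -
             p$destinations$centroids[vc$visits$destination_id, 1])^2 +
            (p$origins$centroids[vc$visits$origin_id, 2] -
             p$destinations$centroids[vc$visits$destination_id, 2])^2)
  expect_true(all(d <= 5))

  # expected totals scale linearly with population: trip_rate * pop
  tot <- tapply(vc$visits$mean_daily_visits, vc$visits$origin_id, sum)
  pop <- setNames(p$origins$regions$population, p$origins$ids)[names(tot)]
  expect_equal(as.numeric(tot / pop), rep(5, length(tot)), tolerance = 0.1)
})

test_that("with a constant true effect the flow ratio concentrates on it", {
  cfg <- city_config(grid_n = 10L, dzn_block = 2L, sigma_noise = 0,
                     beta_eo = 0, beta_er = 0, beta_dist = 0,
                     straddle_frac = 0, trip_rate = 50,
                     panel_rate_base = 500, panel_rate_test = 500,
                     periods = list(period_spec("baseline", 60L),
                                    period_spec("test", 60L)))
  city <- simulate_city(cfg, seed = 2)
  # lambda_true == 0 and equal rates: per-origin total ratio near 1
  bt <- city$visits[city$visits$period == "baseline", ]
  tt <- city$visits[city$visits$period == "test", ]
  rb <- tapply(bt$mean_daily_visits, bt$origin_id, sum)
  rt <- tapply(tt$mean_daily_visits, tt$origin_id, sum)
  expect_equal(as.numeric(rt / rb[names(rt)]), rep(1, length(rt)),
               tolerance = 0.05)
})

test_that("identical config and seed give identical generated output", {
  cfg <- city_config(grid_n = 8L, dzn_block = 2L, straddle_frac = 0.05)
  a <- simulate_city(cfg, seed = 9)
  b <- simulate_city(cfg, seed = 9)
  expect_identical(a$visits, b$visits)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$seifa, b$seifa)
  c2 <- simulate_city(cfg, seed = 10)
  expect_false(identical(a$visits, c2$visits))
})
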