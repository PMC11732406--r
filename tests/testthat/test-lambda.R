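# Outflow aggregation and the coverage-normalised log-ratio statistic.

test_that("aggregation drops excluded destinations and keeps empty origins", {
  visits <- data.frame(
    origin_id = c("i", "i", "j"),
    destination_id = c("z1", "z2", "z1"),
    period = "test",
    mean_daily_visits = c(5, 3, 2),
    stringsAsFactors = FALSE
  )
  ex <- data.frame(origin_id = "i", destination_id = "z1",
                   stringsAsFactors = FALSE)
  out <- aggregate_outflow(visits, ex, "test")
  expect_equal(out[["i"]], 3)
  expect_equal(out[["j"]], 2)
  # empty exclusion set: plain row sums
  out2 <- aggregate_outflow(visits, NULL, "test")
  expect_equal(out2[["i"]], 8)
  # origin whose every edge is excluded maps to 0
  ex2 <- data.frame(origin_id = c("j"), destination_id = c("z1"))
  expect_equal(aggregate_outflow(visits, ex2, "test")[["j"]], 0)
  expect_error(aggregate_outflow(visits, NULL, "nope"), "period")
})

test_that("aggregation equals a brute-force loop on a 6x6 grid fixture", {
  city <- toy_grid(6L, 2L)
  visits <- toy_visits(city, "test")
  ex <- find_excluded_pairs(city$origins, city$destinations)
  got <- aggregate_outflow(visits, ex, "test")
  exkey <- paste(ex$origin_id, ex$destination_id)
  want <- setNames(numeric(length(city$origins$ids)), city$origins$ids)
  for (r in seq_len(nrow(visits))) {
    key <- paste(visits$origin_id[r], visits$destination_id[r])
    if (!key %in% exkey) {
      want[visits$origin_id[r]] <- want[visits$origin_id[r]] +
        visits$mean_daily_visits[r]
    }
  }
  expect_equal(got[sort(names(got))], want[sort(names(want))])
})

cov2 <- function(ids, test, base) {
  rbind(
    data.frame(origin_id = ids, period = "test", coverage = test),
    data.frame(origin_id = ids, period = "baseline", coverage = base)
  )
}

test_that("lambda reproduces the worked log-ratio and identity cases", {
  # outflows 50 (test) and 100 (baseline), coverage 200/200: ln(0.5)
  mc <- compute_lambda(c(i = 50), c(i = 100), cov2("i", 200, 200))
  expect_equal(mc$lambda$lambda_mob, log(0.5), tolerance = 1e-12)
  expect_equal(mc$lambda$A, 0.25)
  expect_equal(mc$lambda$B, 0.5)

  # identical inputs: lambda == 0 everywhere
  o <- c(a = 3, b = 7)
  mc2 <- compute_lambda(o, o, cov2(c("a", "b"), c(10, 20), c(10, 20)))
  expect_equal(mc2$lambda$lambda_mob, c(0, 0))
})

test_that("lambda is invariant under joint rescaling and antisymmetric", {
  set.seed(1)
  ids <- letters[1:10]
  ot <- setNames(runif(10, 10, 50), ids)
  ob <- setNames(runif(10, 10, 50), ids)
  cv <- cov2(ids, runif(10, 100, 300), runif(10, 100, 300))
  base <- compute_lambda(ot, ob, cv)

  # multiply test outflow AND test coverage by 7: unchanged
  cv7 <- cv
  cv7$coverage[cv7$period == "test"] <- cv7$coverage[cv7$period == "test"] * 7
  scaled <- compute_lambda(ot * 7, ob, cv7)
  expect_equal(scaled$lambda$lambda_mob, base$lambda$lambda_mob)

  # per-origin rescaling applied equally to both periods: unchanged
  f <- setNames(runif(10, 0.5, 2), ids)
  cvf <- cv
  cvf$coverage <- cvf$coverage * f[cvf$origin_id]
  both <- compute_lambda(ot * f[ids], ob * f[ids], cvf)
  expect_equal(both$lambda$lambda_mob, base$lambda$lambda_mob)

  # swapping test and baseline negates lambda
  cvs <- cv
  cvs$period <- ifelse(cvs$period == "test", "baseline", "test")
  swapped <- compute_lambda(ob, ot, cvs)
  expect_equal(swapped$lambda$lambda_mob, -base$lambda$lambda_mob)
})

test_that("non-computable origins are omitted with the right reason codes", {
  ids <- c("a", "b", "c", "d")
  ot <- setNames(c(5, 0, 5, 5), ids)
  ob <- setNames(c(5, 5, 0, 5), ids)
  cv <- cov2(c("a", "b", "c"), c(10, 10, 10), c(10, 10, 10))  # d missing
  mc <- compute_lambda(ot, ob, cv)
  expect_equal(mc$lambda$origin_id, "a")
  reasons <- setNames(mc$exclusions$reason, mc$exclusions$origin_id)
  expect_equal(reasons[["b"]], "zero_outflow_test")
  expect_equal(reasons[["c"]], "zero_outflow_base")
  expect_equal(reasons[["d"]], "no_coverage")

  # undefined in one period means undefined in all
  cv1 <- cv[!(cv$origin_id == "a" & cv$period == "test"), ]
  mc2 <- compute_lambda(ot, ob, cv1)
  expect_true("a" %in% mc2$exclusions$origin_id)
})

test_that("enlarging the exclusion set never increases an outflow", {
  city <- toy_grid(6L, 2L)
  visits <- toy_visits(city, "test")
  ex1 <- find_excluded_pairs(city$origins, city$destinations)
  extra <- data.frame(origin_id = "O001", destination_id = "D004",
                      stringsAsFactors = FALSE)
  o1 <- aggregate_outflow(visits, ex1, "test")
  o2 <- aggregate_outflow(visits, rbind(ex1, extra), "test")
  expect_true(all(o2[names(o1)] <= o1 + 1e-12))
})

test_that("lambda summary reports median, count and histogram bins", {
  s <- lambda_summary(c(-1, 0, 1))
  expect_equal(s$median, 0)
  expect_equal(s$n, 3L)
  expect_equal(sum(s$counts), 3L)
  expect_equal(lambda_summary(rep(0.4, 5))$median, 0.4)
  expect_error(lambda_summary(numeric(0)), "input error")
})

test_that("end-to-end: constant true effect is recovered by lambda_mob", {
  cfg <- city_config(grid_n = 14L, dzn_block = 2L, sigma_noise = 0,
                     beta_eo = 0, beta_er = 0, beta_dist = 0,
                     straddle_frac = 0, trip_rate = 20)
  p <- generate_partitions(cfg)
  s <- generate_ses_scores(p$origins, cfg)
  tr <- make_ground_truth(s, p$origins, cfg)
  tr$lambda_true <- rep(-0.693, nrow(tr))  # uniform halving of mobility
  base <- generate_visits(p$origins, p$destinations, tr,
                          period_spec("baseline", 60L), cfg, seed = 3)
  test <- generate_visits(p$origins, p$destinations, tr,
                          period_spec("test", 60L), cfg, seed = 4)
  ex <- find_excluded_pairs(p$origins, p$destinations)
  ot <- aggregate_outflow(test$visits, ex, "test")
  ob <- aggregate_outflow(base$visits, ex, "baseline")
  mc <- compute_lambda(ot, ob, rbind(base$coverage, test$coverage))
  expect_equal(median(mc$lambda$lambda_mob), -0.693, tolerance = 0.05)
})
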