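#' Generate the origin and destination partitions of a synthetic city
#'
#' Builds the square-grid geometry described in [city_config()]: a
#' `grid_n` x `grid_n` origin tiling and the coarser destination tiling of
#' `dzn_block`-sized blocks.  A seeded sample of origins adjacent to an
#' internal destination boundary is deformed — the cell is extended half a
#' cell across the boundary and its right-hand neighbour shrunk to keep
#' origins disjoint — so those origins straddle two destination zones and
#' exercise the undefined-coverage path downstream.  Populations are drawn
#' uniformly on `pop_range`.
#'
#' @param config a [city_config()].
#' @param seed integer seed; defaults to `config$seed + 11`.
#' @return A list with elements `origins` and `destinations`, both
#'   [partition_set()]s.  `origins$regions` carries `population` and
#'   `straddling`.
#' @export
generate_partitions <- function(config, seed = config$seed + 11L) {
  validate_city_config(config)
  g <- config$grid_n
  b <- config$dzn_block
  s <- config$cell_km
  n <- g * g

  idx <- seq_len(n) - 1L
  row <- idx %/% g
  col <- idx %% g
  x0 <- col * s
  x1 <- (col + 1L) * s
  y0 <- row * s
  y1 <- (row + 1L) * s

  n_straddle <- round(config$straddle_frac * n)
  straddling <- logical(n)
  if (n_straddle > 0L) {
    # candidates: right edge on an internal destination boundary
    cand <- which((col + 1L) %% b == 0L & col < g - 1L)
    if (b == 1L) cand <- cand[col[cand] %% 2L == 0L]  # keep neighbours intact
    if (length(cand) < n_straddle) {
      stop("configuration error: straddle_frac too large for this grid",
           call. = FALSE)
    }
    pick <- with_seed(seed, sample(cand, n_straddle))
    straddling[pick] <- TRUE
    x1[pick] <- x1[pick] + s / 2          # extend across the boundary
    x0[pick + 1L] <- x0[pick + 1L] + s / 2  # shrink the right neighbour
  }

  geoms <- vector("list", n)
  for (k in seq_len(n)) {
    geoms[[k]] <- cbind(c(x0[k], x1[k], x1[k], x0[k]),
                        c(y0[k], y0[k], y1[k], y1[k]))
  }
  ids <- sprintf("O%04d", seq_len(n))
  names(geoms) <- ids
  population <- with_seed(seed + 1L,
    sample(seq(config$pop_range[1L], config$pop_range[2L]), n, replace = TRUE))
  origins <- partition_set(
    "origin", geoms,
    data.frame(region_id = ids, population = population,
               straddling = straddling, stringsAsFactors = FALSE),
    validate = FALSE
  )

  gd <- g %/% b
  nd <- gd * gd
  dgeoms <- vector("list", nd)
  dids <- sprintf("D%04d", seq_len(nd))
  side <- b * s
  for (k in seq_len(nd) - 1L) {
    dr <- k %/% gd
    dc <- k %% gd
    dgeoms[[k + 1L]] <- cbind(
      c(dc * side, (dc + 1L) * side, (dc + 1L) * side, dc * side),
      c(dr * side, dr * side, (dr + 1L) * side, (dr + 1L) * side)
    )
  }
  names(dgeoms) <- dids
  destinations <- partition_set("destination", dgeoms, validate = FALSE)

  list(origins = origins, destinations = destinations)
}

#' Generate SEIFA-like ER and EO scores for origin regions
#'
#' ER and EO are drawn from a bivariate Gaussian with correlation
#' `rho_er_eo`; EO is then tilted against distance to the city centre so
#' that `cor(EO, distance)` approaches `gamma_eo_dist` (the tilt shrinks
#' the realised ER-EO correlation by `sqrt(1 - gamma_eo_dist^2)`).  Scores
#' are mapped affinely to the SEIFA-like scale mean 1000, s.d. 100.
#'
#' @param partitions origin [partition_set()].
#' @param config a [city_config()].
#' @param seed integer seed; defaults to `config$seed + 23`.
#' @param city city label attached to every region.
#' @return Data frame (`seifa` table): `origin_id`, `er_score`,
#'   `eo_score`, `city`.
#' @export
generate_ses_scores <- function(partitions, config,
                                seed = config$seed + 23L,
                                city = "synthetic") {
  stopifnot(inherits(partitions, "partition_set"))
  validate_city_config(config)
  rho <- config$rho_er_eo
  gam <- config$gamma_eo_dist
  n <- n_regions(partitions)
  ctr <- .city_centre(config)
  d <- sqrt((partitions$centroids[, 1L] - ctr[1L])^2 +
            (partitions$centroids[, 2L] - ctr[2L])^2)
  zd <- as.numeric(scale(d))
  z <- with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    list(z1 = z1, z2 = z2)
  })
  zeo <- sqrt(1 - gam^2) * z$z2 + gam * zd
  data.frame(
    origin_id = partitions$ids,
    er_score = 1000 + 100 * z$z1,
    eo_score = 1000 + 100 * zeo,
    city = city,
    stringsAsFactors = FALSE
  )
}

.city_centre <- function(config) {
  half <- config$grid_n * config$cell_km / 2
  c(half, half)
}

#' Build the ground-truth mobility-change field
#'
#' `lambda_true(i) = beta_eo * zEO(i) + beta_er * zER(i) +
#' beta_dist * zdist(i) + N(0, sigma_noise)`, with all covariates
#' standardized in-sample.  The returned covariates are the ones the
#' parameter-recovery tests regress against.
#'
#' @param seifa SES score table from [generate_ses_scores()].
#' @param origins origin [partition_set()].
#' @param config a [city_config()].
#' @param seed integer seed; defaults to `config$seed + 37`.
#' @return Data frame: `origin_id`, `lambda_true`, `z_eo`, `z_er`,
#'   `z_dist`.
#' @export
make_ground_truth <- function(seifa, origins, config,
                              seed = config$seed + 37L) {
  stopifnot(inherits(origins, "partition_set"))
  validate_city_config(config)
  seifa <- seifa[match(origins$ids, seifa$origin_id), , drop = FALSE]
  if (anyNA(seifa$origin_id)) {
    stop("seifa table does not cover all origins", call. = FALSE)
  }
  ctr <- .city_centre(config)
  d <- sqrt((origins$centroids[, 1L] - ctr[1L])^2 +
            (origins$centroids[, 2L] - ctr[2L])^2)
  z_eo <- as.numeric(scale(seifa$eo_score))
  z_er <- as.numeric(scale(seifa$er_score))
  z_dist <- as.numeric(scale(d))
  noise <- if (config$sigma_noise > 0) {
    with_seed(seed, rnorm(length(d), 0, config$sigma_noise))
  } else {
    numeric(length(d))
  }
  data.frame(
    origin_id = origins$ids,
    lambda_true = config$beta_eo * z_eo + config$beta_er * z_er +
      config$beta_dist * z_dist + noise,
    z_eo = z_eo, z_er = z_er, z_dist = z_dist,
    stringsAsFactors = FALSE
  )
}

#' Generate visit counts and sample coverage for one period
#'
#' Expected daily flow from origin i to destination z follows a gravity
#' kernel `population(i) * exp(-d(i,z) / decay_km)`, truncated at
#' `max_radius_km` between centroids and normalised so the expected total
#' daily outflow of origin i is `trip_rate * population(i)`.  In a period
#' with effect scale `s`, flows are multiplied by
#' `exp(s * lambda_true(i))`.  Counts are Poisson per day over
#' `duration_days` and reported as mean daily counts (a Poisson total over
#' the period divided by the duration, which is distributionally identical
#' to summing daily draws).
#'
#' Both visit and coverage counts are proportional to the period's device
#' panel size: coverage counts are Poisson with the period's panel rate,
#' and expected visit counts carry the factor
#' `panel_rate(period) / panel_rate_base`.  Coverage is otherwise
#' independent of `lambda_true`, so its normalisation is exercised by
#' panel fluctuations but stays unbiased for the true mobility change.
#' Coverage is absent for straddling origins (no destination zone fully
#' contains them).
#'
#' @param origins,destinations [partition_set()]s from
#'   [generate_partitions()].
#' @param truth ground-truth table from [make_ground_truth()].
#' @param period a [period_spec()].
#' @param config a [city_config()].
#' @param seed integer seed (per period; [simulate_city()] derives one per
#'   period from `config$seed`).
#' @return List with `visits` (data frame `origin_id`, `destination_id`,
#'   `period`, `mean_daily_visits`; zero-count pairs are dropped) and
#'   `coverage` (data frame `origin_id`, `period`, `coverage`).
#' @export
generate_visits <- function(origins, destinations, truth, period, config,
                            seed) {
  stopifnot(inherits(origins, "partition_set"),
            inherits(destinations, "partition_set"),
            inherits(period, "period_spec"))
  validate_city_config(config)
  truth <- truth[match(origins$ids, truth$origin_id), , drop = FALSE]
  if (anyNA(truth$origin_id)) {
    stop("ground truth does not cover all origins", call. = FALSE)
  }
  oc <- origins$centroids
  dc <- destinations$centroids
  no <- nrow(oc)
  ndst <- nrow(dc)
  # no x ndst centroid distance matrix
  dist <- sqrt(outer(oc[, 1L], dc[, 1L], "-")^2 +
               outer(oc[, 2L], dc[, 2L], "-")^2)
  w <- exp(-dist / config$decay_km)
  w[dist > config$max_radius_km] <- 0
  rs <- rowSums(w)
  rs[rs == 0] <- Inf  # origin with no in-range destination: zero flow
  pop <- origins$regions$population
  rate <- .period_panel_rate(config, period)
  panel_scale <- rate / config$panel_rate_base
  mu <- (config$trip_rate * pop * panel_scale / rs) * w
  mu <- mu * exp(period$effect_scale * truth$lambda_true)

  dt <- period$duration_days
  keep <- which(mu > 0)
  counts <- with_seed(seed, rpois(length(keep), mu[keep] * dt))
  nz <- counts > 0
  keep <- keep[nz]
  visits <- data.frame(
    origin_id = origins$ids[(keep - 1L) %% no + 1L],
    destination_id = destinations$ids[(keep - 1L) %/% no + 1L],
    period = period$label,
    mean_daily_visits = counts[nz] / dt,
    stringsAsFactors = FALSE
  )
  visits <- visits[order((keep - 1L) %% no, (keep - 1L) %/% no), ]
  rownames(visits) <- NULL

  covered <- !origins$regions$straddling
  cov_counts <- with_seed(seed + 1L, rpois(sum(covered), rate * dt)) / dt
  coverage <- data.frame(
    origin_id = origins$ids[covered],
    period = period$label,
    coverage = cov_counts,
    stringsAsFactors = FALSE
  )
  list(visits = visits, coverage = coverage)
}

#' Simulate a complete synthetic city
#'
#' Runs partition, score, ground-truth and per-period visit generation
#' under the documented seed-splitting rule, and optionally writes the
#' standard files (`origins.geojson`, `destinations.geojson`,
#' `visits.csv`, `coverage.csv`, `ses.csv`, `truth.csv`) to `out_dir`.
#'
#' @param config a [city_config()].
#' @param out_dir optional output directory.
#' @param seed integer master seed, defaults to `config$seed`.
#' @return List with `origins`, `destinations`, `seifa`, `truth`,
#'   `visits` (all periods bound together) and `coverage`.
#' @export
simulate_city <- function(config = city_config(), out_dir = NULL,
                          seed = config$seed) {
  validate_city_config(config)
  parts <- generate_partitions(config, seed = seed + 11L)
  seifa <- generate_ses_scores(parts$origins, config, seed = seed + 23L)
  truth <- make_ground_truth(seifa, parts$origins, config, seed = seed + 37L)
  visits <- list()
  coverage <- list()
  for (k in seq_along(config$periods)) {
    per <- config$periods[[k]]
    vc <- generate_visits(parts$origins, parts$destinations, truth, per,
                          config, seed = seed + 41L + 2L * (k - 1L))
    visits[[k]] <- vc$visits
    coverage[[k]] <- vc$coverage
  }
  out <- list(
    origins = parts$origins, destinations = parts$destinations,
    seifa = seifa, truth = truth,
    visits = do.call(rbind, visits),
    coverage = do.call(rbind, coverage)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    og <- out$origins
    og$regions <- merge(og$regions, seifa[, c("origin_id", "er_score", "eo_score")],
                        by.x = "region_id", by.y = "origin_id", sort = FALSE)
    og$regions <- og$regions[match(og$ids, og$regions$region_id), , drop = FALSE]
    write_partitions(og, file.path(out_dir, "origins.geojson"))
    write_partitions(out$destinations, file.path(out_dir, "destinations.geojson"))
    write.csv(out$visits, file.path(out_dir, "visits.csv"), row.names = FALSE)
    write.csv(out$coverage, file.path(out_dir, "coverage.csv"), row.names = FALSE)
    write.csv(out$seifa, file.path(out_dir, "ses.csv"), row.names = FALSE)
    write.csv(out$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  out
}
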