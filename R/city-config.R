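#' Synthetic-city configuration
#'
#' Bundles every knob of the synthetic-city generator.  The geometry is a
#' `grid_n` x `grid_n` tiling of square origin cells of side `cell_km`;
#' destination zones are square blocks of `dzn_block` x `dzn_block` origin
#' cells.  A fraction `straddle_frac` of origin cells is deformed to
#' straddle an internal destination-zone boundary, so that no destination
#' zone fully contains them and their sample coverage is undefined —
#' mirroring the regions a real analysis has to drop.
#'
#' Socioeconomic scores mimic SEIFA indices: an economic-resources (ER)
#' and an education-occupation (EO) score per origin region, drawn from a
#' bivariate Gaussian with correlation `rho_er_eo`, EO additionally tilted
#' against distance to the city centre with strength `gamma_eo_dist`
#' (negative: high-EO areas sit near the centre).  The tilt attenuates the
#' realised ER-EO correlation by `sqrt(1 - gamma_eo_dist^2)`.
#'
#' The ground-truth mobility change is
#' `lambda_true = beta_eo * zEO + beta_er * zER + beta_dist * zdist +
#' N(0, sigma_noise)` on standardized covariates.  Visits follow a gravity
#' kernel `pop * exp(-d / decay_km)` truncated at `max_radius_km`, scaled
#' so an origin's expected daily outflow is `trip_rate * population`;
#' counts are Poisson per day.  Coverage counts are Poisson with mean
#' `panel_rate_base` / `panel_rate_test` per day, independent of
#' `lambda_true`, and absent for straddling origins.
#'
#' @param grid_n origin cells per side (>= 4, divisible by `dzn_block`).
#' @param dzn_block origin cells per destination-zone side.
#' @param cell_km origin cell side length, km.
#' @param pop_range integer (min, max) residents per origin region;
#'   the SA1-like default is 200-800.
#' @param rho_er_eo latent ER-EO correlation, |rho| < 1.
#' @param gamma_eo_dist correlation of EO with distance to centre.
#' @param beta_eo,beta_er,beta_dist true effects (per s.d.) on lambda_true.
#' @param sigma_noise s.d. of region-level noise on lambda_true.
#' @param panel_rate_base,panel_rate_test expected daily coverage counts.
#' @param trip_rate expected daily pass-through visits per resident.
#' @param decay_km gravity distance-decay scale, km.
#' @param max_radius_km visit horizon, km.
#' @param straddle_frac fraction of origins deformed to straddle a
#'   destination boundary.
#' @param periods list of [period_spec()]s generated by default runs.
#' @param seed default integer seed; stage seeds are derived from it by
#'   fixed offsets (+11 partitions, +23 SES scores, +37 ground truth,
#'   +41, +43, ... one per period in order, for visits/coverage).
#' @return A validated list of class `city_config`.
#' @export
city_config <- function(grid_n = 50L,
                        dzn_block = 2L,
                        cell_km = 1,
                        pop_range = c(200L, 800L),
                        rho_er_eo = 0.9,
                        gamma_eo_dist = -0.5,
                        beta_eo = -0.1,
                        beta_er = 0,
                        beta_dist = 0,
                        sigma_noise = 0.2,
                        panel_rate_base = 500,
                        panel_rate_test = 400,
                        trip_rate = 2,
                        decay_km = 8,
                        max_radius_km = 50,
                        straddle_frac = 0.04,
                        periods = list(period_spec("baseline"),
                                       period_spec("test")),
                        seed = 1L) {
  cfg <- list(
    grid_n = as.integer(grid_n), dzn_block = as.integer(dzn_block),
    cell_km = cell_km, pop_range = as.integer(pop_range),
    rho_er_eo = rho_er_eo, gamma_eo_dist = gamma_eo_dist,
    beta_eo = beta_eo, beta_er = beta_er, beta_dist = beta_dist,
    sigma_noise = sigma_noise,
    panel_rate_base = panel_rate_base, panel_rate_test = panel_rate_test,
    trip_rate = trip_rate, decay_km = decay_km,
    max_radius_km = max_radius_km, straddle_frac = straddle_frac,
    periods = periods, seed = as.integer(seed)
  )
  class(cfg) <- "city_config"
  validate_city_config(cfg)
  cfg
}

#' @rdname city_config
#' @param cfg a `city_config`.
#' @export
validate_city_config <- function(cfg) {
  stopifnot(inherits(cfg, "city_config"))
  err <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$grid_n < 4L) err("grid_n must be >= 4")
  if (cfg$dzn_block < 1L) err("dzn_block must be >= 1")
  if (cfg$grid_n %% cfg$dzn_block != 0L) {
    err("grid_n (", cfg$grid_n, ") not divisible by dzn_block (",
        cfg$dzn_block, ")")
  }
  if (cfg$cell_km <= 0) err("cell_km must be positive")
  if (length(cfg$pop_range) != 2L || cfg$pop_range[1L] < 1L ||
      cfg$pop_range[1L] > cfg$pop_range[2L]) {
    err("pop_range must be an increasing positive pair")
  }
  if (abs(cfg$rho_er_eo) >= 1) err("|rho_er_eo| must be < 1")
  if (abs(cfg$gamma_eo_dist) >= 1) err("|gamma_eo_dist| must be < 1")
  if (cfg$sigma_noise < 0) err("sigma_noise must be >= 0")
  if (cfg$panel_rate_base <= 0 || cfg$panel_rate_test <= 0) {
    err("panel rates must be positive")
  }
  if (cfg$trip_rate <= 0) err("trip_rate must be positive")
  if (cfg$decay_km <= 0) err("decay_km must be positive")
  if (cfg$max_radius_km <= 0) err("max_radius_km must be positive")
  if (cfg$straddle_frac < 0 || cfg$straddle_frac >= 1) {
    err("straddle_frac must be in [0, 1)")
  }
  labs <- vapply(cfg$periods, function(p) p$label, character(1L))
  if (anyDuplicated(labs)) err("duplicate period labels")
  invisible(cfg)
}

#' Period specification
#'
#' A named analysis period.  `effect_scale` multiplies the ground-truth
#' `lambda_true` field in that period: 0 for pre-pandemic baselines,
#' 1 for a fully expressed test period.  `panel_rate` overrides the
#' config-level expected daily coverage count, emulating device panels
#' that fluctuate between periods.
#'
#' @param label period name, e.g. `"baseline"`, `"test"`, `"lockdown"`.
#' @param duration_days number of days averaged over (>= 1).
#' @param effect_scale multiplier on `lambda_true`; defaults to 1 for the
#'   label `"test"`, else 0.
#' @param panel_rate optional expected daily coverage count.
#' @return A list of class `period_spec`.
#' @export
period_spec <- function(label, duration_days = 30L,
                        effect_scale = if (identical(label, "test")) 1 else 0,
                        panel_rate = NULL) {
  duration_days <- as.integer(duration_days)
  if (is.na(duration_days) || duration_days < 1L) {
    stop("duration_days must be >= 1", call. = FALSE)
  }
  structure(
    list(label = as.character(label), duration_days = duration_days,
         effect_scale = effect_scale, panel_rate = panel_rate),
    class = "period_spec"
  )
}

.find_period <- function(cfg, label) {
  for (p in cfg$periods) if (identical(p$label, label)) return(p)
  stop("period '", label, "' not declared in config", call. = FALSE)
}

.period_panel_rate <- function(cfg, period) {
  period$panel_rate %||%
    if (period$effect_scale == 0) cfg$panel_rate_base else cfg$panel_rate_test
}
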