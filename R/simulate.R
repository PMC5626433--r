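#' Synthetic landscape configuration
#'
#' Defaults emulate the study conditions the pipeline targets: a 4 x 4 km
#' agricultural mosaic observed at 30 m (vegetation index) with a 10 m DEM.
#' Field size is controlled by the number of Voronoi seeds (`n_fields`); a
#' configurable fraction of fields is flagged semi-natural with a distinct
#' (greener) index range. Relief is a Gaussian random field with a given
#' amplitude (SD of elevation, metres) and correlation length.
#'
#' @param extent_m Side length of the square site (default 4000).
#' @param ndvi_pixel_m,dem_pixel_m Pixel sizes (default 30 and 10 m).
#' @param n_fields Number of Voronoi field seeds (default 120, giving
#'   median field widths of a few hundred metres).
#' @param ndvi_field_mean_range Range of per-field mean index for cropped
#'   fields (default `c(0.2, 0.85)`).
#' @param ndvi_semi_natural_range Index range for semi-natural fields
#'   (default `c(0.55, 0.95)`).
#' @param ndvi_within_field_sd Within-field Gaussian noise SD (default 0.02).
#' @param semi_natural_fraction Fraction of fields flagged semi-natural
#'   (default 0.1).
#' @param relief_amplitude_m SD of elevation (default 25 m).
#' @param relief_correlation_length_m Gaussian-field correlation length
#'   (default 500 m).
#' @param seed Integer seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(extent_m = 4000, ndvi_pixel_m = 30,
                             dem_pixel_m = 10, n_fields = 120,
                             ndvi_field_mean_range = c(0.2, 0.85),
                             ndvi_semi_natural_range = c(0.55, 0.95),
                             ndvi_within_field_sd = 0.02,
                             semi_natural_fraction = 0.1,
                             relief_amplitude_m = 25,
                             relief_correlation_length_m = 500,
                             seed = 1L) {
  stopifnot(extent_m > 0, ndvi_pixel_m > 0, dem_pixel_m > 0, n_fields >= 1,
            semi_natural_fraction >= 0, semi_natural_fraction <= 1,
            relief_amplitude_m >= 0, relief_correlation_length_m > 0)
  structure(as.list(environment()), class = "landscape_config")
}

# stationary Gaussian random field on an n x n torus via FFT smoothing of
# white noise with a Gaussian kernel (sd = corr_len_px)
gaussian_field <- function(n, corr_len_px) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k1 <- exp(-d^2 / (2 * corr_len_px^2))
  K <- outer(k1, k1)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(K), inverse = TRUE)) / n^2
  (sm - mean(sm)) / stats::sd(sm)
}

#' Simulate a patchy agricultural landscape and its DEM
#'
#' The vegetation index is a Voronoi mosaic of fields, each with its own
#' mean index (cropped or semi-natural range) plus within-field Gaussian
#' noise, clamped to `[-1, 1]`. The DEM is a Gaussian random field scaled
#' to the configured amplitude. Fully deterministic under the config seed.
#'
#' @param cfg A [landscape_config()].
#' @return List with `ndvi` and `dem` [raster_grid()] layers.
#' @export
simulate_landscape <- function(cfg = landscape_config()) {
  stopifnot(inherits(cfg, "landscape_config"))
  set.seed(cfg$seed)
  n_ndvi <- max(3L, floor(cfg$extent_m / cfg$ndvi_pixel_m))
  sx <- stats::runif(cfg$n_fields, 0, cfg$extent_m)
  sy <- stats::runif(cfg$n_fields, 0, cfg$extent_m)
  semi <- stats::runif(cfg$n_fields) < cfg$semi_natural_fraction
  means <- ifelse(semi,
                  stats::runif(cfg$n_fields, cfg$ndvi_semi_natural_range[1],
                               cfg$ndvi_semi_natural_range[2]),
                  stats::runif(cfg$n_fields, cfg$ndvi_field_mean_range[1],
                               cfg$ndvi_field_mean_range[2]))
  cx <- (seq_len(n_ndvi) - 0.5) * cfg$ndvi_pixel_m
  cy <- cfg$extent_m - (seq_len(n_ndvi) - 0.5) * cfg$ndvi_pixel_m
  # nearest field seed per cell (Voronoi assignment)
  nearest <- matrix(0L, n_ndvi, n_ndvi)
  for (j in seq_len(n_ndvi)) {
    d2 <- vapply(seq_len(cfg$n_fields),
                 function(k) (cy - sy[k])^2 + (cx[j] - sx[k])^2,
                 numeric(n_ndvi))
    nearest[, j] <- max.col(-d2, ties.method = "first")
  }
  vals <- means[nearest] +
    if (cfg$ndvi_within_field_sd > 0)
      stats::rnorm(n_ndvi * n_ndvi, 0, cfg$ndvi_within_field_sd) else 0
  ndvi <- raster_grid(matrix(pmin(pmax(vals, -1), 1), n_ndvi, n_ndvi),
                      origin = c(0, cfg$extent_m),
                      pixel_size = cfg$ndvi_pixel_m)
  n_dem <- max(3L, floor(cfg$extent_m / cfg$dem_pixel_m))
  dem_vals <- if (cfg$relief_amplitude_m == 0) {
    matrix(0, n_dem, n_dem)
  } else {
    gaussian_field(n_dem, cfg$relief_correlation_length_m / cfg$dem_pixel_m) *
      cfg$relief_amplitude_m
  }
  dem <- raster_grid(dem_vals, origin = c(0, cfg$extent_m),
                     pixel_size = cfg$dem_pixel_m)
  list(ndvi = ndvi, dem = dem)
}

#' Place one trap per grid cell
#'
#' Divides the square site into `grid_step_m` cells and places one trap per
#' cell, uniformly jittered within the cell. When `max_radius` is given the
#' positions are additionally clipped so the largest buffer stays inside
#' the site. The default 4 km extent with 1 km cells yields 16 traps.
#'
#' @param extent_m Site side length (default 4000).
#' @param grid_step_m Cell size (default 1000).
#' @param jitter_m Maximum displacement from the cell center in each axis;
#'   default half the cell (uniform anywhere in the cell); 0 gives cell
#'   centers.
#' @param seed Integer seed.
#' @param site Site label (default `"SYN"`).
#' @param max_radius Optional clip margin in metres.
#' @return Tibble with `trap_id`, `x`, `y`, `site`.
#' @export
place_traps <- function(extent_m = 4000, grid_step_m = 1000,
                        jitter_m = grid_step_m / 2, seed = 1L, site = "SYN",
                        max_radius = NULL) {
  stopifnot(grid_step_m <= extent_m)
  set.seed(seed)
  k <- floor(extent_m / grid_step_m)
  centers <- (seq_len(k) - 0.5) * grid_step_m
  grid <- expand.grid(cx = centers, cy = centers)
  x <- grid$cx + stats::runif(nrow(grid), -jitter_m, jitter_m)
  y <- grid$cy + stats::runif(nrow(grid), -jitter_m, jitter_m)
  x <- pmin(pmax(x, grid$cx - grid_step_m / 2), grid$cx + grid_step_m / 2)
  y <- pmin(pmax(y, grid$cy - grid_step_m / 2), grid$cy + grid_step_m / 2)
  if (!is.null(max_radius)) {
    x <- pmin(pmax(x, max_radius), extent_m - max_radius)
    y <- pmin(pmax(y, max_radius), extent_m - max_radius)
  }
  tibble::tibble(trap_id = sprintf("%s_t%02d", site, seq_len(nrow(grid))),
                 x = x, y = y, site = site)
}

#' Synthetic bee-community configuration
#'
#' Controls the generative model of trap catches: per trap x year x season
#' the log-expected total count is linear in the *scaled* local entropy and
#' roughness predictors plus site, season and year effects; totals are
#' negative-binomial (Poisson when `overdispersion = 0`) and individuals
#' are allotted to species by a log-normal species-abundance distribution
#' drawn per site. A configurable fraction of the pool is flagged as the
#' bumble-bee genus.
#'
#' @param n_species_pool Species-pool size (default 80).
#' @param sad_lognormal_mu,sad_lognormal_sigma Log-normal SAD parameters
#'   (defaults 0 and 1.2).
#' @param beta0 Intercept of the log-expected count (default `log(25)`,
#'   i.e. about 25 bees per trap and period).
#' @param beta_entropy,beta_roughness True effects on the log-expected
#'   count per SD of the predictor (defaults 0.1).
#' @param site_sd,year_sd SDs of the Gaussian site and year effects
#'   (defaults 0.3 and 0.2).
#' @param season_effect Additive late-season effect on the log scale
#'   (default -0.3).
#' @param overdispersion Negative-binomial overdispersion `theta` with
#'   `var = mu + theta mu^2`; 0 means Poisson (default 0.1).
#' @param trapping_days Trap-days per period (default 42.5).
#' @param years Calendar years simulated (default 2010:2012).
#' @param bombus_fraction Fraction of the pool flagged as bumble bees
#'   (default 0.1).
#' @param entropy_col,roughness_col Predictor-table columns carrying the
#'   effects (defaults `"ent1_mean_100"`, `"rough_mean_100"`).
#' @param seed Integer seed.
#' @return A `community_config` list.
#' @export
community_config <- function(n_species_pool = 80, sad_lognormal_mu = 0,
                             sad_lognormal_sigma = 1.2, beta0 = log(25),
                             beta_entropy = 0.1, beta_roughness = 0.1,
                             site_sd = 0.3, year_sd = 0.2,
                             season_effect = -0.3, overdispersion = 0.1,
                             trapping_days = 42.5, years = 2010:2012,
                             bombus_fraction = 0.1,
                             entropy_col = "ent1_mean_100",
                             roughness_col = "rough_mean_100", seed = 1L) {
  stopifnot(n_species_pool >= 2, overdispersion >= 0, trapping_days > 0)
  structure(as.list(environment()), class = "community_config")
}

#' Simulate trap records from local heterogeneity
#'
#' @param traps Tibble from [place_traps()].
#' @param predictors Predictor table containing the configured entropy and
#'   roughness columns (scaled internally to SD 1 across traps, so the
#'   betas are per-SD effects).
#' @param cfg A [community_config()].
#' @return Tibble of records: `trap_id`, `year`, `season`, `species`,
#'   `count`, `trapping_days`.
#' @export
simulate_community <- function(traps, predictors, cfg = community_config()) {
  stopifnot(inherits(cfg, "community_config"))
  need <- c(cfg$entropy_col, cfg$roughness_col)
  if (!all(need %in% names(predictors))) {
    stop("predictors lack column(s): ",
         paste(setdiff(need, names(predictors)), collapse = ", "),
         call. = FALSE)
  }
  set.seed(cfg$seed)
  scale01 <- function(v) (v - mean(v)) / stats::sd(v)
  ent <- scale01(predictors[[cfg$entropy_col]])
  rough <- scale01(predictors[[cfg$roughness_col]])
  sites <- unique(predictors$site)
  site_eff <- stats::setNames(stats::rnorm(length(sites), 0, cfg$site_sd), sites)
  year_eff <- stats::setNames(stats::rnorm(length(cfg$years), 0, cfg$year_sd),
                              cfg$years)
  is_bb <- seq_len(cfg$n_species_pool) <= round(cfg$bombus_fraction *
                                                  cfg$n_species_pool)
  species <- ifelse(is_bb,
                    sprintf("Bombus synth%03d", seq_len(cfg$n_species_pool)),
                    sprintf("Solitarius synth%03d", seq_len(cfg$n_species_pool)))
  # site-specific SAD draws over a shared pool
  sad <- lapply(sites, function(s) {
    p <- exp(stats::rnorm(cfg$n_species_pool, cfg$sad_lognormal_mu,
                          cfg$sad_lognormal_sigma))
    p / sum(p)
  })
  names(sad) <- sites
  design <- tidyr::crossing(idx = seq_len(nrow(predictors)),
                            year = cfg$years, season = c("early", "late"))
  recs <- purrr::pmap(design, function(idx, year, season) {
    lp <- cfg$beta0 + cfg$beta_entropy * ent[idx] +
      cfg$beta_roughness * rough[idx] +
      site_eff[[predictors$site[idx]]] + year_eff[[as.character(year)]] +
      if (season == "late") cfg$season_effect else 0
    lambda <- exp(lp)
    total <- if (cfg$overdispersion == 0) stats::rpois(1, lambda) else
      stats::rnbinom(1, mu = lambda, size = 1 / cfg$overdispersion)
    if (total == 0) return(NULL)
    counts <- as.vector(stats::rmultinom(1, total, sad[[predictors$site[idx]]]))
    keep <- counts > 0
    tibble::tibble(trap_id = predictors$trap_id[idx], year = year,
                   season = season, species = species[keep],
                   count = counts[keep], trapping_days = cfg$trapping_days)
  })
  dplyr::bind_rows(recs)
}

#' Simulate a complete synthetic study
#'
#' Landscape, traps, texture layers, buffer predictors and trap records in
#' one call — the inputs every downstream stage expects.
#'
#' @param landscape A [landscape_config()].
#' @param community A [community_config()].
#' @param radii Buffer distance classes (default `seq(100, 1000, 100)`).
#' @param kind Buffer geometry (default `"annulus"`).
#' @param n_levels,window,roughness_smoothing_window Texture settings.
#' @param seed Master seed; stage seeds are derived from it so the whole
#'   study is reproducible from one integer.
#' @return List with `ndvi`, `dem`, `traps`, `layers`, `predictors`,
#'   `records`.
#' @export
simulate_study <- function(landscape = landscape_config(),
                           community = community_config(),
                           radii = seq(100, 1000, by = 100),
                           kind = "annulus", n_levels = 32, window = 3,
                           roughness_smoothing_window = 9, seed = 1L) {
  landscape$seed <- seed
  community$seed <- seed + 1000L
  scene <- simulate_landscape(landscape)
  traps <- place_traps(landscape$extent_m, seed = seed + 2000L,
                       max_radius = NULL)
  layers <- texture_layers(scene$ndvi, scene$dem, n_levels = n_levels,
                           spec = texture_window(window),
                           roughness_smoothing_window = roughness_smoothing_window)
  predictors <- assemble_predictors(traps, layers, radii = radii, kind = kind)
  records <- simulate_community(traps, predictors, community)
  c(scene, list(traps = traps, layers = layers, predictors = predictors,
                records = records))
}

#' Synthetic predictor table with correlated distance classes
#'
#' Generates, for each variable, distance-class columns following a
#' first-order autoregressive correlation across adjacent classes
#' (population correlation `adjacent_correlation` between neighbouring
#' classes, decaying geometrically with class separation) — the
#' cross-scale correlation structure that motivates distance-class
#' pruning. With strong adjacent correlation and the extremes-first
#' priority, greedy pruning retains exactly the 100 m and 1000 m classes.
#'
#' @param n_rows Number of observations (default 500).
#' @param variables Variable stems, `<metric>_<summary>` (default two).
#' @param classes Distance classes (default `seq(100, 1000, 100)`).
#' @param adjacent_correlation AR(1) coefficient between adjacent classes
#'   (default 0.94).
#' @param seed Integer seed.
#' @return Tibble with `trap_id` and one column per variable x class.
#' @export
simulate_correlated_classes <- function(n_rows = 500,
                                        variables = c("ent1_mean", "rough_mean"),
                                        classes = seq(100, 1000, by = 100),
                                        adjacent_correlation = 0.94,
                                        seed = 1L) {
  set.seed(seed)
  out <- list(trap_id = sprintf("t%04d", seq_len(n_rows)))
  for (v in variables) {
    z <- stats::rnorm(n_rows)
    for (k in seq_along(classes)) {
      if (k > 1) {
        z <- adjacent_correlation * z +
          sqrt(1 - adjacent_correlation^2) * stats::rnorm(n_rows)
      }
      out[[paste(v, classes[k], sep = "_")]] <- z
    }
  }
  tibble::as_tibble(out)
}
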