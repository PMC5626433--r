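#' Simulation experiments for validating the pipeline
#'
#' These functions bundle the package's standard simulation studies: they
#' generate synthetic inputs, run the relevant pipeline stages, and return
#' per-replicate results as tibbles ready for summarising. They are used
#' by the test suite and the reproduction script, and are exported so the
#' same experiments can be rerun interactively.
#'
#' @name experiments
NULL

#' Windowed-versus-enumeration check of the co-occurrence statistics
#'
#' Draws random quantized windows (odd sizes between `min_window` and
#' `max_window`, random grey-level counts, optional interior nodata) and
#' compares the moving-window GLCM statistics against the independent
#' pair-enumeration reference ([glcm_reference()]) on each.
#'
#' @param n_windows Number of random windows (default 120).
#' @param min_window,max_window Odd window-size bounds (defaults 3 and 9).
#' @param na_fraction Fraction of interior cells set to nodata (default
#'   0.05; the center cell is never nodata).
#' @param seed Integer seed.
#' @return Tibble with one row per window and statistic: `window`, `size`,
#'   `statistic`, `windowed`, `reference`, `abs_error`.
#' @export
glcm_oracle_experiment <- function(n_windows = 120, min_window = 3,
                                   max_window = 9, na_fraction = 0.05,
                                   seed = 1L) {
  set.seed(seed)
  sizes <- seq(min_window, max_window, by = 2)
  out <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    sz <- sample(sizes, 1)
    ng <- sample(3:8, 1)
    lev <- matrix(sample(0:(ng - 1), sz * sz, replace = TRUE), sz, sz)
    if (na_fraction > 0) {
      na_idx <- which(stats::runif(sz * sz) < na_fraction)
      na_idx <- setdiff(na_idx, (sz * sz + 1) %/% 2)  # keep the center valid
      lev[na_idx] <- NA
    }
    q <- structure(list(levels = lev, n_levels = ng,
                        bin_edges = seq(0, ng, by = 1),
                        origin = c(0, sz), pixel_size = 1, crs = "local"),
                   class = "quantized_raster")
    got <- glcm_textures(q, texture_window(sz))
    ctr <- (sz + 1) %/% 2
    ref <- glcm_reference(lev)
    out[[w]] <- tibble::tibble(
      window = w, size = sz,
      statistic = c("contrast", "dissimilarity", "entropy", "homogeneity"),
      windowed = vapply(got, function(g) g$values[ctr, ctr], numeric(1)),
      reference = unlist(ref))
  }
  dplyr::mutate(dplyr::bind_rows(out),
                abs_error = abs(.data$windowed - .data$reference))
}

#' Planted-effect parameter-recovery experiment
#'
#' The end-to-end study the synthetic generator exists for: in each
#' replicate a fresh landscape is simulated, texture and roughness layers
#' are computed, buffer predictors assembled, a bee community generated
#' with the planted per-SD effects of local entropy and roughness on the
#' log-expected count, and the all-subsets AIC-averaged model refit to the
#' log bee count of the full wild-bee dataset. The test-predictor menu is
#' the pair of planted predictors, the estimand the averaging procedure is
#' asked to recover.
#'
#' @param n_rep Number of replicates (default 100).
#' @param beta_entropy,beta_roughness Planted per-SD effects (defaults 0.1).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param years Simulated years (default 2010:2012: 16 traps x 2 seasons x
#'   3 years = 96 observations per replicate).
#' @return Tibble with one row per replicate and planted predictor:
#'   `rep`, `term`, `truth`, `estimate`, `sd`, `importance`, `p.value`,
#'   `covered` (truth within estimate +/- 2 sd).
#' @export
recovery_experiment <- function(n_rep = 100, beta_entropy = 0.1,
                                beta_roughness = 0.1, seed = 1L,
                                years = 2010:2012) {
  cfg0 <- community_config(beta_entropy = beta_entropy,
                           beta_roughness = beta_roughness, years = years)
  menu <- c(cfg0$entropy_col, cfg0$roughness_col)
  truth <- stats::setNames(c(beta_entropy, beta_roughness), menu)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_study(community = cfg0, radii = c(100, 1000),
                          seed = seed * 10000L + r)
    bio <- add_bc_log(build_biodiversity(sim$records))
    pred <- scale_predictors(sim$predictors[c("trap_id", "site", menu)], menu)
    joined <- dplyr::inner_join(dplyr::filter(bio, .data$group == "nohb"),
                                pred, by = "trap_id")
    fit <- fit_texture_model(joined, "BC_log", menu, usable_controls(joined))
    out[[r]] <- dplyr::mutate(fit$averaged, rep = r,
                              truth = truth[.data$term], .before = 1)
  }
  dplyr::mutate(dplyr::bind_rows(out),
                covered = abs(.data$estimate - .data$truth) <= 2 * .data$sd)
}

#' Permutation-correlogram calibration experiment
#'
#' Draws `n_datasets` sets of exchangeable (independent normal) residuals
#' at random point layouts and collects every evaluated bin's permutation
#' p-value. Under exchangeability the per-bin rejection rate at level
#' `alpha` should sit at the nominal level.
#'
#' @param n_datasets Number of simulated datasets (default 500).
#' @param n_points Points per dataset (default 100).
#' @param n_perm Permutations per correlogram (default 500).
#' @param extent_m Square extent the points are scattered over (default
#'   4000).
#' @param bin_width Distance-class width (default 100).
#' @param seed Integer seed.
#' @return Tibble with one row per dataset x bin: `dataset`, `bin_center`,
#'   `rho`, `n_pairs`, `p_perm`.
#' @export
correlogram_calibration <- function(n_datasets = 500, n_points = 100,
                                    n_perm = 500, extent_m = 4000,
                                    bin_width = 100, seed = 1L) {
  out <- vector("list", n_datasets)
  set.seed(seed)
  dataset_seeds <- sample.int(2^30, n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(dataset_seeds[d])
    pts <- tibble::tibble(x = stats::runif(n_points, 0, extent_m),
                          y = stats::runif(n_points, 0, extent_m))
    z <- stats::rnorm(n_points)
    cg <- residual_correlogram(z, pts, bin_width = bin_width, n_perm = n_perm,
                               seed = dataset_seeds[d])
    out[[d]] <- dplyr::mutate(cg$bins, dataset = d, .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Field-size / entropy monotonicity experiment
#'
#' The mechanism that makes first-order entropy informative about farmland
#' heterogeneity: smaller fields put more field borders into each moving
#' window, raising the window's grey-level disorder. For each of
#' `n_seeds` paired seeds, two landscapes are simulated that differ only
#' in the number of Voronoi fields, and the mean first-order entropy layer
#' value is recorded for both.
#'
#' @param n_seeds Number of paired seeds (default 20).
#' @param n_fields_small_fields Voronoi seed count giving *small* fields
#'   (default 300).
#' @param n_fields_large_fields Voronoi seed count giving *large* fields
#'   (default 40).
#' @param seed Base seed.
#' @return Tibble with `seed`, `entropy_small_fields`,
#'   `entropy_large_fields`, `small_exceeds_large`.
#' @export
entropy_fieldsize_experiment <- function(n_seeds = 20,
                                         n_fields_small_fields = 300,
                                         n_fields_large_fields = 40,
                                         seed = 1L) {
  mean_entropy <- function(n_fields, s) {
    scene <- simulate_landscape(landscape_config(n_fields = n_fields, seed = s))
    layers <- firstorder_textures(quantize(scene$ndvi))
    mean(layers$entropy$values, na.rm = TRUE)
  }
  purrr::map_dfr(seq_len(n_seeds), function(k) {
    s <- seed * 1000L + k
    small <- mean_entropy(n_fields_small_fields, s)
    large <- mean_entropy(n_fields_large_fields, s)
    tibble::tibble(seed = s, entropy_small_fields = small,
                   entropy_large_fields = large,
                   small_exceeds_large = small > large)
  })
}
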