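#' Pipeline run configuration
#'
#' One nested list drives every stage; it round-trips losslessly through
#' YAML (`read_run_config()` / `write_run_config()`). All randomness is
#' governed by the single `seed`; stages derive their own substreams from
#' it.
#'
#' @param outdir Output directory for artifacts and manifests.
#' @param seed Master seed.
#' @param paths Named list of input paths (`ndvi`, `dem`, `traps`,
#'   `records`); stages fall back to the artifacts of upstream stages in
#'   `outdir`.
#' @param textures,buffers,screening,modelling,diagnostics,simulate Stage
#'   option lists; missing entries take the documented defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = "beescape-run", seed = 1L, paths = list(),
                       textures = list(), buffers = list(), screening = list(),
                       modelling = list(), diagnostics = list(),
                       simulate = list()) {
  defaults <- list(
    textures = list(n_levels = 32, window = 3, glcm_distance = 1,
                    roughness_smoothing_window = 9),
    buffers = list(radii = seq(100, 1000, by = 100), kind = "annulus"),
    screening = list(threshold = 0.7,
                     class_priority = c(100, 1000, 500, 200, 300, 400, 600,
                                        700, 800, 900),
                     importance_ranking = NULL, sqrt_vif_threshold = 2,
                     max_vif_predictors = 12),
    modelling = list(delta_threshold = 2,
                     responses = c("BC_log", "SD", "SpR"),
                     max_predictors = 6),
    diagnostics = list(bin_width = 100, n_perm = 500, max_distance = NULL),
    simulate = list())
  cfg <- list(outdir = outdir, seed = as.integer(seed), paths = paths,
              textures = utils::modifyList(defaults$textures, textures),
              buffers = utils::modifyList(defaults$buffers, buffers),
              screening = utils::modifyList(defaults$screening, screening,
                                            keep.null = TRUE),
              modelling = utils::modifyList(defaults$modelling, modelling),
              diagnostics = utils::modifyList(defaults$diagnostics, diagnostics,
                                              keep.null = TRUE),
              simulate = simulate)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

artifact <- function(cfg, ...) file.path(cfg$outdir, ...)

require_artifact <- function(cfg, file, produced_by) {
  p <- artifact(cfg, file)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s'; run stage '%s' first", file,
                 produced_by), call. = FALSE)
  }
  p
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  man <- list(stage = stage, inputs = inputs, outputs = outputs,
              seed = cfg$seed, config_hash = rlang::hash(unclass(cfg)),
              package_version = as.character(utils::packageVersion("beescape")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, artifact(cfg, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Control factors usable in a model
#'
#' Returns the control columns present in the data with at least two
#' distinct values (a single-site or single-year dataset cannot estimate
#' the corresponding effect).
#'
#' @param data Joined modelling tibble.
#' @param controls Candidate control columns.
#' @return Character vector of usable control columns.
#' @export
usable_controls <- function(data, controls = c("site", "year", "season")) {
  controls <- intersect(controls, names(data))
  controls[vapply(controls, function(cc) length(unique(data[[cc]])) > 1,
                  logical(1))]
}

#' Log-transformed bee count with zero handling
#'
#' Bee counts are modelled on the log scale; zero counts are replaced by
#' half the smallest positive value before taking logs (flagged via the
#' `"bc_log_offset"` attribute).
#'
#' @param biodiversity A [build_biodiversity()] tibble.
#' @return The tibble with a `BC_log` column.
#' @export
add_bc_log <- function(biodiversity) {
  pos <- biodiversity$BC[biodiversity$BC > 0]
  if (!length(pos)) stop("all bee counts are zero", call. = FALSE)
  off <- min(pos) / 2
  out <- dplyr::mutate(biodiversity,
                       BC_log = log(ifelse(.data$BC > 0, .data$BC, off)))
  attr(out, "bc_log_offset") <- off
  out
}

#' Run one pipeline stage (or all of them)
#'
#' Stages, in order: `simulate` (synthetic landscape, traps, records),
#' `textures` (NDVI texture and roughness layers), `buffers` (zonal
#' predictor table), `diversity` (biodiversity responses), `screen`
#' (predictor screening), `fit` (all-subsets AIC model averaging per group
#' and response), `diag` (residual permutation correlograms). `all` runs
#' textures through diag. Every stage writes its artifacts plus a JSON
#' manifest (inputs, config hash, seed, package version) into
#' `cfg$outdir`; a stage whose upstream artifact is missing stops with a
#' message naming the stage to run first.
#'
#' @param stage One of `"simulate"`, `"textures"`, `"buffers"`,
#'   `"diversity"`, `"screen"`, `"fit"`, `"diag"`, `"all"`.
#' @param cfg A [run_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage = c("simulate", "textures", "buffers", "diversity",
                                "screen", "fit", "diag", "all"),
                      cfg = run_config()) {
  stage <- match.arg(stage)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("textures", "buffers", "diversity", "screen", "fit", "diag")) {
      run_stage(s, cfg)
    }
    return(invisible(cfg$outdir))
  }
  switch(stage,
         simulate = stage_simulate(cfg),
         textures = stage_textures(cfg),
         buffers = stage_buffers(cfg),
         diversity = stage_diversity(cfg),
         screen = stage_screen(cfg),
         fit = stage_fit(cfg),
         diag = stage_diag(cfg))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg = run_config()) {
  run_stage("simulate", cfg)
  run_stage("all", cfg)
}

stage_simulate <- function(cfg) {
  sim <- do.call(simulate_study,
                 c(cfg$simulate[setdiff(names(cfg$simulate),
                                        c("landscape", "community"))],
                   list(landscape = do.call(landscape_config,
                                            cfg$simulate$landscape %||% list()),
                        community = do.call(community_config,
                                            cfg$simulate$community %||% list()),
                        seed = cfg$seed)))
  write_raster(sim$ndvi, artifact(cfg, "ndvi.asc"))
  write_raster(sim$dem, artifact(cfg, "dem.asc"))
  utils::write.csv(sim$traps, artifact(cfg, "traps.csv"), row.names = FALSE)
  utils::write.csv(sim$records, artifact(cfg, "records.csv"), row.names = FALSE)
  write_manifest(cfg, "simulate", inputs = list(),
                 outputs = c("ndvi.asc", "dem.asc", "traps.csv", "records.csv"))
  invisible(artifact(cfg, c("ndvi.asc", "dem.asc", "traps.csv", "records.csv")))
}

stage_input <- function(cfg, key, file, produced_by) {
  cfg$paths[[key]] %||% require_artifact(cfg, file, produced_by)
}

stage_textures <- function(cfg) {
  ndvi_path <- stage_input(cfg, "ndvi", "ndvi.asc", "simulate")
  dem_path <- cfg$paths$dem %||% artifact(cfg, "dem.asc")
  ndvi <- read_raster(ndvi_path)
  dem <- if (file.exists(dem_path)) read_raster(dem_path) else NULL
  tx <- cfg$textures
  layers <- texture_layers(ndvi, dem, n_levels = tx$n_levels,
                           spec = texture_window(tx$window, tx$glcm_distance),
                           roughness_smoothing_window =
                             tx$roughness_smoothing_window)
  dir.create(artifact(cfg, "layers"), showWarnings = FALSE)
  outs <- character()
  for (nm in names(layers)) {
    p <- artifact(cfg, "layers", paste0(nm, ".asc"))
    write_raster(layers[[nm]], p)
    outs <- c(outs, p)
  }
  write_manifest(cfg, "textures", inputs = list(ndvi = ndvi_path,
                                                dem = dem_path),
                 outputs = basename(outs))
  invisible(outs)
}

stage_buffers <- function(cfg) {
  traps_path <- stage_input(cfg, "traps", "traps.csv", "simulate")
  layer_dir <- artifact(cfg, "layers")
  if (!dir.exists(layer_dir)) {
    stop("missing artifact 'layers/'; run stage 'textures' first", call. = FALSE)
  }
  traps <- read_trap_points(traps_path)
  files <- list.files(layer_dir, pattern = "\\.asc$", full.names = TRUE)
  layers <- stats::setNames(lapply(files, read_raster),
                            tools::file_path_sans_ext(basename(files)))
  pred <- assemble_predictors(traps, layers, radii = cfg$buffers$radii,
                              kind = cfg$buffers$kind)
  utils::write.csv(pred, artifact(cfg, "predictors.csv"), row.names = FALSE)
  write_manifest(cfg, "buffers",
                 inputs = list(traps = traps_path, layers = basename(files)),
                 outputs = "predictors.csv")
  invisible(artifact(cfg, "predictors.csv"))
}

stage_diversity <- function(cfg) {
  rec_path <- stage_input(cfg, "records", "records.csv", "simulate")
  biodiv <- add_bc_log(build_biodiversity(read_bee_records(rec_path)))
  utils::write.csv(biodiv, artifact(cfg, "biodiversity.csv"), row.names = FALSE)
  write_manifest(cfg, "diversity", inputs = list(records = rec_path),
                 outputs = "biodiversity.csv")
  invisible(artifact(cfg, "biodiversity.csv"))
}

stage_screen <- function(cfg) {
  pred_path <- require_artifact(cfg, "predictors.csv", "buffers")
  pred <- tibble::as_tibble(utils::read.csv(pred_path))
  bio_path <- require_artifact(cfg, "biodiversity.csv", "diversity")
  bio <- tibble::as_tibble(utils::read.csv(bio_path))
  # correlation pruning works at trap level; VIFs are computed on the
  # modelling rows (trap x year x season) with the control factors, as in
  # the full models they guard
  joined <- dplyr::inner_join(
    dplyr::filter(bio, .data$group == "nohb")[c("trap_id", "year", "season")],
    pred, by = "trap_id")
  sc <- cfg$screening
  res <- screen_predictors(pred, threshold = sc$threshold,
                           class_priority = sc$class_priority,
                           importance_ranking = sc$importance_ranking,
                           vif_data = joined,
                           sqrt_vif_threshold = sc$sqrt_vif_threshold,
                           max_vif_predictors = sc$max_vif_predictors)
  utils::write.csv(res$table, artifact(cfg, "predictors_screened.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kept_columns = res$report$kept_columns,
         dropped_columns = res$report$dropped_columns,
         thresholds = res$report$thresholds),
    artifact(cfg, "screening.json"), auto_unbox = TRUE, pretty = TRUE)
  write_manifest(cfg, "screen", inputs = list(predictors = pred_path),
                 outputs = c("predictors_screened.csv", "screening.json"))
  invisible(artifact(cfg, "predictors_screened.csv"))
}

fit_joined_data <- function(cfg) {
  pred <- tibble::as_tibble(utils::read.csv(
    require_artifact(cfg, "predictors_screened.csv", "screen")))
  biodiv <- tibble::as_tibble(utils::read.csv(
    require_artifact(cfg, "biodiversity.csv", "diversity")))
  # all-subsets enumeration is exponential in the menu size; cap it at the
  # leading screened columns (the study design never used more than six)
  tests <- utils::head(predictor_columns(pred),
                       cfg$modelling$max_predictors %||% 6)
  list(pred = pred, biodiv = biodiv, tests = tests)
}

stage_fit <- function(cfg) {
  dat <- fit_joined_data(cfg)
  pred_scaled <- scale_predictors(dat$pred, dat$tests)
  results <- list(); glances <- list(); cands <- list()
  for (g in unique(dat$biodiv$group)) {
    joined <- dplyr::inner_join(dplyr::filter(dat$biodiv, .data$group == g),
                                pred_scaled, by = "trap_id")
    controls <- usable_controls(joined)
    for (resp in cfg$modelling$responses) {
      fit <- fit_texture_model(joined, resp, dat$tests, controls,
                               delta_threshold = cfg$modelling$delta_threshold)
      results[[paste(g, resp)]] <- dplyr::mutate(tidy(fit), group = g,
                                                 .before = 1)
      glances[[paste(g, resp)]] <- dplyr::mutate(glance(fit), group = g,
                                                 .before = 1)
      cands[[paste(g, resp)]] <- dplyr::mutate(tidy(fit$candidates),
                                               group = g, response = resp,
                                               .before = 1)
    }
  }
  utils::write.csv(dplyr::bind_rows(results), artifact(cfg, "model_results.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(glances), artifact(cfg, "model_r2.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(cands), artifact(cfg, "model_candidates.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "fit",
                 inputs = c("predictors_screened.csv", "biodiversity.csv"),
                 outputs = c("model_results.csv", "model_r2.csv",
                             "model_candidates.csv"))
  invisible(artifact(cfg, "model_results.csv"))
}

stage_diag <- function(cfg) {
  dat <- fit_joined_data(cfg)
  traps <- read_trap_points(stage_input(cfg, "traps", "traps.csv", "simulate"))
  pred_scaled <- scale_predictors(dat$pred, dat$tests)
  dg <- cfg$diagnostics
  out <- list()
  for (g in unique(dat$biodiv$group)) {
    joined <- dplyr::inner_join(dplyr::filter(dat$biodiv, .data$group == g),
                                pred_scaled, by = "trap_id")
    controls <- usable_controls(joined)
    for (resp in cfg$modelling$responses) {
      data <- prepare_model_data(joined, controls)
      fit <- stats::lm(stats::reformulate(c(controls, dat$tests),
                                          response = resp), data = data)
      res_by_trap <- tibble::tibble(trap_id = data$trap_id,
                                    res = stats::residuals(fit)) |>
        dplyr::group_by(.data$trap_id) |>
        dplyr::summarise(res = mean(.data$res))
      res_by_trap <- dplyr::inner_join(res_by_trap, traps, by = "trap_id")
      cg <- residual_correlogram(res_by_trap$res, res_by_trap,
                                 bin_width = dg$bin_width, n_perm = dg$n_perm,
                                 seed = cfg$seed,
                                 max_distance = dg$max_distance)
      out[[paste(g, resp)]] <- dplyr::mutate(cg$bins, group = g,
                                             response = resp, .before = 1)
    }
  }
  utils::write.csv(dplyr::bind_rows(out), artifact(cfg, "correlograms.csv"),
                   row.names = FALSE)
  write_manifest(cfg, "diag",
                 inputs = c("predictors_screened.csv", "biodiversity.csv",
                            "traps.csv"),
                 outputs = "correlograms.csv")
  invisible(artifact(cfg, "correlograms.csv"))
}
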