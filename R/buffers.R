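#' Build distance-class buffers around trap points
#'
#' With `kind = "annulus"` the first buffer is the 0 to `radii[1]` disk and
#' each subsequent buffer is the `(r[k-1], r[k]]` ring, so the distance
#' classes partition the largest disk. With `kind = "disk"` the buffers are
#' nested disks of each radius.
#'
#' @param points Tibble/data frame with columns `trap_id`, `x`, `y` (and
#'   typically `site`), coordinates in metres.
#' @param radii Strictly increasing positive radii in metres.
#' @param kind `"annulus"` or `"disk"`.
#' @return A tibble with one row per trap x distance class: `trap_id`,
#'   `distance_class` (the outer radius), `r_inner`, `r_outer`, `kind`.
#' @export
build_buffers <- function(points, radii, kind = c("annulus", "disk")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(points), all(c("trap_id", "x", "y") %in% names(points)))
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("`radii` must be positive and strictly increasing", call. = FALSE)
  }
  inner <- if (kind == "annulus") c(0, utils::head(radii, -1)) else rep(0, length(radii))
  tidyr::crossing(trap_id = points$trap_id,
                  tibble::tibble(distance_class = radii, r_inner = inner,
                                 r_outer = radii)) |>
    dplyr::mutate(kind = kind) |>
    dplyr::left_join(dplyr::select(points, "trap_id", "x", "y"), by = "trap_id")
}

# distances from every cell center of `layer` to (x0, y0); returns the cell
# values inside the buffer geometry (cell-center membership, no partial areas)
cells_in_buffer <- function(layer, x0, y0, r_inner, r_outer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values); px <- layer$pixel_size
  cx <- layer$origin[1] + (seq_len(nc) - 0.5) * px
  cy <- layer$origin[2] - (seq_len(nr) - 0.5) * px
  # restrict to the bounding box of the outer circle before computing distances
  jj <- which(cx >= x0 - r_outer - px & cx <= x0 + r_outer + px)
  ii <- which(cy >= y0 - r_outer - px & cy <= y0 + r_outer + px)
  if (!length(ii) || !length(jj)) return(numeric(0))
  d2 <- outer((cy[ii] - y0)^2, (cx[jj] - x0)^2, `+`)
  v <- layer$values[ii, jj, drop = FALSE]
  inside <- d2 <= r_outer^2 & (r_inner == 0 | d2 > r_inner^2)
  v[inside & !is.na(v)]
}

#' Summarize a raster layer within one buffer
#'
#' Statistics over all non-nodata cells whose *center* falls inside the
#' buffer geometry. `sd` is the sample standard deviation; `cv = sd / mean`
#' and is `NA` (undefined) when `abs(mean)` is below `mean_tol`.
#'
#' @param layer A [raster_grid()].
#' @param x,y Buffer center in map coordinates (metres).
#' @param r_inner,r_outer Ring radii, `0 <= r_inner < r_outer`.
#' @param stats Subset of `c("mean", "sd", "cv")`.
#' @param mean_tol Threshold below which the CV denominator is considered
#'   zero (default 1e-9).
#' @param trap_id Optional label used in the empty-zone error message.
#' @return Named list of the requested statistics.
#' @export
zonal_summary <- function(layer, x, y, r_inner, r_outer,
                          stats = c("mean", "sd", "cv"), mean_tol = 1e-9,
                          trap_id = "?") {
  stopifnot(is_raster_grid(layer), r_inner >= 0, r_inner < r_outer)
  stats <- match.arg(stats, several.ok = TRUE)
  v <- cells_in_buffer(layer, x, y, r_inner, r_outer)
  if (!length(v)) {
    stop(sprintf("empty zone: no valid cells for trap %s in buffer %g-%g m",
                 trap_id, r_inner, r_outer), call. = FALSE)
  }
  m <- mean(v)
  s <- if (length(v) > 1) stats::sd(v) else 0
  out <- list(mean = m, sd = s,
              cv = if (abs(m) < mean_tol) NA_real_ else s / m,
              n_cells = length(v))
  out[c(stats, "n_cells")]
}

#' Assemble the predictor table
#'
#' Crosses every raster layer with every distance class and summary
#' statistic, one row per trap. Columns are named
#' `<metric>_<summary>_<distance_class>` (e.g. `ent1_mean_100`,
#' `rough_sd_300`), except the vegetation-index layer named `NDVI`, which
#' contributes `NDVI_mean_*` and `NDVI_cv_*` (the paper-style mean and
#' coefficient of variation). Layers may sit on different native grids
#' (e.g. 30 m NDVI textures and a 10 m DEM roughness); each is summarized
#' in its own resolution within the same metric buffer geometry.
#'
#' @param points Tibble with `trap_id`, `x`, `y`, `site`.
#' @param layers Named list of [raster_grid()] layers.
#' @param radii Distance classes in metres (default `seq(100, 1000, 100)`).
#' @param kind Buffer geometry, `"annulus"` (default) or `"disk"`.
#' @param ndvi_layer Name of the layer summarized as mean + CV
#'   (default `"NDVI"`); all other layers get mean + SD.
#' @return A tibble, one row per trap: `trap_id`, `site`, then the predictor
#'   columns in deterministic (layer, summary, radius) order. The cell
#'   counts per (layer, trap, class) are attached as attribute
#'   `"provenance"`.
#' @export
assemble_predictors <- function(points, layers, radii = seq(100, 1000, by = 100),
                                kind = c("annulus", "disk"),
                                ndvi_layer = "NDVI") {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(points), length(names(layers)) == length(layers))
  buffers <- build_buffers(points, radii, kind)
  prov <- list()
  cols <- list()
  for (lname in names(layers)) {
    layer <- layers[[lname]]
    stats <- if (identical(lname, ndvi_layer)) c("mean", "cv") else c("mean", "sd")
    for (k in seq_along(radii)) {
      b <- buffers[buffers$distance_class == radii[k], ]
      vals <- purrr::pmap(list(b$x, b$y, b$r_inner, b$r_outer, b$trap_id),
                          function(x, y, ri, ro, id) {
                            zonal_summary(layer, x, y, ri, ro, stats = stats,
                                          trap_id = id)
                          })
      for (s in stats) {
        cols[[paste(lname, s, radii[k], sep = "_")]] <-
          purrr::map_dbl(vals, s)
      }
      prov[[length(prov) + 1]] <- tibble::tibble(
        layer = lname, distance_class = radii[k], trap_id = b$trap_id,
        n_cells = purrr::map_int(vals, ~ as.integer(.x$n_cells)))
    }
  }
  out <- dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(points), dplyr::any_of(c("trap_id", "site"))),
    tibble::as_tibble(cols))
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

#' Parse predictor column names
#'
#' Splits `<metric>_<summary>_<radius>` from the right, so metric names may
#' themselves contain underscores.
#'
#' @param cols Character vector of predictor column names.
#' @return Tibble with `column`, `metric`, `summary`, `distance_class`.
#' @export
parse_predictor_names <- function(cols) {
  parts <- strsplit(cols, "_")
  tibble::tibble(
    column = cols,
    metric = purrr::map_chr(parts, ~ paste(utils::head(.x, -2), collapse = "_")),
    summary = purrr::map_chr(parts, ~ .x[length(.x) - 1]),
    distance_class = purrr::map_dbl(parts, ~ suppressWarnings(as.numeric(.x[length(.x)])))
  )
}

#' Predictor columns of a table
#'
#' Every column that is not an identifier or control
#' (`trap_id`, `site`, `year`, `season`).
#'
#' @param table Predictor tibble.
#' @param controls Columns to exclude.
#' @return Character vector of predictor column names.
#' @export
predictor_columns <- function(table, controls = c("trap_id", "site", "year", "season")) {
  setdiff(names(table), controls)
}
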