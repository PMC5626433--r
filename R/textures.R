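#' Normalized Difference Vegetation Index
#'
#' Per-cell `(NIR - RED) / (NIR + RED)`. Cells where either band is nodata,
#' or where the band sum is zero (undefined ratio), become nodata.
#'
#' @param red,nir Aligned [raster_grid()] objects holding the red and
#'   near-infrared bands (reflectance or radiance; the ratio is unitless).
#' @return A [raster_grid()] with values in `[-1, 1]`.
#' @export
compute_ndvi <- function(red, nir) {
  stopifnot(is_raster_grid(red), is_raster_grid(nir))
  check_aligned(red, nir, "red and nir bands")
  s <- nir$values + red$values
  out <- (nir$values - red$values) / s
  out[!is.na(s) & s == 0] <- NA
  with_values(red, out)
}

#' Texture window specification
#'
#' Bundles the moving-window parameters shared by the occurrence and
#' co-occurrence texture layers: an odd window size (default 3x3 pixels),
#' the inter-pixel distance of the co-occurrence offsets (default 1), and
#' the edge policy (cells whose window is incomplete become nodata; no
#' padding is ever used). Co-occurrence statistics are always averaged over
#' the four standard angles (0, 45, 90, 135 degrees).
#'
#' @param window_size Odd integer >= 3, in pixels.
#' @param glcm_distance Inter-pixel distance in pixels (>= 1).
#' @return A `texture_window_spec` list.
#' @export
texture_window <- function(window_size = 3, glcm_distance = 1) {
  if (window_size < 3 || window_size %% 2 != 1) {
    stop("`window_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (glcm_distance < 1) stop("`glcm_distance` must be >= 1", call. = FALSE)
  structure(list(window_size = as.integer(window_size),
                 glcm_distance = as.integer(glcm_distance),
                 edge_policy = "nodata_at_border"),
            class = "texture_window_spec")
}

check_window_fits <- function(q, spec) {
  if (spec$window_size > min(dim(q$levels))) {
    stop(sprintf("window (%d) larger than raster (%d x %d)",
                 spec$window_size, nrow(q$levels), ncol(q$levels)),
         call. = FALSE)
  }
}

#' First-order (occurrence) texture layers
#'
#' Statistics of the grey-level histogram `P(i)` within the moving window:
#' mean `sum(i P(i))`, entropy `-sum(P(i) ln P(i))` (with `0 ln 0 = 0`),
#' evenness `entropy / ln(Ng)` where `Ng` is the number of *distinct* levels
#' present in the window (evenness is 1 for single-level windows), and
#' variance `sum((i - M)^2 P(i))` around the window mean `M`.
#'
#' @param q A [quantize()]d raster.
#' @param spec A [texture_window()].
#' @return A named list of four [raster_grid()] layers:
#'   `mean`, `entropy`, `evenness`, `variance`.
#' @export
firstorder_textures <- function(q, spec = texture_window()) {
  stopifnot(inherits(q, "quantized_raster"))
  check_window_fits(q, spec)
  res <- cpp_firstorder(q$levels, spec$window_size, q$n_levels)
  lapply(res, function(m) with_values(q, m))
}

#' Grey-level co-occurrence (GLCM) texture layers
#'
#' For each window and each of the four angles, the symmetric normalized
#' co-occurrence matrix `P(i, j)` is built from all pixel pairs at the
#' angle's offset that lie inside the window (each pair counted in both
#' directions). From it: contrast `sum P(i,j) (i-j)^2`, dissimilarity
#' `sum P(i,j) |i-j|`, entropy `-sum P(i,j) ln P(i,j)`, homogeneity
#' `sum P(i,j) / (1 + (i-j)^2)`. The reported value is the arithmetic mean
#' over the four angles; an angle with zero valid pairs in a window is
#' excluded from that window's mean.
#'
#' @inheritParams firstorder_textures
#' @return A named list of four [raster_grid()] layers:
#'   `contrast`, `dissimilarity`, `entropy`, `homogeneity`.
#' @export
glcm_textures <- function(q, spec = texture_window()) {
  stopifnot(inherits(q, "quantized_raster"))
  check_window_fits(q, spec)
  res <- cpp_glcm(q$levels, spec$window_size, spec$glcm_distance, q$n_levels)
  lapply(res, function(m) with_values(q, m))
}

#' Terrain roughness (ruggedness) of a DEM
#'
#' Per-cell ruggedness is the square root of the summed squared elevation
#' differences between the cell and its eight neighbours,
#' `sqrt(sum((x_ij - x_00)^2))`. The per-cell values are then averaged over
#' a moving smoothing window (default 9x9 cells). Cells whose neighbourhood
#' or smoothing window is incomplete, or touches nodata, become nodata.
#'
#' @param dem A [raster_grid()] of elevations in metres.
#' @param smoothing_window Odd integer; `1` skips smoothing.
#' @return A [raster_grid()] of roughness values (metres, >= 0).
#' @export
terrain_roughness <- function(dem, smoothing_window = 9) {
  stopifnot(is_raster_grid(dem))
  if (smoothing_window %% 2 != 1 || smoothing_window < 1) {
    stop("`smoothing_window` must be a positive odd integer", call. = FALSE)
  }
  rug <- cpp_ruggedness(dem$values)
  if (smoothing_window > 1) rug <- cpp_boxmean(rug, as.integer(smoothing_window))
  with_values(dem, rug)
}

#' All texture layers used by the heterogeneity analysis
#'
#' Convenience wrapper producing the named layer set that downstream zonal
#' summaries expect: the NDVI itself (`NDVI`), four first-order layers
#' (`mean1`, `ent1`, `even1`, `var1`), four co-occurrence layers (`con2`,
#' `dis2`, `ent2`, `hom2`), and, when a DEM is supplied, terrain roughness
#' (`rough`, computed in the DEM's native resolution).
#'
#' @param ndvi A [raster_grid()] NDVI layer.
#' @param dem Optional [raster_grid()] DEM (may have a different resolution).
#' @param n_levels Grey levels for quantization (default 32).
#' @param spec A [texture_window()].
#' @param roughness_smoothing_window Odd integer, default 9.
#' @return A named list of [raster_grid()] layers.
#' @export
texture_layers <- function(ndvi, dem = NULL, n_levels = 32,
                           spec = texture_window(),
                           roughness_smoothing_window = 9) {
  q <- quantize(ndvi, n_levels = n_levels)
  fo <- firstorder_textures(q, spec)
  so <- glcm_textures(q, spec)
  layers <- list(NDVI = ndvi,
                 mean1 = fo$mean, ent1 = fo$entropy,
                 even1 = fo$evenness, var1 = fo$variance,
                 con2 = so$contrast, dis2 = so$dissimilarity,
                 ent2 = so$entropy, hom2 = so$homogeneity)
  if (!is.null(dem)) {
    layers$rough <- terrain_roughness(dem, roughness_smoothing_window)
  }
  layers
}
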