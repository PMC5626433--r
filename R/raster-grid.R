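#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus the georeference needed
#' to place cell centers in projected map coordinates. Nodata is encoded as
#' `NA`. The coordinate system must be projected (metric units) so that
#' buffer radii expressed in metres are meaningful.
#'
#' @param values Numeric matrix; rows run north to south, columns west to
#'   east. `NA` marks nodata.
#' @param origin Length-2 numeric, map coordinates `(x, y)` of the
#'   *upper-left corner* of the grid.
#' @param pixel_size Cell edge length in metres (square pixels).
#' @param crs Free-text identifier of the projected CRS (e.g.
#'   `"ETRS89/UTM32N"`). Carried as metadata only.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), pixel_size = 1,
                        crs = "local-metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(length(origin) == 2, is.finite(origin))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size), crs = crs),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, %g m pixels, origin (%g, %g), crs %s\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2], x$crs))
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Map coordinates of all cell centers
#'
#' @param raster A [raster_grid()].
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
raster_cells <- function(raster) {
  stopifnot(is_raster_grid(raster))
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  tibble::tibble(
    row = rows, col = cols,
    x = raster$origin[1] + (cols - 0.5) * raster$pixel_size,
    y = raster$origin[2] - (rows - 0.5) * raster$pixel_size,
    value = as.vector(raster$values)
  )
}

# same shape, origin, pixel size (and CRS label)
check_aligned <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)) ||
      any(abs(a$origin - b$origin) > 1e-9) ||
      abs(a$pixel_size - b$pixel_size) > 1e-12 ||
      !identical(a$crs, b$crs)) {
    stop(sprintf("%s are not aligned (shape, origin, pixel size and CRS must match)",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

# carry georeference of `template` onto a new values matrix
with_values <- function(template, values) {
  raster_grid(values, origin = template$origin,
              pixel_size = template$pixel_size, crs = template$crs)
}

#' Quantize a raster into equal-width grey-level bins
#'
#' Linear binning of the non-nodata values into `n_levels` equal-width bins,
#' the prerequisite of the occurrence / co-occurrence texture statistics.
#' Under `range_policy = "global_minmax"` the bin range is the scene's global
#' min-max; a constant raster then maps every cell to level 0. Under
#' `"fixed_range"` the range is supplied (values outside it are clamped to
#' the extreme bins). The maximum value of the range maps to level
#' `n_levels - 1`.
#'
#' @param raster A [raster_grid()].
#' @param n_levels Number of grey levels (>= 2).
#' @param range_policy `"global_minmax"` or `"fixed_range"`.
#' @param range Length-2 numeric, required for `"fixed_range"`.
#' @return An object of class `quantized_raster` with fields `levels`
#'   (integer matrix, levels in `0:(n_levels-1)`, `NA` = nodata), `n_levels`,
#'   `bin_edges`, and the source georeference.
#' @export
quantize <- function(raster, n_levels = 32,
                     range_policy = c("global_minmax", "fixed_range"),
                     range = NULL) {
  stopifnot(is_raster_grid(raster))
  range_policy <- match.arg(range_policy)
  if (!is.numeric(n_levels) || length(n_levels) != 1 || n_levels < 2) {
    stop("`n_levels` must be a single integer >= 2", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  v <- raster$values
  if (range_policy == "global_minmax") {
    rng <- range(v, na.rm = TRUE)
  } else {
    if (is.null(range) || length(range) != 2 || range[1] >= range[2]) {
      stop("`fixed_range` needs `range = c(lo, hi)` with lo < hi", call. = FALSE)
    }
    rng <- as.numeric(range)
  }
  edges <- seq(rng[1], rng[2], length.out = n_levels + 1)
  if (rng[1] == rng[2]) {
    # degenerate (constant) raster: everything level 0
    lev <- ifelse(is.na(v), NA_integer_, 0L)
    edges <- c(rng[1], rng[1] + seq_len(n_levels) * .Machine$double.eps)
  } else {
    scaled <- (v - rng[1]) / (rng[2] - rng[1]) * n_levels
    lev <- pmin(pmax(floor(scaled), 0), n_levels - 1)
    lev[is.na(v)] <- NA
    storage.mode(lev) <- "integer"
  }
  lev <- matrix(as.integer(lev), nrow = nrow(v))
  structure(
    list(levels = lev, n_levels = n_levels, bin_edges = edges,
         origin = raster$origin, pixel_size = raster$pixel_size,
         crs = raster$crs),
    class = "quantized_raster"
  )
}

#' @export
print.quantized_raster <- function(x, ...) {
  cat(sprintf("<quantized_raster> %d x %d cells, %d grey levels\n",
              nrow(x$levels), ncol(x$levels), x$n_levels))
  invisible(x)
}
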