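#' Read and write rasters
#'
#' Two plain on-disk representations are supported. ESRI ASCII grid
#' (`.asc`) carries its own georeference in the header and is read and
#' written directly. TIFF (`.tif`/`.tiff`, via the `tiff` package) stores
#' the pixel values; the georeference travels in a JSON sidecar
#' (`<file>.geo.json`) with fields `origin`, `pixel_size`, `crs`.
#'
#' @param path File path; format chosen by extension.
#' @param raster A [raster_grid()] (for writing).
#' @param crs CRS label attached on read (`.asc` has no CRS field).
#' @return [raster_grid()] for `read_raster()`; the path, invisibly, for
#'   `write_raster()`.
#' @export
read_raster <- function(path, crs = "local-metric") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") return(read_raster_asc(path, crs))
  if (ext %in% c("tif", "tiff")) return(read_raster_tiff(path, crs))
  stop("unsupported raster format: .", ext, call. = FALSE)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  stopifnot(is_raster_grid(raster))
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") return(write_raster_asc(raster, path))
  if (ext %in% c("tif", "tiff")) return(write_raster_tiff(raster, path))
  stop("unsupported raster format: .", ext, call. = FALSE)
}

read_raster_asc <- function(path, crs = "local-metric") {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- hdr[["nrows"]]; nc <- hdr[["ncols"]]
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(hdr["nodata_value"])) m[m == hdr[["nodata_value"]]] <- NA
  # asc origin is the lower-left corner
  cell <- hdr[["cellsize"]]
  raster_grid(m, origin = c(hdr[["xllcorner"]], hdr[["yllcorner"]] + nr * cell),
              pixel_size = cell, crs = crs)
}

write_raster_asc <- function(raster, path, nodata = -9999) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2] - nr * raster$pixel_size),
           sprintf("cellsize %.10g", raster$pixel_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE,
                                                 digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".geo.json")

# the tiff package stores floats in [0, 1]; values are normalized on write
# (value_min/value_max kept in the sidecar) and nodata encoded as 0 below a
# 0.25 valid floor
read_raster_tiff <- function(path, crs = "local-metric") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF rasters", call. = FALSE)
  }
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  geo <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list(origin = c(0, nrow(m)), pixel_size = 1, crs = crs)
  if (!is.null(geo$value_min)) {
    na <- m < 0.125
    m <- (m - 0.25) / 0.75 * (geo$value_max - geo$value_min) + geo$value_min
    m[na] <- NA
  }
  raster_grid(m, origin = unlist(geo$origin), pixel_size = geo$pixel_size,
              crs = geo$crs %||% crs)
}

write_raster_tiff <- function(raster, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF rasters", call. = FALSE)
  }
  v <- raster$values
  vmin <- min(v, na.rm = TRUE); vmax <- max(v, na.rm = TRUE)
  span <- max(vmax - vmin, .Machine$double.eps)
  norm <- 0.25 + 0.75 * (v - vmin) / span
  norm[is.na(v)] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32)
  jsonlite::write_json(list(origin = raster$origin,
                            pixel_size = raster$pixel_size, crs = raster$crs,
                            value_min = vmin, value_max = vmax),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trap locations and trap records
#'
#' Thin CSV readers with schema checks: trap points need
#' `trap_id,x,y,site`; records need
#' `trap_id,year,season,species,count,trapping_days` with
#' `season` in `early`/`late`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_trap_points <- function(path) {
  pts <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("trap_id", "x", "y", "site")
  if (!all(need %in% names(pts))) {
    stop("trap points CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pts$trap_id)) stop("duplicate trap_id values", call. = FALSE)
  pts
}

#' @rdname read_trap_points
#' @export
read_bee_records <- function(path) {
  rec <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("trap_id", "year", "season", "species", "count", "trapping_days")
  if (!all(need %in% names(rec))) {
    stop("records CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(rec$season %in% c("early", "late"))) {
    stop("`season` must be 'early' or 'late'", call. = FALSE)
  }
  if (any(rec$count < 0) || any(rec$trapping_days <= 0)) {
    stop("counts must be >= 0 and trapping_days > 0", call. = FALSE)
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
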