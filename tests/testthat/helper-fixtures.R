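# small in-code fixtures shared across test files

# raster from a matrix given by rows, default 1 m pixels at origin (0, nrow)
rg <- function(m, pixel = 1) {
  m <- as.matrix(m)
  raster_grid(m, origin = c(0, nrow(m) * pixel), pixel_size = pixel)
}

# quantized raster straight from an integer level matrix
qr_fixture <- function(lev, n_levels = max(lev, na.rm = TRUE) + 1L) {
  lev <- as.matrix(lev)
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 bin_edges = seq(0, n_levels, by = 1),
                 origin = c(0, nrow(lev)), pixel_size = 1, crs = "local"),
            class = "quantized_raster")
}

# toy bee records: two traps, one year, both seasons
toy_records <- function() {
  tibble::tibble(
    trap_id = rep(c("t1", "t2"), each = 4),
    year = 2011L,
    season = rep(c("early", "early", "late", "late"), 2),
    species = c("Bombus terrestris", "Andrena flavipes",
                "Bombus terrestris", "Apis mellifera",
                "Andrena flavipes", "Lasioglossum morio",
                "Bombus lapidarius", "Andrena flavipes"),
    count = c(3L, 2L, 4L, 9L, 5L, 1L, 2L, 2L),
    trapping_days = 42.5)
}

# predictor table with an exact sample correlation between two columns:
# x2 = r * x1 + sqrt(1 - r^2) * e with x1, e empirically orthonormal
exact_corr_pair <- function(n = 40, r = 0.9, seed = 1) {
  set.seed(seed)
  z <- qr.Q(qr(cbind(1, stats::rnorm(n), stats::rnorm(n))))[, 2:3] * sqrt(n - 1)
  tibble::tibble(x1 = z[, 1], x2 = r * z[, 1] + sqrt(1 - r^2) * z[, 2])
}
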