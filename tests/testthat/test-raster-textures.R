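test_that("NDVI follows the band ratio and flags undefined cells", {
  red <- rg(matrix(c(0.1, 0.3, 0.2, 0.0), 2))
  nir <- rg(matrix(c(0.5, 0.3, NA, 0.0), 2))
  ndvi <- compute_ndvi(red, nir)
  expect_equal(ndvi$values[1, 1], 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(ndvi$values[2, 1], 0)          # equal bands
  expect_true(is.na(ndvi$values[1, 2]))       # nodata input
  expect_true(is.na(ndvi$values[2, 2]))       # zero band sum
  expect_true(all(abs(ndvi$values) <= 1, na.rm = TRUE))
})

test_that("NDVI refuses misaligned bands", {
  a <- rg(matrix(0.1, 2, 2))
  b <- raster_grid(matrix(0.2, 2, 2), origin = c(5, 2), pixel_size = 1)
  expect_error(compute_ndvi(a, b), "aligned")
})

test_that("quantization bins linearly and handles degenerate ranges", {
  r <- rg(matrix(c(0, 0.5, 1, NA), 2))
  q <- quantize(r, n_levels = 2, range_policy = "fixed_range", range = c(0, 1))
  expect_equal(sort(q$levels[!is.na(q$levels)]), c(0L, 1L, 1L))
  expect_equal(q$bin_edges, c(0, 0.5, 1))
  expect_true(is.na(q$levels[2, 2]))

  const <- quantize(rg(matrix(2.5, 3, 3)), n_levels = 8)
  expect_true(all(const$levels == 0L))

  expect_error(quantize(r, n_levels = 1), "n_levels")
})

test_that("first-order window statistics match hand-computed histograms", {
  # all cells one level: no disorder
  fo <- firstorder_textures(qr_fixture(matrix(2L, 3, 3), 4))
  expect_equal(fo$entropy$values[2, 2], 0)
  expect_equal(fo$variance$values[2, 2], 0)
  expect_equal(fo$evenness$values[2, 2], 1)
  expect_equal(fo$mean$values[2, 2], 2)

  # 4 cells of one level, 5 of another
  lev <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 1), 3)
  fo <- firstorder_textures(qr_fixture(lev, 2))
  expect_equal(fo$entropy$values[2, 2],
               -(4 / 9) * log(4 / 9) - (5 / 9) * log(5 / 9),
               tolerance = 1e-12)
  expect_equal(fo$mean$values[2, 2], 5 / 9, tolerance = 1e-12)

  # uniform over the levels present: evenness 1, entropy ln k
  lev3 <- matrix(rep(0:2, each = 3), 3)
  fo <- firstorder_textures(qr_fixture(lev3, 3))
  expect_equal(fo$entropy$values[2, 2], log(3), tolerance = 1e-12)
  expect_equal(fo$evenness$values[2, 2], 1, tolerance = 1e-12)
  # two levels at equal frequency (one corner nodata pads 9 to 8 cells)
  lev2 <- matrix(c(NA, 0, 0, 0, 0, 1, 1, 1, 1), 3)
  fo <- firstorder_textures(qr_fixture(lev2, 2))
  expect_equal(fo$entropy$values[2, 2], log(2), tolerance = 1e-12)
  expect_equal(fo$evenness$values[2, 2], 1, tolerance = 1e-12)

  # border cells have no complete window
  fo <- firstorder_textures(qr_fixture(matrix(0:8, 3), 9))
  expect_true(all(is.na(fo$mean$values[c(1, 3), ])))
  expect_error(firstorder_textures(qr_fixture(matrix(0L, 2, 2), 2)),
               "larger than raster")
})

test_that("pair-enumeration reference reproduces hand-computed GLCM values", {
  lev <- matrix(c(0, 0, 2, 0, 1, 2, 1, 1, 2), 3)  # rows [[0,0,1],[0,1,1],[2,2,2]]
  ref0 <- glcm_reference(lev, angles = 0)
  expect_equal(ref0$contrast, 1 / 3, tolerance = 1e-12)
  expect_equal(ref0$homogeneity, 5 / 6, tolerance = 1e-12)

  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(glcm_reference(checker, angles = 0)$contrast, 1, tolerance = 1e-12)
})

test_that("windowed GLCM equals the enumeration reference and behaves at degenerate windows", {
  so <- glcm_textures(qr_fixture(matrix(3L, 3, 3), 5))
  expect_equal(so$contrast$values[2, 2], 0)
  expect_equal(so$dissimilarity$values[2, 2], 0)
  expect_equal(so$entropy$values[2, 2], 0)
  expect_equal(so$homogeneity$values[2, 2], 1)

  res <- glcm_oracle_experiment(n_windows = 100, seed = 7)
  expect_true(all(res$abs_error < 1e-12))
  expect_true(all(res$windowed[res$statistic == "homogeneity"] > 0))
  expect_true(all(res$windowed[res$statistic == "homogeneity"] <= 1 + 1e-12))
  expect_true(all(res$windowed[res$statistic != "homogeneity"] >= -1e-12))
})

test_that("difference-based GLCM statistics are invariant to level relabelling by a constant", {
  set.seed(3)
  lev <- matrix(sample(0:3, 25, replace = TRUE), 5)
  a <- glcm_textures(qr_fixture(lev, 4), texture_window(5))
  b <- glcm_textures(qr_fixture(lev + 2L, 8), texture_window(5))
  ctr <- c(3, 3)
  for (s in c("contrast", "dissimilarity", "homogeneity", "entropy")) {
    expect_equal(a[[s]]$values[3, 3], b[[s]]$values[3, 3], tolerance = 1e-12)
  }
})

test_that("terrain roughness matches the neighbour-difference formula", {
  flat <- terrain_roughness(rg(matrix(5, 11, 11)), smoothing_window = 9)
  expect_equal(flat$values[6, 6], 0)

  bump <- matrix(0, 3, 3); bump[2, 2] <- 1
  r1 <- terrain_roughness(rg(bump), smoothing_window = 1)
  expect_equal(r1$values[2, 2], sqrt(8), tolerance = 1e-12)

  # tilted plane: constant slope => constant roughness away from borders
  plane <- outer(1:15, 1:15, function(i, j) 2 * i + 0.5 * j)
  rr <- terrain_roughness(rg(plane), smoothing_window = 3)
  inner <- rr$values[3:13, 3:13]
  expect_lt(diff(range(inner)), 1e-9)
  expect_true(all(rr$values >= 0, na.rm = TRUE))
})
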