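test_that("community splitting drops honeybees and partitions by genus", {
  g <- split_groups(toy_records())
  expect_false(any(g$nohb$species == "Apis mellifera"))
  expect_true(all(startsWith(g$bb$species, "Bombus")))
  expect_false(any(startsWith(g$sb$species, "Bombus")))
  # conservation: nohb = bb + sb
  expect_equal(sum(g$nohb$count), sum(g$bb$count) + sum(g$sb$count))

  empty <- split_groups(toy_records()[0, ])
  expect_equal(vapply(empty, nrow, integer(1)), c(bb = 0L, sb = 0L, nohb = 0L))

  apis_only <- dplyr::mutate(toy_records(), species = "Apis mellifera")
  expect_equal(vapply(split_groups(apis_only), nrow, integer(1)),
               c(bb = 0L, sb = 0L, nohb = 0L))
})

test_that("normalized count divides by trapping effort", {
  expect_equal(normalized_count(85, 42.5), 2)
  expect_equal(normalized_count(0, 10), 0)
  expect_error(normalized_count(5, 0), "trapping_days")
})

test_that("Shannon diversity matches closed forms and vegan", {
  expect_equal(shannon_diversity(c(10, 10, 10, 10)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(7)), 0)
  expect_equal(shannon_diversity(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_true(is.na(shannon_diversity(integer(0))))
  # maximal for even communities, invariant to relabeling
  set.seed(1)
  x <- rmultinom(1, 200, rep(1 / 6, 6))[, 1]
  expect_lte(shannon_diversity(x), log(6))
  expect_equal(shannon_diversity(x), shannon_diversity(rev(x)))
  skip_if_not_installed("vegan")
  y <- c(12, 5, 3, 1, 1)
  expect_equal(shannon_diversity(y),
               unname(vegan::diversity(y, index = "shannon")),
               tolerance = 1e-12)
})

test_that("rarefied richness follows the hypergeometric closed form", {
  # X = (2,1,1), n = 4, m = 2: 3 - [C(2,2) + 2 C(3,2)] / C(4,2) = 11/6
  expect_equal(rarefied_richness(c(2, 1, 1), 2), 11 / 6, tolerance = 1e-12)
  # identity at the full sample and the one-individual floor
  x <- c(5, 3, 2, 1, 1)
  expect_equal(rarefied_richness(x, sum(x)), 5, tolerance = 1e-12)
  expect_equal(rarefied_richness(x, 1), 1, tolerance = 1e-12)
  expect_error(rarefied_richness(x, 0), "m_target")
  expect_error(rarefied_richness(c(0, 0), 3), "empty")
})

test_that("rarefaction curve is monotone, concave, and extrapolates to the Chao1 limit", {
  set.seed(42)
  x <- as.vector(rmultinom(1, 60, exp(rnorm(25, 0, 1.2))))
  x <- x[x > 0]
  n <- sum(x)
  curve <- vapply(1:n, function(m) rarefied_richness(x, m), numeric(1))
  expect_true(all(diff(curve) > -1e-12))
  expect_true(all(diff(diff(curve)) < 1e-9))       # concave interpolation
  expect_equal(curve[n], length(x), tolerance = 1e-9)

  f1 <- sum(x == 1); f2 <- sum(x == 2)
  f0 <- (n - 1) / n * (if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2)
  far <- rarefied_richness(x, 100 * n)
  expect_lt(far, length(x) + f0 + 1e-6)
  expect_gt(far, rarefied_richness(x, 2 * n))

  # no singletons: extrapolation returns the observed richness
  expect_equal(rarefied_richness(c(4, 2, 2), 20), 3)
})

test_that("interpolated richness agrees with vegan's rarefy", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:5) {
    x <- as.vector(rmultinom(1, 80, exp(rnorm(15, 0, 1))))
    x <- x[x > 0]
    m <- sample(seq_len(sum(x)), 1)
    expect_equal(rarefied_richness(x, m),
                 as.numeric(suppressWarnings(vegan::rarefy(x, sample = m))),
                 tolerance = 1e-8)
  }
})

test_that("the dataset standardization target is a rounded multiple of the minimum abundance", {
  expect_equal(dataset_m_target(c(12, 40, 7)), 21L)
  expect_equal(dataset_m_target(10), 30L)
  expect_equal(dataset_m_target(c(0, 5, 9)), 15L)
  expect_error(dataset_m_target(c(0, 0)), "empty")
})

test_that("the biodiversity table aggregates records per trap, season and group", {
  bio <- build_biodiversity(toy_records())
  expect_setequal(unique(bio$group), c("bb", "sb", "nohb"))
  nohb <- dplyr::filter(bio, group == "nohb")
  t1_early <- dplyr::filter(nohb, trap_id == "t1", season == "early")
  expect_equal(t1_early$n, 5L)           # Apis removed from the 14 caught
  expect_equal(t1_early$BC, 5 / 42.5)
  expect_equal(t1_early$s_obs, 2L)
  # conservation of totals across the split
  tot <- bio |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = sum(n))
  expect_equal(tot$n[tot$group == "nohb"],
               tot$n[tot$group == "bb"] + tot$n[tot$group == "sb"])
})

test_that("season correlation recovers a known correlation and degenerate cases", {
  make_tbl <- function(early, late) {
    k <- length(early)
    tibble::tibble(trap_id = rep(sprintf("t%d", 1:k), 2),
                   year = 2011L,
                   season = rep(c("early", "late"), each = k),
                   BC = c(early, late))
  }
  v <- c(1, 3, 2, 5, 4)
  expect_equal(season_correlation(make_tbl(v, v))$estimate, 1, tolerance = 1e-12)
  expect_equal(season_correlation(make_tbl(v, -v))$estimate, -1, tolerance = 1e-12)
  expect_error(season_correlation(make_tbl(v[1:2], v[1:2])), "3")

  set.seed(11)
  n <- 500; rho <- 0.4
  e <- rnorm(n); l <- rho * e + sqrt(1 - rho^2) * rnorm(n)
  r <- season_correlation(make_tbl(e, l))
  expect_lt(abs(r$estimate - 0.4), 0.1)
  expect_equal(r$n_pairs, n)
})
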