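# two-variable predictor table where v's classes have controlled correlation
make_class_table <- function(n = 60, r12 = 0.9, seed = 1) {
  set.seed(seed)
  z <- qr.Q(qr(cbind(1, rnorm(n), rnorm(n))))[, 2:3] * sqrt(n - 1)
  tibble::tibble(trap_id = sprintf("t%02d", 1:n),
                 v_mean_100 = z[, 1],
                 v_mean_200 = r12 * z[, 1] + sqrt(1 - r12^2) * z[, 2])
}

test_that("distance-class pruning applies the correlation threshold per variable", {
  hi <- make_class_table(r12 = 0.9)
  rep_hi <- prune_distance_classes(hi)
  expect_equal(rep_hi$kept_columns, "v_mean_100")
  expect_equal(rep_hi$dropped_columns$reason, "class_correlated")

  lo <- make_class_table(r12 = 0.5)
  rep_lo <- prune_distance_classes(lo)
  expect_setequal(rep_lo$kept_columns, c("v_mean_100", "v_mean_200"))

  # all classes mutually correlated collapse to the top-priority class
  t3 <- simulate_correlated_classes(n_rows = 300, variables = "v_mean",
                                    classes = c(100, 200, 300),
                                    adjacent_correlation = 0.97, seed = 2)
  rep3 <- prune_distance_classes(t3)
  expect_equal(rep3$kept_columns, "v_mean_100")

  # constant column dropped with its own reason
  cc <- dplyr::mutate(lo, w_mean_100 = 1)
  rep_cc <- prune_distance_classes(cc)
  expect_true("w_mean_100" %in% rep_cc$dropped_columns$column)
  expect_equal(
    rep_cc$dropped_columns$reason[rep_cc$dropped_columns$column == "w_mean_100"],
    "constant")
})

test_that("between-variable pruning drops the less important member of each pair", {
  pair <- exact_corr_pair(n = 50, r = 0.8)
  tab <- tibble::tibble(trap_id = sprintf("t%02d", 1:50),
                        A_mean_100 = pair$x1, B_mean_100 = pair$x2)
  rep1 <- prune_variables(tab, importance_ranking = c("A_mean", "B_mean"))
  expect_equal(rep1$kept_columns, "A_mean_100")
  # reversed ranking reverses the drop
  rep1r <- prune_variables(tab, importance_ranking = c("B_mean", "A_mean"))
  expect_equal(rep1r$kept_columns, "B_mean_100")

  # uncorrelated pair: identity
  tab_lo <- tibble::tibble(trap_id = tab$trap_id,
                           A_mean_100 = pair$x1,
                           B_mean_100 = 0.3 * pair$x1 +
                             sqrt(1 - 0.09) * (pair$x2 - 0.8 * pair$x1) / 0.6)
  rep2 <- prune_variables(tab_lo, importance_ranking = c("A_mean", "B_mean"))
  expect_setequal(rep2$kept_columns, c("A_mean_100", "B_mean_100"))

  expect_error(prune_variables(tab, importance_ranking = "A_mean"), "lacks")
})

test_that("a correlation chain drops every lower-ranked member", {
  # A ~ B and B ~ C strongly; A ~ C weaker than the threshold
  set.seed(5)
  n <- 400
  a <- rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(n)
  c_ <- 0.8 * b + sqrt(1 - 0.64) * rnorm(n)
  stopifnot(abs(cor(a, c_)) < 0.7, cor(a, b) > 0.7, cor(b, c_) > 0.7)
  tab <- tibble::tibble(trap_id = sprintf("t%03d", 1:n),
                        A_mean_100 = a, B_mean_100 = b, C_mean_100 = c_)
  rep <- prune_variables(tab, importance_ranking = c("A_mean", "B_mean", "C_mean"))
  expect_equal(rep$kept_columns, "A_mean_100")
  expect_setequal(rep$dropped_columns$column, c("B_mean_100", "C_mean_100"))
})

test_that("VIF filtering matches the closed form and car::vif", {
  pair <- exact_corr_pair(n = 40, r = 0.9)
  tab <- tibble::tibble(trap_id = sprintf("t%02d", 1:40),
                        x1_mean_100 = pair$x1, x2_mean_100 = pair$x2)
  # before removal both VIFs are 1 / (1 - 0.81)
  expect_equal(abs(cor(pair$x1, pair$x2)), 0.9, tolerance = 1e-10)
  rep <- vif_filter(tab, controls = character(0))
  expect_equal(nrow(rep$dropped_columns), 1)
  expect_equal(rep$dropped_columns$reason, "vif")

  skip_if_not_installed("car")
  set.seed(9)
  d <- tibble::tibble(y = rnorm(40), a = pair$x1, b = pair$x2)
  v_car <- car::vif(lm(y ~ a + b, data = d))
  expect_equal(unname(v_car["a"]), 1 / (1 - 0.81), tolerance = 1e-8)

  # orthogonal predictors: VIF 1, nothing removed
  orth <- tibble::tibble(trap_id = tab$trap_id,
                         o1_mean_100 = pair$x1,
                         o2_mean_100 = (pair$x2 - 0.9 * pair$x1) / sqrt(0.19))
  rep_o <- vif_filter(orth, controls = character(0))
  expect_equal(nrow(rep_o$dropped_columns), 0)
  expect_equal(unname(attr(rep_o, "vif")), c(1, 1), tolerance = 1e-10)

  dup <- dplyr::mutate(tab, x3_mean_100 = x1_mean_100)
  expect_error(vif_filter(dup, controls = character(0)), "rank-deficient")
})

test_that("retained predictors all satisfy the sqrt-VIF bound and screening is idempotent", {
  tab <- simulate_correlated_classes(n_rows = 200,
                                     variables = c("p_mean", "q_mean", "r_mean"),
                                     classes = c(100, 200, 300),
                                     adjacent_correlation = 0.8, seed = 3)
  res <- screen_predictors(tab, importance_ranking = c("p_mean", "q_mean", "r_mean"))
  vifs <- attr(res$report, "vif")
  expect_true(all(sqrt(vifs) <= 2))
  res2 <- screen_predictors(res$table,
                            importance_ranking = c("p_mean", "q_mean", "r_mean"))
  expect_equal(sort(names(res2$table)), sort(names(res$table)))
  expect_equal(nrow(res2$report$dropped_columns), 0)
})

test_that("AR(1)-correlated classes with extremes-first priority retain exactly 100 and 1000", {
  tab <- simulate_correlated_classes(seed = 4)
  rep <- prune_distance_classes(tab)
  info <- parse_predictor_names(rep$kept_columns)
  for (v in unique(info$metric)) {
    expect_setequal(info$distance_class[info$metric == v], c(100, 1000))
  }
})
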