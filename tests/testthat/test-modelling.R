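# small modelling dataset with controls and two test predictors
make_model_data <- function(n_trap = 12, beta1 = 0, beta2 = 0, sigma = 1,
                            seed = 1) {
  set.seed(seed)
  base <- tibble::tibble(trap_id = sprintf("t%02d", 1:n_trap),
                         site = rep(c("A", "B"), length.out = n_trap),
                         x1 = rnorm(n_trap), x2 = rnorm(n_trap))
  d <- tidyr::crossing(base, year = 2010:2011, season = c("early", "late"))
  d$y <- beta1 * d$x1 + beta2 * d$x2 +
    0.5 * (d$site == "B") + 0.3 * (d$season == "late") +
    0.2 * (d$year == 2011) + rnorm(nrow(d), 0, sigma)
  d
}

test_that("predictor scaling gives exact z-scores and is idempotent", {
  tab <- tibble::tibble(trap_id = c("a", "b", "c"), p_mean_100 = c(1, 2, 3))
  s <- scale_predictors(tab)
  expect_equal(s$p_mean_100, c(-1, 0, 1))
  s2 <- scale_predictors(s)
  expect_equal(s2$p_mean_100, s$p_mean_100, tolerance = 1e-12)
  expect_equal(attr(s, "scaling")$sd, 1)
  expect_error(scale_predictors(dplyr::mutate(tab, q_mean_100 = 5)), "constant")
})

test_that("all-subsets enumeration has the right size and matches a refit oracle", {
  d <- make_model_data(beta1 = 1, seed = 2)
  cand <- fit_all_subsets(d, "y", c("x1", "x2"))
  expect_equal(nrow(cand$candidates), 4)

  null_only <- fit_all_subsets(d, "y", character(0))
  expect_equal(nrow(null_only$candidates), 1)
  expect_equal(null_only$candidates$weight, 1)

  # independent oracle: explicit formulas + stats::AIC, p = 3 predictors
  d3 <- dplyr::mutate(d, x3 = rnorm(nrow(d)))
  cand3 <- fit_all_subsets(d3, "y", c("x1", "x2", "x3"))
  subsets <- lapply(0:7, function(id) c("x1", "x2", "x3")[bitwAnd(id, c(1, 2, 4)) > 0])
  oracle <- vapply(subsets, function(s) {
    f <- reformulate(c("site", "year", "season", s), response = "y")
    stats::AIC(lm(f, data = dplyr::mutate(d3, year = factor(year))))
  }, numeric(1))
  got <- cand3$candidates$AIC[order(cand3$candidates$model_id)]
  expect_equal(got, oracle, tolerance = 1e-9)

  # dominant simulated effect is selected
  strong <- make_model_data(beta1 = 2, sigma = 1, seed = 3)
  best <- fit_all_subsets(strong, "y", c("x1", "x2"))$candidates$terms[[1]]
  expect_true("x1" %in% best)

  dup <- dplyr::mutate(d, x2 = x1)
  expect_error(fit_all_subsets(dup, "y", c("x1", "x2")), "rank-deficient")
})

test_that("Akaike weights sum to one and the top set renormalizes as the closed form", {
  d <- make_model_data(seed = 4)
  cand <- fit_all_subsets(d, "y", c("x1", "x2"))
  expect_equal(sum(cand$candidates$weight), 1, tolerance = 1e-12)
  top <- top_set(cand, 2)
  expect_equal(sum(top$candidates$weight), 1, tolerance = 1e-12)
  expect_true(all(top$candidates$delta_aic <= 2))

  # two models at delta AIC 0 and 2: weights 1/(1+e^-1) and e^-1/(1+e^-1)
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(w, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(w[1], 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("model averaging reduces to hand computations", {
  d <- make_model_data(beta1 = 5, sigma = 0.5, seed = 5)
  cand <- fit_all_subsets(d, "y", c("x1", "x2"))
  single <- cand
  single$candidates <- cand$candidates[1, ]
  single$candidates$weight <- 1
  single$fits <- cand$fits[1]
  avg1 <- model_average(single)
  f1 <- cand$fits[[1]]
  for (tm in intersect(cand$candidates$terms[[1]], c("x1", "x2"))) {
    row <- avg1$coefficients[avg1$coefficients$term == tm, ]
    expect_equal(row$estimate, unname(coef(f1)[tm]), tolerance = 1e-12)
    expect_equal(row$sd, unname(sqrt(diag(vcov(f1))[tm])), tolerance = 1e-12)
    expect_equal(row$importance, 1)
  }

  # two-model hand oracle on the full average
  two <- cand
  two$candidates <- cand$candidates[1:2, ]
  two$candidates$weight <- two$candidates$weight / sum(two$candidates$weight)
  two$fits <- cand$fits[1:2]
  avg2 <- model_average(two)
  w <- two$candidates$weight
  for (tm in c("x1", "x2")) {
    b <- vapply(1:2, function(i) {
      if (tm %in% two$candidates$terms[[i]]) unname(coef(two$fits[[i]])[tm]) else 0
    }, numeric(1))
    v <- vapply(1:2, function(i) {
      if (tm %in% two$candidates$terms[[i]]) unname(diag(vcov(two$fits[[i]]))[tm]) else 0
    }, numeric(1))
    est <- sum(w * b)
    row <- avg2$coefficients[avg2$coefficients$term == tm, ]
    expect_equal(row$estimate, est, tolerance = 1e-12)
    expect_equal(row$sd, sqrt(sum(w * (v + (b - est)^2))), tolerance = 1e-12)
    expect_equal(row$importance, sum(w[vapply(two$candidates$terms,
                                              function(s) tm %in% s,
                                              logical(1))]),
                 tolerance = 1e-12)
  }

  # a predictor absent from every averaged model gets estimate 0, importance 0
  no_x2 <- cand
  keep <- !vapply(cand$candidates$terms, function(s) "x2" %in% s, logical(1))
  no_x2$candidates <- cand$candidates[keep, ]
  no_x2$candidates$weight <- no_x2$candidates$weight / sum(no_x2$candidates$weight)
  no_x2$fits <- cand$fits[keep]
  avg0 <- model_average(no_x2)
  row <- avg0$coefficients[avg0$coefficients$term == "x2", ]
  expect_equal(row$estimate, 0)
  expect_equal(row$importance, 0)
})

test_that("AICc correction and conditional averaging behave as documented", {
  d <- make_model_data(beta1 = 0.4, seed = 14)
  cand <- fit_all_subsets(d, "y", c("x1", "x2"))
  candc <- fit_all_subsets(d, "y", c("x1", "x2"), ic = "AICc")
  n <- nrow(d)
  ord <- order(cand$candidates$model_id); ordc <- order(candc$candidates$model_id)
  k <- cand$candidates$k[ord]
  expect_equal(candc$candidates$AIC[ordc],
               cand$candidates$AIC[ord] + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)

  top <- top_set(cand, 2)
  full <- model_average(top, mode = "full")
  cond <- model_average(top, mode = "conditional")
  for (tm in c("x1", "x2")) {
    fr <- full$coefficients[full$coefficients$term == tm, ]
    cr <- cond$coefficients[cond$coefficients$term == tm, ]
    expect_equal(fr$importance, cr$importance)
    if (fr$importance > 0 && fr$importance < 1) {
      # conditional estimates are the full ones un-shrunk by importance
      expect_equal(cr$estimate, fr$estimate / fr$importance, tolerance = 1e-9)
    }
  }
})

test_that("likelihood-ratio tests detect strong effects and degenerate to p = 1", {
  strong <- make_model_data(beta1 = 2, sigma = 0.5, seed = 6)
  p <- lrt_pvalues(strong, "y", c("x1", "x2"))
  expect_lt(p$p.value[p$term == "x1"], 0.001)

  # a no-information predictor leaves the likelihood unchanged: deviance 0, p = 1
  d <- make_model_data(seed = 7)
  d$x_dup <- 0 * d$x1
  p0 <- lrt_pvalues(d, "y", c("x1", "x_dup"))
  expect_equal(p0$statistic[p0$term == "x_dup"], 0, tolerance = 1e-9)
  expect_equal(p0$p.value[p0$term == "x_dup"], 1, tolerance = 1e-9)
})

test_that("LRT p-values are close to uniform under the null", {
  set.seed(8)
  reps <- 300
  pvals <- numeric(reps)
  base <- make_model_data(seed = 9)
  for (i in seq_len(reps)) {
    base$y <- rnorm(nrow(base))
    base$x1 <- rnorm(nrow(base))
    pvals[i] <- lrt_pvalues(base, "y", "x1")$p.value
  }
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("global-versus-null R2 behaves at the extremes", {
  d <- make_model_data(seed = 10)
  d$y_ctrl <- 0.5 * (d$site == "B") + 0.3 * (d$season == "late")
  r <- suppressWarnings(r2_comparison(d, "y_ctrl", c("x1", "x2")))
  expect_equal(r$r2_null, 1, tolerance = 1e-9)
  expect_equal(r$r2_global, 1, tolerance = 1e-9)
  expect_gte(r$delta_r2 + 1e-12, 0)

  strong <- make_model_data(beta1 = 2, sigma = 0.5, seed = 11)
  r2 <- r2_comparison(strong, "y", c("x1", "x2"))
  expect_gt(r2$delta_r2, 0.3)

  noise <- make_model_data(seed = 12)
  r3 <- r2_comparison(noise, "y", c("x1", "x2"))
  expect_lt(r3$delta_r2, 0.15)
  expect_gte(r3$delta_r2, 0)
})

test_that("the fitted model object exposes tidy and glance summaries", {
  d <- make_model_data(beta1 = 1, seed = 13)
  fit <- fit_texture_model(d, "y", c("x1", "x2"))
  td <- tidy(fit)
  expect_setequal(td$term, c("x1", "x2"))
  expect_true(all(c("estimate", "sd", "importance", "p.value") %in% names(td)))
  expect_true(all(td$importance >= 0 & td$importance <= 1))
  gl <- glance(fit)
  expect_true(all(c("r2_global", "r2_null", "delta_r2", "n_model") %in% names(gl)))
  expect_gte(gl$delta_r2, 0)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
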