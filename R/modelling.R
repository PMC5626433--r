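#' Scale test predictors to zero mean and unit SD
#'
#' Centering/scaling makes averaged coefficients comparable across
#' predictors ("relative effects"). Control columns are untouched; the
#' scaling parameters are stored in attribute `"scaling"` for the inverse
#' transform.
#'
#' @param table Predictor tibble.
#' @param cols Columns to scale; defaults to every non-control column.
#' @return The table with scaled predictor columns.
#' @export
scale_predictors <- function(table, cols = predictor_columns(table)) {
  mus <- vapply(cols, function(cc) mean(table[[cc]]), numeric(1))
  sds <- vapply(cols, function(cc) stats::sd(table[[cc]]), numeric(1))
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  for (cc in cols) table[[cc]] <- (table[[cc]] - mus[cc]) / sds[cc]
  attr(table, "scaling") <- tibble::tibble(column = cols, mean = unname(mus),
                                           sd = unname(sds))
  table
}

prepare_model_data <- function(data, controls) {
  dplyr::mutate(tibble::as_tibble(data),
                dplyr::across(dplyr::all_of(controls), as.factor))
}

check_full_rank <- function(formula, data) {
  X <- stats::model.matrix(formula, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
}

#' Fit all subsets of the test predictors
#'
#' Fits the `2^p` ordinary-least-squares models formed by every subset of
#' the `p` test predictors, always keeping the control factors, and ranks
#' them by AIC (`-2 logLik + 2k`, `k` counting the residual variance).
#' Ordering is deterministic: by AIC, ties broken by subset enumeration
#' order.
#'
#' @param data Tibble holding the response, scaled test predictors and
#'   control columns (one row per trap x year x season observation).
#' @param response Response column name (e.g. `"BC_log"`, `"SD"`, `"SpR"`).
#' @param test_predictors Character vector of test predictor columns.
#' @param controls Character vector of control factor columns
#'   (default `c("site", "year", "season")` intersected with the data).
#' @param ic Information criterion, `"AIC"` (default) or `"AICc"` (the
#'   small-sample correction `AIC + 2k(k+1)/(n-k-1)`).
#' @return An object of class `candidate_set`: a list with `candidates`
#'   (tibble: `model_id`, `terms` list-column, `k`, `logLik`, `AIC`,
#'   `delta_aic`, `weight`), the fitted `lm` objects, and the model spec.
#' @export
fit_all_subsets <- function(data, response, test_predictors,
                            controls = intersect(c("site", "year", "season"),
                                                 names(data)),
                            ic = c("AIC", "AICc")) {
  ic <- match.arg(ic)
  data <- prepare_model_data(data, controls)
  p <- length(test_predictors)
  global_rhs <- c(controls, test_predictors)
  global_formula <- stats::reformulate(if (length(global_rhs)) global_rhs else "1",
                                       response = response)
  check_full_rank(global_formula, data)
  subsets <- lapply(seq_len(2^p) - 1L, function(id) {
    test_predictors[bitwAnd(id, bitwShiftL(1L, seq_len(p) - 1L)) > 0]
  })
  fits <- lapply(subsets, function(terms) {
    rhs <- c(controls, terms)
    stats::lm(stats::reformulate(if (length(rhs)) rhs else "1",
                                 response = response), data = data)
  })
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  k <- vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1))
  aic <- -2 * ll + 2 * k
  if (ic == "AICc") aic <- aic + 2 * k * (k + 1) / (nrow(data) - k - 1)
  ord <- order(aic, seq_along(aic))
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  cand <- tibble::tibble(
    model_id = (seq_len(2^p) - 1L)[ord],
    terms = subsets[ord],
    k = k[ord], logLik = ll[ord], AIC = aic[ord],
    delta_aic = delta[ord], weight = w[ord])
  structure(list(candidates = cand, fits = fits[ord], response = response,
                 test_predictors = test_predictors, controls = controls,
                 data = data),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d models for %s (%d test predictors)\n",
              nrow(x$candidates), x$response, length(x$test_predictors)))
  print(dplyr::select(x$candidates, -"terms"), n = 5)
  invisible(x)
}

#' Restrict a candidate set to the AIC top set
#'
#' Keeps the models with `delta_aic <= delta_threshold` and renormalizes
#' the Akaike weights within the retained set.
#'
#' @param candidates A [fit_all_subsets()] result.
#' @param delta_threshold AIC difference cut-off (default 2).
#' @return A `candidate_set` restricted to the top models.
#' @export
top_set <- function(candidates, delta_threshold = 2) {
  stopifnot(inherits(candidates, "candidate_set"))
  keep <- candidates$candidates$delta_aic <= delta_threshold
  out <- candidates
  out$candidates <- candidates$candidates[keep, ]
  out$candidates$weight <- out$candidates$weight / sum(out$candidates$weight)
  out$fits <- candidates$fits[keep]
  out
}

#' Model-averaged estimates over a candidate set
#'
#' Full (zero-substitution) averaging: a predictor absent from a model
#' contributes a coefficient of 0 (with zero variance) to the weighted
#' average, shrinking weakly supported effects towards zero. The
#' unconditional standard deviation combines within-model variance and
#' between-model spread,
#' `sqrt(sum_i w_i (var_ij + (beta_ij - est_j)^2))`. Relative importance is
#' the summed weight of the models containing the predictor.
#'
#' @param top A (typically [top_set()]-restricted) `candidate_set`.
#' @param mode `"full"` (default, zero-substitution) or `"conditional"`
#'   (average only over the models containing the predictor, with weights
#'   renormalized by its importance; no shrinkage).
#' @return An object of class `averaged_model` with a per-predictor tibble
#'   (`term`, `estimate`, `sd`, `importance`) and `n_model`.
#' @export
model_average <- function(top, mode = c("full", "conditional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(top, "candidate_set"))
  w <- top$candidates$weight
  terms <- top$candidates$terms
  est <- sd2 <- imp <- stats::setNames(numeric(length(top$test_predictors)),
                                       top$test_predictors)
  beta <- vars <- matrix(0, nrow(top$candidates), length(top$test_predictors),
                         dimnames = list(NULL, top$test_predictors))
  for (i in seq_along(top$fits)) {
    f <- top$fits[[i]]
    cf <- stats::coef(f); vc <- diag(stats::vcov(f))
    for (tm in terms[[i]]) {
      beta[i, tm] <- cf[[tm]]
      vars[i, tm] <- vc[[tm]]
      imp[tm] <- imp[tm] + w[i]
    }
  }
  has <- vapply(top$test_predictors, function(tm) {
    vapply(terms, function(s) tm %in% s, logical(1))
  }, logical(length(terms)))
  has <- matrix(has, nrow = length(terms),
                dimnames = list(NULL, top$test_predictors))
  for (tm in top$test_predictors) {
    wt <- if (mode == "full") w else {
      if (imp[tm] == 0) w * 0 else w * has[, tm] / imp[tm]
    }
    est[tm] <- sum(wt * beta[, tm])
    sd2[tm] <- sum(wt * (vars[, tm] + (beta[, tm] - est[tm])^2))
  }
  structure(list(
    coefficients = tibble::tibble(term = top$test_predictors,
                                  estimate = unname(est),
                                  sd = sqrt(unname(sd2)),
                                  importance = unname(imp)),
    n_model = nrow(top$candidates), response = top$response),
    class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> %s, averaged over %d models\n",
              x$response, x$n_model))
  print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio p-values for the test predictors
#'
#' Each test predictor is tested by comparing the global model to the model
#' without that predictor: deviance `2 (logLik_full - logLik_reduced)`
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @inheritParams fit_all_subsets
#' @return Tibble with `term`, `statistic`, `p.value`.
#' @export
lrt_pvalues <- function(data, response, test_predictors,
                        controls = intersect(c("site", "year", "season"),
                                             names(data))) {
  data <- prepare_model_data(data, controls)
  fit_ll <- function(terms) {
    rhs <- c(controls, terms)
    as.numeric(stats::logLik(stats::lm(
      stats::reformulate(if (length(rhs)) rhs else "1", response = response),
      data = data)))
  }
  ll_full <- fit_ll(test_predictors)
  purrr::map_dfr(test_predictors, function(tm) {
    dev <- 2 * (ll_full - fit_ll(setdiff(test_predictors, tm)))
    tibble::tibble(term = tm, statistic = dev,
                   p.value = stats::pchisq(pmax(dev, 0), df = 1,
                                           lower.tail = FALSE))
  })
}

#' Global-versus-null coefficient of determination
#'
#' R-squared of the global model (controls plus all retained test
#' predictors) and of the null model (controls only); their difference is
#' the variance share attributable to the heterogeneity predictors.
#'
#' @inheritParams fit_all_subsets
#' @return Tibble with `r2_global`, `r2_null`, `delta_r2`.
#' @export
r2_comparison <- function(data, response, test_predictors,
                          controls = intersect(c("site", "year", "season"),
                                               names(data))) {
  data <- prepare_model_data(data, controls)
  r2 <- function(terms) {
    rhs <- c(controls, terms)
    summary(stats::lm(stats::reformulate(if (length(rhs)) rhs else "1",
                                         response = response),
                      data = data))$r.squared
  }
  g <- r2(test_predictors); n <- r2(character(0))
  tibble::tibble(r2_global = g, r2_null = n, delta_r2 = g - n)
}

#' Fit the full texture-biodiversity model for one response
#'
#' End-to-end modelling for one response and dataset: all-subsets OLS with
#' control factors, AIC top-set (`delta_aic <= delta_threshold`) model
#' averaging, likelihood-ratio p-values and the global-versus-null
#' R-squared comparison — the per-response block of the results table.
#'
#' @inheritParams fit_all_subsets
#' @inheritParams model_average
#' @param delta_threshold AIC top-set cut-off (default 2).
#' @return Object of class `bee_texture_model` with elements `averaged`
#'   (coefficients tibble incl. `p.value`), `candidates`, `top`, `r2`,
#'   `response`.
#' @export
fit_texture_model <- function(data, response, test_predictors,
                              controls = intersect(c("site", "year", "season"),
                                                   names(data)),
                              delta_threshold = 2, ic = "AIC", mode = "full") {
  cand <- fit_all_subsets(data, response, test_predictors, controls, ic = ic)
  top <- top_set(cand, delta_threshold)
  avg <- model_average(top, mode = mode)
  lrt <- lrt_pvalues(data, response, test_predictors, controls)
  r2 <- r2_comparison(data, response, test_predictors, controls)
  coefs <- dplyr::left_join(avg$coefficients,
                            dplyr::select(lrt, "term", "p.value"), by = "term")
  structure(list(averaged = coefs, candidates = cand, top = top,
                 n_model = avg$n_model, r2 = r2, response = response,
                 test_predictors = test_predictors, controls = controls),
            class = "bee_texture_model")
}

#' @export
print.bee_texture_model <- function(x, ...) {
  cat(sprintf("<bee_texture_model> response %s, %d models averaged\n",
              x$response, x$n_model))
  print(x$averaged)
  cat(sprintf("R2 global %.3f, null %.3f, delta %.3f\n",
              x$r2$r2_global, x$r2$r2_null, x$r2$delta_r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.averaged_model <- function(x, ...) x$coefficients

#' @export
tidy.bee_texture_model <- function(x, ...) {
  dplyr::mutate(x$averaged, response = x$response, .before = 1)
}

#' @export
glance.bee_texture_model <- function(x, ...) {
  dplyr::mutate(x$r2, n_model = x$n_model, response = x$response, .before = 1)
}

#' @export
tidy.candidate_set <- function(x, ...) {
  dplyr::mutate(dplyr::select(x$candidates, -"terms"),
                terms = purrr::map_chr(x$candidates$terms, paste, collapse = "+"),
                .after = "model_id")
}
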