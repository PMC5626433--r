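#' Screening report
#'
#' Shared result container of the three screening steps: which predictor
#' columns were kept, which were dropped and why.
#'
#' @param kept Character vector of kept columns.
#' @param dropped Tibble with columns `column`, `reason`.
#' @param thresholds Named list of the thresholds used.
#' @return An object of class `screening_report`.
#' @keywords internal
screening_report <- function(kept, dropped, thresholds) {
  if (!all(c("column", "reason") %in% names(dropped))) {
    dropped <- tibble::tibble(column = character(0), reason = character(0))
  }
  structure(list(kept_columns = kept, dropped_columns = dropped,
                 thresholds = thresholds),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d kept, %d dropped\n",
              length(x$kept_columns), nrow(x$dropped_columns)))
  if (nrow(x$dropped_columns)) print(dplyr::count(x$dropped_columns, .data$reason))
  invisible(x)
}

#' Apply a screening report to a predictor table
#' @param table Predictor tibble.
#' @param report A `screening_report`.
#' @return The table restricted to kept predictor columns (control columns
#'   untouched).
#' @export
apply_screening <- function(table, report) {
  drop <- report$dropped_columns$column
  dplyr::select(table, -dplyr::all_of(intersect(drop, names(table))))
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Prune correlated distance classes within each variable
#'
#' For every variable (metric x summary combination), classes are retained
#' greedily in `class_priority` order: a class is dropped when its absolute
#' Pearson correlation with an already-kept class of the same variable
#' exceeds `threshold`. A variable whose classes are all mutually
#' correlated collapses to its single top-priority class. Constant columns
#' (undefined correlation) are dropped with their own reason.
#'
#' @param table Predictor tibble (control columns `trap_id`, `site`,
#'   `year`, `season` are ignored).
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @param class_priority Distance classes in decreasing retention priority;
#'   default puts the extremes first: 100, 1000, then 500, 200, ...
#' @return A `screening_report`.
#' @export
prune_distance_classes <- function(table, threshold = 0.7,
                                   class_priority = c(100, 1000, 500, 200, 300,
                                                      400, 600, 700, 800, 900)) {
  cols <- predictor_columns(table)
  info <- parse_predictor_names(cols)
  kept <- character(); dropped <- list()
  for (v in unique(paste(info$metric, info$summary, sep = "_"))) {
    vi <- info[paste(info$metric, info$summary, sep = "_") == v, ]
    ord <- order(match(vi$distance_class, class_priority,
                       nomatch = length(class_priority) + 1), vi$distance_class)
    vi <- vi[ord, ]
    v_kept <- character()
    for (col in vi$column) {
      x <- table[[col]]
      if (stats::sd(x) == 0) {
        dropped[[col]] <- "constant"
        next
      }
      r <- vapply(v_kept, function(k) abs(safe_cor(x, table[[k]])), numeric(1))
      if (length(r) && any(r > threshold, na.rm = TRUE)) {
        dropped[[col]] <- "class_correlated"
      } else {
        v_kept <- c(v_kept, col)
      }
    }
    kept <- c(kept, v_kept)
  }
  screening_report(kept,
                   tibble::tibble(column = names(dropped),
                                  reason = unlist(dropped, use.names = FALSE)),
                   list(correlation_threshold = threshold))
}

#' Prune correlated variables by biological importance
#'
#' Among the remaining predictor columns, every pair with absolute Pearson
#' correlation above `threshold` loses its less important member, where
#' importance is the user-supplied ranking of variables (metric x summary),
#' most important first. The rule is applied to all correlated pairs, so a
#' correlation chain A~B~C under ranking (A, B, C) drops both B and C.
#'
#' @inheritParams prune_distance_classes
#' @param importance_ranking Character vector of variable names
#'   (`<metric>_<summary>`), most important first; must cover every
#'   remaining variable.
#' @return A `screening_report`.
#' @export
prune_variables <- function(table, threshold = 0.7, importance_ranking) {
  cols <- predictor_columns(table)
  info <- parse_predictor_names(cols)
  vars <- paste(info$metric, info$summary, sep = "_")
  missing <- setdiff(unique(vars), importance_ranking)
  if (length(missing)) {
    stop("`importance_ranking` lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rank <- match(vars, importance_ranking)
  drop <- rep(FALSE, length(cols))
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (i == j) next
      r <- safe_cor(table[[cols[i]]], table[[cols[j]]])
      if (!is.na(r) && abs(r) > threshold) {
        # lower-ranked (larger rank number) member of the pair is dropped;
        # ties broken towards the later column for determinism
        if (rank[i] > rank[j] || (rank[i] == rank[j] && i > j)) drop[i] <- TRUE
      }
    }
  }
  screening_report(cols[!drop],
                   tibble::tibble(column = cols[drop],
                                  reason = rep("variable_correlated", sum(drop))),
                   list(correlation_threshold = threshold))
}

# R^2 of regressing column `target` on the remaining design columns
aux_r2 <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  1 - rss / tss
}

#' Variance-inflation-factor filter
#'
#' The VIF of each test predictor is `1 / (1 - R^2)` from regressing it on
#' all other test predictors plus the dummy-coded control factors. While
#' any predictor has `sqrt(VIF)` above the threshold, the worst offender is
#' removed and the VIFs recomputed. Controls are never removable.
#'
#' @param table Predictor tibble including control columns.
#' @param controls Control factor columns entering every auxiliary
#'   regression (default `c("site")`, plus `year`/`season` when present).
#' @param sqrt_vif_threshold Threshold on `sqrt(VIF)` (default 2).
#' @return A `screening_report`; the final VIFs of the kept predictors are
#'   attached as attribute `"vif"`.
#' @export
vif_filter <- function(table, controls = intersect(c("site", "year", "season"),
                                                   names(table)),
                       sqrt_vif_threshold = 2) {
  cols <- predictor_columns(table)
  X_ctrl <- if (length(controls)) {
    stats::model.matrix(stats::reformulate(controls), data =
                          dplyr::mutate(table, dplyr::across(dplyr::all_of(controls),
                                                             as.factor)))[, -1, drop = FALSE]
  } else NULL
  dropped <- character()
  repeat {
    active <- setdiff(cols, dropped)
    X_all <- cbind(as.matrix(table[active]), X_ctrl)
    qrX <- qr(cbind(1, X_all))
    if (qrX$rank < ncol(X_all) + 1) {
      aliased <- colnames(X_all)[qrX$pivot[-seq_len(qrX$rank)] - 1]
      stop("rank-deficient design; aliased columns: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    vifs <- vapply(active, function(col) {
      others <- setdiff(active, col)
      X <- cbind(as.matrix(table[others]), X_ctrl)
      1 / (1 - aux_r2(table[[col]], X))
    }, numeric(1))
    if (!length(vifs) || all(sqrt(vifs) <= sqrt_vif_threshold)) break
    dropped <- c(dropped, names(which.max(vifs)))
  }
  rep <- screening_report(setdiff(cols, dropped),
                          tibble::tibble(column = dropped,
                                         reason = rep("vif", length(dropped))),
                          list(sqrt_vif_threshold = sqrt_vif_threshold))
  attr(rep, "vif") <- vifs
  rep
}

#' Full predictor screening
#'
#' Runs the three screening steps in order (distance-class pruning,
#' between-variable pruning, VIF filtering) and returns the filtered table
#' together with a merged report.
#'
#' @inheritParams prune_distance_classes
#' @inheritParams prune_variables
#' @inheritParams vif_filter
#' @param vif_data Optional table on which the VIFs are computed (e.g. the
#'   modelling rows, one per trap x year x season, with the control
#'   columns); defaults to the screened predictor table itself.
#' @param controls Control factor columns for the VIF regressions; by
#'   default whichever of `site`, `year`, `season` are present in the VIF
#'   data.
#' @param max_vif_predictors Rank guard: at most this many columns (taken
#'   in importance, then class-priority order) enter the VIF step, since a
#'   VIF design with more predictors than independent rows is
#'   rank-deficient; the rest are dropped with reason `"rank_guard"`.
#' @return List with `table` (filtered tibble) and `report`
#'   (`screening_report` combining all three steps).
#' @export
screen_predictors <- function(table, threshold = 0.7,
                              class_priority = c(100, 1000, 500, 200, 300, 400,
                                                 600, 700, 800, 900),
                              importance_ranking = NULL,
                              vif_data = NULL,
                              controls = NULL,
                              sqrt_vif_threshold = 2,
                              max_vif_predictors = 12) {
  r1 <- prune_distance_classes(table, threshold, class_priority)
  t1 <- apply_screening(table, r1)
  if (is.null(importance_ranking)) {
    # default biological-importance order: the heterogeneity variables the
    # analysis centres on first, then everything else as encountered
    preferred <- c("NDVI_cv", "rough_mean", "ent1_mean", "con2_mean",
                   "hom2_mean", "NDVI_mean", "rough_sd", "ent1_sd")
    info <- parse_predictor_names(predictor_columns(t1))
    seen <- unique(paste(info$metric, info$summary, sep = "_"))
    importance_ranking <- c(intersect(preferred, seen),
                            setdiff(seen, preferred))
  }
  r2 <- prune_variables(t1, threshold, importance_ranking)
  t2 <- apply_screening(t1, r2)
  # rank guard: the VIF design needs fewer predictors than independent
  # rows; columns beyond the cap are set aside in importance order
  r_cap <- NULL
  cols2 <- predictor_columns(t2)
  if (length(cols2) > max_vif_predictors) {
    info2 <- parse_predictor_names(cols2)
    ord <- order(match(paste(info2$metric, info2$summary, sep = "_"),
                       importance_ranking),
                 match(info2$distance_class, class_priority,
                       nomatch = length(class_priority) + 1))
    drop_cols <- cols2[ord][-seq_len(max_vif_predictors)]
    r_cap <- screening_report(setdiff(cols2, drop_cols),
                              tibble::tibble(column = drop_cols,
                                             reason = rep("rank_guard",
                                                          length(drop_cols))),
                              list())
    t2 <- apply_screening(t2, r_cap)
  }
  vif_tab <- apply_screening(apply_screening(
    if (is.null(vif_data)) table else vif_data, r1), r2)
  if (!is.null(r_cap)) vif_tab <- apply_screening(vif_tab, r_cap)
  if (is.null(controls)) {
    controls <- usable_controls(vif_tab)
  }
  r3 <- vif_filter(vif_tab, controls, sqrt_vif_threshold)
  t3 <- apply_screening(t2, r3)
  dropped <- dplyr::bind_rows(r1$dropped_columns, r2$dropped_columns,
                              if (!is.null(r_cap)) r_cap$dropped_columns,
                              r3$dropped_columns)
  rep <- screening_report(r3$kept_columns, dropped,
                          list(correlation_threshold = threshold,
                               sqrt_vif_threshold = sqrt_vif_threshold))
  attr(rep, "vif") <- attr(r3, "vif")
  list(table = t3, report = rep)
}
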