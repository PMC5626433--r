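#' Split trap records into the three community subsets
#'
#' Honeybees are removed everywhere (managed colonies would confound the
#' heterogeneity signal). `bb` holds records whose species name starts with
#' the bumble-bee genus, `sb` the remaining wild bees, `nohb` their union
#' (all wild bees without honeybees).
#'
#' @param records Tibble with columns `trap_id`, `year`, `season`
#'   (`"early"`/`"late"`), `species`, `count`, `trapping_days`.
#' @param bumble_genus Genus prefix identifying bumble bees
#'   (default `"Bombus"`).
#' @param honeybee_list Species removed entirely
#'   (default `"Apis mellifera"`).
#' @return Named list of three tibbles: `bb`, `sb`, `nohb`.
#' @export
split_groups <- function(records, bumble_genus = "Bombus",
                         honeybee_list = "Apis mellifera") {
  stopifnot(all(c("trap_id", "year", "season", "species", "count",
                  "trapping_days") %in% names(records)))
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$species %in% honeybee_list)
  is_bb <- startsWith(records$species, paste0(bumble_genus, " ")) |
    records$species == bumble_genus
  list(bb = records[is_bb, ], sb = records[!is_bb, ], nohb = records)
}

#' Bee count normalized to trapping effort
#'
#' @param n Total individuals caught.
#' @param trapping_days Trap-active days for the period (> 0).
#' @return Individuals per trapping day.
#' @export
normalized_count <- function(n, trapping_days) {
  if (any(trapping_days <= 0)) stop("`trapping_days` must be > 0", call. = FALSE)
  n / trapping_days
}

#' Shannon diversity of a community
#'
#' `-sum(p_i ln p_i)` over species relative abundances. Zero for a
#' single-species community; `NA` (flagged) for an empty one.
#'
#' @param abundances Non-negative species counts (zeros are ignored).
#' @return Shannon index (natural log).
#' @export
shannon_diversity <- function(abundances) {
  x <- abundances[abundances > 0]
  if (!length(x)) return(NA_real_)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Individual-based rarefied / extrapolated species richness
#'
#' Expected species richness at a standardized number of individuals
#' `m_target`. Below the sample size `n` this is classical hypergeometric
#' rarefaction, `S_obs - sum_i C(n - X_i, m) / C(n, m)`. Above `n` the
#' Chao1-based extrapolation is used:
#' `S_obs + f0 * (1 - (1 - f1 / (n f0 + f1))^(m - n))` with the
#' bias-corrected Chao1 estimate of undetected species
#' `f0 = ((n-1)/n) f1^2 / (2 f2)` when doubletons exist, else
#' `((n-1)/n) f1 (f1 - 1) / 2`. With no singletons the extrapolation
#' returns `S_obs`.
#'
#' @param abundances Non-negative integer species counts.
#' @param m_target Positive integer number of individuals to standardize to.
#' @return Expected species richness (numeric).
#' @export
rarefied_richness <- function(abundances, m_target) {
  if (m_target < 1) stop("`m_target` must be >= 1", call. = FALSE)
  x <- abundances[abundances > 0]
  n <- sum(x)
  if (n < 1) stop("community is empty (n = 0)", call. = FALSE)
  s_obs <- length(x)
  m_target <- as.integer(round(m_target))
  if (m_target <= n) {
    # log-scale binomial ratios for numerical stability
    keep <- (n - x) >= m_target
    miss <- sum(exp(lchoose(n - x[keep], m_target) - lchoose(n, m_target)))
    return(s_obs - miss)
  }
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(as.numeric(s_obs))
  f0 <- if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2) else
    (n - 1) / n * f1 * (f1 - 1) / 2
  if (f0 == 0) return(as.numeric(s_obs))
  m_star <- m_target - n
  s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^m_star)
}

#' Standardization target: a multiple of the minimum community abundance
#'
#' The rarefaction target for a dataset is `factor` times the smallest
#' non-zero community total, rounded to the nearest integer. Communities
#' with zero individuals are excluded.
#'
#' @param n_values Community totals (one per trap x year x season).
#' @param factor Multiplier (default 3).
#' @return Positive integer target.
#' @export
dataset_m_target <- function(n_values, factor = 3) {
  n_values <- n_values[n_values >= 1]
  if (!length(n_values)) stop("all communities are empty", call. = FALSE)
  max(1L, as.integer(round(factor * min(n_values))))
}

#' Biodiversity response table
#'
#' Aggregates trap records into one row per trap x year x season x group
#' with the three responses: `BC` (count normalized to trapping days),
#' `SD` (Shannon diversity) and `SpR` (richness rarefied/extrapolated to
#' `rarefaction_factor` times the group's minimum community abundance).
#' Rows with zero individuals keep `BC = 0` and flagged (`NA`) `SD`/`SpR`.
#'
#' @inheritParams split_groups
#' @param rarefaction_factor Multiplier for [dataset_m_target()] (default 3).
#' @return Tibble with columns `group`, `trap_id`, `year`, `season`, `n`,
#'   `s_obs`, `BC`, `SD`, `SpR`, plus per-group attribute `"m_target"`.
#' @export
build_biodiversity <- function(records, bumble_genus = "Bombus",
                               honeybee_list = "Apis mellifera",
                               rarefaction_factor = 3) {
  groups <- split_groups(records, bumble_genus, honeybee_list)
  m_targets <- list()
  out <- purrr::imap(groups, function(recs, gname) {
    if (!nrow(recs)) return(tibble::tibble())
    comm <- recs |>
      dplyr::group_by(.data$trap_id, .data$year, .data$season, .data$species) |>
      dplyr::summarise(count = sum(.data$count),
                       trapping_days = .data$trapping_days[1], .groups = "drop")
    by_trap <- comm |>
      dplyr::group_by(.data$trap_id, .data$year, .data$season) |>
      dplyr::summarise(abund = list(.data$count[.data$count > 0]),
                       n = sum(.data$count),
                       trapping_days = .data$trapping_days[1], .groups = "drop")
    m_t <- dataset_m_target(by_trap$n, rarefaction_factor)
    m_targets[[gname]] <<- m_t
    by_trap |>
      dplyr::mutate(
        group = gname,
        s_obs = purrr::map_int(.data$abund, length),
        BC = normalized_count(.data$n, .data$trapping_days),
        SD = purrr::map_dbl(.data$abund, shannon_diversity),
        SpR = purrr::map_dbl(.data$abund, function(a) {
          if (sum(a) < 1) NA_real_ else rarefied_richness(a, m_t)
        })) |>
      dplyr::select("group", "trap_id", "year", "season", "n", "s_obs",
                    "BC", "SD", "SpR")
  }) |> dplyr::bind_rows()
  attr(out, "m_target") <- m_targets
  out
}

#' Early-versus-late season correlation of a biodiversity response
#'
#' Pearson correlation between the early and late values of one response,
#' paired by trap x year (and group if present), with the usual t-based
#' two-sided p-value. A strong correlation indicates a systematic seasonal
#' structure appropriately handled as a fixed season effect.
#'
#' @param table A [build_biodiversity()] table (or any tibble with
#'   `trap_id`, `year`, `season` and the response column).
#' @param variable One of `"BC"`, `"SD"`, `"SpR"`.
#' @return A tibble with `estimate` (r), `p.value`, `n_pairs`.
#' @export
season_correlation <- function(table, variable = c("BC", "SD", "SpR")) {
  variable <- match.arg(variable)
  keys <- intersect(c("group", "trap_id", "year"), names(table))
  wide <- table |>
    dplyr::select(dplyr::all_of(c(keys, "season", variable))) |>
    tidyr::pivot_wider(names_from = "season", values_from = dplyr::all_of(variable)) |>
    tidyr::drop_na(dplyr::any_of(c("early", "late")))
  if (nrow(wide) < 3) stop("need at least 3 trap x year pairs with both seasons",
                           call. = FALSE)
  ct <- stats::cor.test(wide$early, wide$late, method = "pearson")
  tibble::tibble(variable = variable, estimate = unname(ct$estimate),
                 p.value = ct$p.value, n_pairs = nrow(wide))
}
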