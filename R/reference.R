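#' Brute-force reference implementations of the window texture statistics
#'
#' Straightforward enumeration-based versions of the co-occurrence and
#' occurrence statistics for a *single* window, kept deliberately
#' independent of the moving-window kernels so the two routes can be
#' compared: `glcm_reference()` enumerates every ordered pixel pair at each
#' angle offset and tabulates the symmetric co-occurrence distribution
#' explicitly; `firstorder_reference()` tabulates the value histogram.
#'
#' @param levels Integer matrix of grey levels for one window (`NA`
#'   allowed).
#' @param distance Co-occurrence offset distance in pixels.
#' @param angles Which of the four angles to use, as a subset of
#'   `c(0, 45, 90, 135)`.
#' @return `glcm_reference()`: named list `contrast`, `dissimilarity`,
#'   `entropy`, `homogeneity` (averaged over the angles with at least one
#'   valid pair); `firstorder_reference()`: named list `mean`, `entropy`,
#'   `evenness`, `variance`.
#' @export
glcm_reference <- function(levels, distance = 1, angles = c(0, 45, 90, 135)) {
  offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                  `135` = c(-1, -1))
  nr <- nrow(levels); nc <- ncol(levels)
  per_angle <- list()
  for (a in as.character(angles)) {
    off <- offsets[[a]] * distance
    pairs <- list()
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
        v1 <- levels[i, j]; v2 <- levels[i2, j2]
        if (is.na(v1) || is.na(v2)) next
        # symmetric matrix: count the ordered pair both ways
        pairs[[length(pairs) + 1]] <- c(v1, v2)
        pairs[[length(pairs) + 1]] <- c(v2, v1)
      }
    }
    if (!length(pairs)) next
    tab <- table(vapply(pairs, paste, "", collapse = ","))
    p <- as.numeric(tab) / sum(tab)
    ij <- do.call(rbind, lapply(strsplit(names(tab), ","), as.numeric))
    d <- ij[, 1] - ij[, 2]
    per_angle[[a]] <- c(contrast = sum(p * d^2),
                        dissimilarity = sum(p * abs(d)),
                        entropy = -sum(p * log(p)),
                        homogeneity = sum(p / (1 + d^2)))
  }
  if (!length(per_angle)) {
    return(list(contrast = NA_real_, dissimilarity = NA_real_,
                entropy = NA_real_, homogeneity = NA_real_))
  }
  as.list(colMeans(do.call(rbind, per_angle)))
}

#' @rdname glcm_reference
#' @export
firstorder_reference <- function(levels) {
  v <- levels[!is.na(levels)]
  tab <- table(v)
  p <- as.numeric(tab) / sum(tab)
  lev <- as.numeric(names(tab))
  m <- sum(lev * p)
  ent <- -sum(p * log(p))
  list(mean = m, entropy = ent,
       evenness = if (length(p) == 1) 1 else ent / log(length(p)),
       variance = sum((lev - m)^2 * p))
}
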