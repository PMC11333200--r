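# Spatial aggregation tests: lagged autocorrelation with a permutation
# null, Mantel tests, and the sympatric-allopatric differentiation contrast.

# Row-wise Spearman correlation between two n x L matrices (average ranks).
.row_spearman <- function(A, B) {
  rk <- function(M) {
    L <- ncol(M)
    R <- matrix(1, nrow(M), L)
    for (a in seq_len(L)) for (b in seq_len(L)) {
      if (a == b) next
      R[, a] <- R[, a] + (M[, b] < M[, a]) + 0.5 * (M[, b] == M[, a])
    }
    R
  }
  ra <- rk(A); rb <- rk(B)
  ra <- ra - rowMeans(ra); rb <- rb - rowMeans(rb)
  num <- rowSums(ra * rb)
  den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Per-focal-window adjacent-block coefficients for one ordered track.
.block_coefficients <- function(values, scaffold, lag) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (sc in unique(scaffold)) {
    idx <- which(scaffold == sc)
    v <- values[idx]
    m <- length(v)
    n_focal <- m - 2 * lag + 1
    if (n_focal < 1) next
    A <- matrix(0, n_focal, lag)
    B <- matrix(0, n_focal, lag)
    for (l in seq_len(lag)) {
      A[, l] <- v[(0:(n_focal - 1)) + l]
      B[, l] <- v[(0:(n_focal - 1)) + lag + l]
    }
    out[idx[seq_len(n_focal)]] <- .row_spearman(A, B)
  }
  out
}

#' Lagged spatial autocorrelation along scaffolds
#'
#' For each focal window `i` with `2 * lag` successors on its scaffold, the
#' coefficient is the Spearman correlation between the two adjacent
#' non-overlapping blocks `[i, i + lag)` and `[i + lag, i + 2 lag)` of the
#' track. Blocks never span scaffolds; scaffolds shorter than `2 * lag`
#' windows are fully masked. Being rank-based, the coefficients are
#' invariant to strictly monotone transforms of the track.
#'
#' @param track data.frame/data.table with `scaffold`, `index` (order
#'   within scaffold) and `value`.
#' @param lag block size in windows (>= 2).
#' @return data.table `scaffold`, `index`, `value`, `coefficient`.
#' @export
lagged_autocorrelation <- function(track, lag) {
  stopifnot(lag >= 2)
  dt <- data.table(track)[, .(scaffold, index, value)]
  setorder(dt, scaffold, index)
  dt[, coefficient := .block_coefficients(value, scaffold, lag)]
  dt[]
}

#' Whole-scaffold lag-shift autocorrelation
#'
#' The alternative scaffold-level mode: one coefficient per scaffold and
#' lag, the Spearman correlation between the track and its lag-shifted
#' self, `cor(v[1..m-L], v[L+1..m])`. Unlike the per-window adjacent-block
#' coefficient this directly measures process autocorrelation at the lag
#' scale (a track smoothed over `k` windows shows positive coefficients
#' for lags below `k` and none above).
#'
#' @param track as in [lagged_autocorrelation()].
#' @param lag shift in windows (>= 1).
#' @return data.table `scaffold`, `coefficient`, `n_pairs`.
#' @export
lag_shift_autocorrelation <- function(track, lag) {
  stopifnot(lag >= 1)
  dt <- data.table(track)[, .(scaffold, index, value)]
  setorder(dt, scaffold, index)
  dt[, {
    m <- .N
    if (m <= lag + 2) {
      list(coefficient = NA_real_, n_pairs = 0L)
    } else {
      list(coefficient = stats::cor(rank(value[1:(m - lag)]),
                                    rank(value[(1 + lag):m])),
           n_pairs = m - lag)
    }
  }, by = scaffold]
}

#' Permutation null and per-window p-values for the autocorrelation scan
#'
#' Permutes the track values genome-wide `n_perm` times, recomputes every
#' eligible coefficient, pools all permuted coefficients into one null
#' distribution, and assigns each observed coefficient a two-sided
#' add-one p-value `p = (1 + #\{|null| >= |obs|\}) / (N_null + 1)`.
#'
#' @param track as in [lagged_autocorrelation()].
#' @param lag block size.
#' @param n_perm number of genome-wide permutations (>= 100).
#' @param seed RNG seed.
#' @return list: `result` (the [lagged_autocorrelation()] table plus
#'   `p_value`), `null` (pooled permuted coefficients).
#' @export
autocorr_permutation_null <- function(track, lag, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  obs <- lagged_autocorrelation(track, lag)
  set.seed(seed)
  dt <- data.table(track)[, .(scaffold, index, value)]
  setorder(dt, scaffold, index)
  null <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm <- dt$value[sample.int(nrow(dt))]
    null[[b]] <- .block_coefficients(perm, dt$scaffold, lag)
  }
  null <- unlist(null)
  null <- null[!is.na(null)]
  absn <- sort(abs(null))
  N <- length(absn)
  cnt <- N - findInterval(abs(obs$coefficient) - 1e-12, absn)
  obs[, p_value := fifelse(is.na(coefficient), NA_real_,
                           (1 + cnt) / (N + 1))]
  list(result = obs[], null = null)
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle entries;
#' significance comes from joint row/column permutations of the second
#' matrix with the one-sided (positive association) add-one p-value, which
#' never returns 0.
#'
#' @param m1,m2 square symmetric matrices with identical dimensions (and
#'   labels, when both are labelled).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = 1) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1)) {
    stop("mantel_test: matrices must be square with equal dimensions")
  }
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("mantel_test: matrix labels differ")
  }
  lower <- lower.tri(m1)
  v1 <- m1[lower]
  r_obs <- stats::cor(v1, m2[lower])
  set.seed(seed)
  n <- nrow(m1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    if (stats::cor(v1, m2[idx, idx][lower]) >= r_obs - 1e-15) {
      count <- count + 1L
    }
  }
  list(r = r_obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

#' Great-circle distance matrix between group centroids
#'
#' @param metadata data.frame with `lat`, `lon` (decimal degrees) and a
#'   grouping column.
#' @param by grouping column name (default `"species"`).
#' @return symmetric matrix of distances in km.
#' @export
geo_distance_matrix <- function(metadata, by = "species") {
  cen <- stats::aggregate(metadata[, c("lat", "lon")],
                          by = list(group = metadata[[by]]), mean)
  n <- nrow(cen)
  d <- matrix(0, n, n, dimnames = list(cen$group, cen$group))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- geosphere::distHaversine(
      c(cen$lon[i], cen$lat[i]), c(cen$lon[j], cen$lat[j])) / 1000
  }
  d
}

#' Sympatric-allopatric differentiation contrast
#'
#' For every species pair and window, the mean FST over sympatric
#' population pairs (same location) minus the mean over allopatric pairs
#' (different locations). The per-pair difference tracks are assembled into
#' a landscape matrix and summarized with [landscape_pca()]: a small PC1
#' fraction indicates no systematic shared geography-of-gene-flow signal.
#'
#' @param pop_fst data.table with columns `window_id`, `sp1`, `pop1`,
#'   `sp2`, `pop2`, `fst` for between-species population pairs.
#' @param metadata sample metadata mapping populations to locations.
#' @param standardize passed to [landscape_pca()].
#' @return list: `contrast` (window_id, pair_id, sympatric, allopatric,
#'   difference), `matrix` (windows x pairs difference matrix), `pca`
#'   (landscape summary), `excluded_pairs`.
#' @export
sympatric_allopatric_contrast <- function(pop_fst, metadata,
                                          standardize = TRUE) {
  dt <- data.table(pop_fst)
  ploc <- unique(data.table(metadata)[, .(population, location)])
  dt <- merge(dt, ploc, by.x = "pop1", by.y = "population")
  setnames(dt, "location", "loc1")
  dt <- merge(dt, ploc, by.x = "pop2", by.y = "population")
  setnames(dt, "location", "loc2")
  dt[, pair_id := paste(pmin(sp1, sp2), pmax(sp1, sp2), sep = ":")]
  agg <- dt[, .(
    sympatric = mean(fst[loc1 == loc2], na.rm = TRUE),
    allopatric = mean(fst[loc1 != loc2], na.rm = TRUE)
  ), by = .(window_id, pair_id)]
  agg[, difference := sympatric - allopatric]
  agg[is.nan(sympatric) | is.nan(allopatric), difference := NA_real_]
  # pairs lacking either category anywhere are excluded
  bad <- agg[, .(all_na = all(is.na(difference))), by = pair_id][all_na == TRUE,
                                                                pair_id]
  if (length(bad)) {
    .msg("contrast: excluding pairs without both categories: %s",
         paste(bad, collapse = ", "))
    agg <- agg[!pair_id %in% bad]
  }
  m <- build_landscape_matrix(
    agg[, .(window_id, column = pair_id, value = difference)])
  pca <- tryCatch(suppressWarnings(landscape_pca(m, standardize = standardize)),
                  error = function(e) NULL)
  list(contrast = agg[], matrix = m, pca = pca, excluded_pairs = bad)
}
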