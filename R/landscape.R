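# Windows x species (or species-pair) landscape matrices, PCA summary,
# and the Spearman correlation structure of the mean landscapes.

#' Assemble a landscape matrix from long-format window statistics
#'
#' @param stats long data.table with columns `window_id`, a column-key
#'   column (`column` by default, e.g. species or pair id), and `value`.
#' @param column name of the column-key column.
#' @return matrix windows x columns (rownames = window ids, columns in
#'   lexicographic order); cells without an observation are NA.
#' @export
build_landscape_matrix <- function(stats, column = "column") {
  dt <- data.table(stats)
  stopifnot(all(c("window_id", column, "value") %in% names(dt)))
  cols <- sort(unique(dt[[column]]))
  wins <- sort(unique(dt$window_id))
  m <- matrix(NA_real_, length(wins), length(cols),
              dimnames = list(wins, cols))
  m[cbind(match(dt$window_id, wins), match(dt[[column]], cols))] <- dt$value
  m
}

#' Landscape PCA summary
#'
#' Principal component analysis of a windows x columns landscape matrix.
#' Rows with any missing cell are dropped listwise; zero-variance columns
#' are dropped with a warning. Columns are centered and, by default,
#' scaled to unit variance (correlation-matrix PCA), because landscapes of
#' pairs at different divergence levels live on different scales. The PC1
#' score sign is fixed so that Spearman correlation with the row-mean
#' landscape is non-negative (PCA signs are otherwise arbitrary).
#'
#' @param m landscape matrix from [build_landscape_matrix()].
#' @param standardize scale columns to unit variance (default TRUE).
#' @return list of class `landscape_summary`: `pc1_variance_fraction`,
#'   `variance_fractions` (all components, summing to 1), `pc1_loadings`
#'   (per retained window; named by window id), `mean_landscape` (same
#'   windows), `r_s` (Spearman between the two), `n_windows`, `n_columns`,
#'   `dropped_windows`.
#' @export
landscape_pca <- function(m, standardize = TRUE) {
  stopifnot(is.matrix(m))
  complete <- stats::complete.cases(m)
  dropped <- sum(!complete)
  x <- m[complete, , drop = FALSE]
  if (nrow(x) < 3) stop("fewer than 3 complete windows: PCA undefined")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need >= 2 informative columns")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1]
  mean_land <- rowMeans(x)
  rs <- stats::cor(scores, mean_land, method = "spearman")
  if (!is.na(rs) && rs < 0) {
    scores <- -scores
    rs <- -rs
  }
  structure(list(
    pc1_variance_fraction = fr[1],
    variance_fractions = fr,
    pc1_loadings = stats::setNames(scores, rownames(x)),
    mean_landscape = stats::setNames(mean_land, rownames(x)),
    r_s = rs,
    n_windows = nrow(x),
    n_columns = ncol(x),
    dropped_windows = dropped
  ), class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf(
    "landscape PCA: %d windows x %d columns; PC1 explains %.1f%%; r_S(PC1, mean) = %.3f\n",
    x$n_windows, x$n_columns, 100 * x$pc1_variance_fraction, x$r_s))
  invisible(x)
}

#' Row-mean landscape
#'
#' The per-window value averaged over available columns — the canonical
#' single landscape used downstream in place of PC1 loadings (the two are
#' nearly rank-identical at high inter-column correlation).
#'
#' @param m landscape matrix.
#' @return named numeric vector (window ids).
#' @export
mean_landscape <- function(m) {
  stats::setNames(rowMeans(m, na.rm = TRUE), rownames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control; adjusted values are
#' monotone in the raw ordering and never smaller than the raw p-values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman correlation structure of window tracks
#'
#' All pairwise Spearman rank correlations among named per-window tracks,
#' with average-rank ties, t-approximation p-values, one-batch
#' Benjamini-Hochberg adjustment over the full family, and seeded bootstrap
#' standard errors. Pairs with fewer than `min_n` complete windows are
#' masked.
#'
#' @param tracks data.frame/data.table of per-window values (one column per
#'   statistic; rows aligned on the same windows) or a named list of
#'   equal-length vectors.
#' @param n_boot bootstrap resamples for the SE (0 disables).
#' @param seed seed for the bootstrap.
#' @param min_n minimum paired windows per cell.
#' @return list of matrices `r` (unit diagonal, symmetric), `p_raw`,
#'   `p_adj`, `se`, `n`.
#' @export
correlation_structure <- function(tracks, n_boot = 1000, seed = 1,
                                  min_n = 10) {
  df <- as.data.frame(tracks)
  k <- ncol(df)
  nm <- colnames(df)
  r <- p <- se <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  nmat <- matrix(0L, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  diag(p) <- 0
  set.seed(seed)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- df[[i]]; y <- df[[j]]
    ok <- stats::complete.cases(x, y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < min_n) next
    res <- spearman_rs(x[ok], y[ok])
    r[i, j] <- r[j, i] <- res$estimate
    p[i, j] <- p[j, i] <- res$p.value
    if (n_boot > 0) {
      xs <- x[ok]; ys <- y[ok]; nn <- length(xs)
      bs <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nn, nn, replace = TRUE)
        suppressWarnings(stats::cor(rank(xs[idx]), rank(ys[idx])))
      }, 0)
      se[i, j] <- se[j, i] <- stats::sd(bs)
    }
  }
  upper <- upper.tri(p)
  padj <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  vals <- p[upper]
  ok <- !is.na(vals)
  adj <- vals
  adj[ok] <- bh_adjust(vals[ok])
  padj[upper] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  diag(padj) <- 0
  list(r = r, p_raw = p, p_adj = padj, se = se, n = nmat)
}
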