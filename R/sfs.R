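# Folded site-frequency spectra by expectation maximization.

#' Folding map for minor-allele counts
#'
#' Category `k` and `n - k` are merged by summation; the middle category at
#' even `n` is represented once (never double-counted).
#'
#' @param n haploid sample size.
#' @return (n+1) x (floor(n/2)+1) 0/1 matrix `F` with `L_folded = L %*% F`.
#' @export
fold_map <- function(n) {
  m <- floor(n / 2) + 1
  F <- matrix(0, n + 1, m)
  for (k in 0:n) F[k + 1, min(k, n - k) + 1] <- 1
  F
}

#' Fold a SAF matrix
#' @param saf sites x (n+1) linear SAF matrix.
#' @param n haploid sample size.
#' @return sites x (floor(n/2)+1) folded likelihood matrix.
#' @export
fold_saf <- function(saf, n) saf %*% fold_map(n)

#' Exchangeable-assignment likelihood from an assignment-sum SAF
#'
#' A SAF vector is the sum over allele assignments; the probability of the
#' data given the count `k` under uniformly exchangeable assignments is
#' that sum divided by `choose(n, k)`. The correction matters only for
#' sites whose likelihood is smeared over counts (missing or uncertain
#' individuals); for data-certain sites it cancels in the per-site
#' normalization. Mixture fits (EM SFS, posteriors) use the corrected
#' likelihood so that the estimated spectrum stays consistent under
#' missingness.
#'
#' @param saf sites x (n+1) linear SAF matrix (or a vector).
#' @param n haploid sample size.
#' @return matrix/vector of the same shape.
#' @export
saf_to_likelihood <- function(saf, n) {
  w <- choose(n, 0:n)
  if (is.null(dim(saf))) return(saf / w)
  sweep(saf, 2, w, "/")
}

# Shared EM engine: lik is sites x categories (linear, any per-row scale).
.em_engine <- function(lik, tol, max_iter) {
  m <- ncol(lik)
  p <- rep(1 / m, m)
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- sweep(lik, 2, p, "*")
    rs <- rowSums(W)
    ll <- sum(log(rs))
    post <- W / rs
    p_new <- colMeans(post)
    trace <- c(trace, ll)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
    loglik <- ll
  }
  list(p = p, loglik = trace[length(trace)], trace = trace,
       converged = converged, iterations = length(trace))
}

#' ML folded site-frequency spectrum by EM
#'
#' Maximizes `sum_sites log sum_k p_k L_site(k)` over the probability
#' simplex with plain EM. The log-likelihood is non-decreasing across
#' iterations; convergence is declared when the largest parameter change
#' falls below `tol` or after `max_iter` iterations (then a warning is
#' raised and the best estimate returned).
#'
#' @param saf a `saf_set` from [saf_matrix()], or a sites x (n+1) linear SAF
#'   matrix (then `n` must be given).
#' @param n haploid sample size (taken from the `saf_set` if missing).
#' @param folded fold minor-allele categories before optimization (default).
#' @param tol,max_iter convergence controls.
#' @return object of class `glscape_sfs`: `probs` (sums to 1), `n`,
#'   `folded`, `loglik`, `loglik_trace`, `converged`, `iterations`.
#' @export
em_sfs <- function(saf, n = NULL, folded = TRUE, tol = 1e-8, max_iter = 500) {
  if (inherits(saf, "saf_set")) {
    n <- saf$n
    saf <- saf$saf
  }
  if (is.null(n)) stop("n required when saf is a bare matrix")
  if (is.null(dim(saf))) saf <- matrix(saf, nrow = 1)
  if (nrow(saf) == 0) stop("empty SAF set")
  stopifnot(ncol(saf) == n + 1, tol > 0)
  lik <- saf_to_likelihood(saf, n)
  lik <- if (folded) fold_saf(lik, n) else lik
  fit <- .em_engine(lik, tol, max_iter)
  if (!fit$converged) warning("em_sfs: EM did not converge in ", max_iter,
                              " iterations")
  structure(list(probs = fit$p, n = n, folded = folded, dim = 1L,
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 converged = fit$converged, iterations = fit$iterations),
            class = "glscape_sfs")
}

#' @export
print.glscape_sfs <- function(x, ...) {
  cat(sprintf("%s %dD SFS, n=%s, %d categories, loglik=%.4f (%d EM iterations)\n",
              if (x$folded) "folded" else "unfolded", x$dim,
              paste(x$n, collapse = "x"), length(x$probs), x$loglik,
              x$iterations))
  invisible(x)
}

#' Joint folding structure for a 2D SFS grid
#'
#' Cells `(j, k)` and `(nA - j, nB - k)` are merged (joint fold). Returns
#' the group assignment and the representative unfolded cell of each group.
#'
#' @param nA,nB haploid sample sizes.
#' @return list: `group` (per-cell group index over the column-major
#'   (nA+1) x (nB+1) grid), `rep_j`, `rep_k` (representatives per group).
#' @export
fold_map_2d <- function(nA, nB) {
  cells <- expand.grid(j = 0:nA, k = 0:nB)
  id <- cells$j + cells$k * (nA + 1)
  partner <- (nA - cells$j) + (nB - cells$k) * (nA + 1)
  canon <- pmin(id, partner)
  group <- match(canon, sort(unique(canon)))
  reps <- !duplicated(group)
  list(group = group,
       rep_j = cells$j[reps][order(group[reps])],
       rep_k = cells$k[reps][order(group[reps])])
}

# sites x groups folded product likelihood for a species pair
# (with the exchangeable-assignment correction applied per side)
.pair_lik <- function(safA, safB, folded = TRUE) {
  nA <- ncol(safA) - 1
  nB <- ncol(safB) - 1
  safA <- saf_to_likelihood(safA, nA)
  safB <- saf_to_likelihood(safB, nB)
  jc <- rep(0:nA, nB + 1)
  kc <- rep(0:nB, each = nA + 1)
  M <- safA[, jc + 1, drop = FALSE] * safB[, kc + 1, drop = FALSE]
  if (!folded) {
    return(list(lik = M, rep_j = jc, rep_k = kc))
  }
  fm <- fold_map_2d(nA, nB)
  G <- matrix(0, length(fm$group), max(fm$group))
  G[cbind(seq_along(fm$group), fm$group)] <- 1
  lik <- M %*% G
  list(lik = lik, rep_j = fm$rep_j, rep_k = fm$rep_k)
}

#' ML 2D site-frequency spectrum by EM
#'
#' EM over the `(nA+1) x (nB+1)` grid of joint minor-allele counts for two
#' groups sharing the same sites, with the same convergence contract as
#' [em_sfs()]. With `folded = TRUE`, cells `(j,k)` and `(nA-j, nB-k)` are
#' merged jointly.
#'
#' @param saf_A,saf_B `saf_set` objects over identical sites.
#' @param folded joint folding flag.
#' @param tol,max_iter convergence controls.
#' @return `glscape_sfs` object with `dim = 2`, `probs` over (folded grid)
#'   cells, `rep_j`/`rep_k` giving the representative unfolded cell of each
#'   category, and `n = c(nA, nB)`.
#' @export
em_sfs_2d <- function(saf_A, saf_B, folded = TRUE, tol = 1e-8,
                      max_iter = 500) {
  stopifnot(inherits(saf_A, "saf_set"), inherits(saf_B, "saf_set"))
  if (nrow(saf_A$sites) != nrow(saf_B$sites) ||
      !all(saf_A$sites$scaffold == saf_B$sites$scaffold &
             saf_A$sites$pos == saf_B$sites$pos)) {
    stop("em_sfs_2d: SAF sets are not indexed by the same sites")
  }
  pl <- .pair_lik(saf_A$saf, saf_B$saf, folded)
  fit <- .em_engine(pl$lik, tol, max_iter)
  if (!fit$converged) warning("em_sfs_2d: EM did not converge in ", max_iter,
                              " iterations")
  structure(list(probs = fit$p, n = c(saf_A$n, saf_B$n), folded = folded,
                 dim = 2L, rep_j = pl$rep_j, rep_k = pl$rep_k,
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 converged = fit$converged, iterations = fit$iterations),
            class = "glscape_sfs")
}

#' Per-site posterior spectrum under an SFS prior
#'
#' `posterior_k = prior_k * L(k) / sum_k prior_k * L(k)`; a pseudo-mass of
#' 1e-12 is added to prior categories with zero mass so the posterior is
#' always defined where the likelihood has support.
#'
#' @param lik per-site likelihood over categories: a vector, or a
#'   sites x categories matrix (folded to match the prior).
#' @param prior a `glscape_sfs` or bare probability vector.
#' @return posterior of the same shape as `lik`; rows sum to 1.
#' @export
posterior_site_spectrum <- function(lik, prior) {
  p <- if (inherits(prior, "glscape_sfs")) prior$probs else prior
  p <- p + 1e-12
  vec <- is.null(dim(lik))
  if (vec) lik <- matrix(lik, nrow = 1)
  if (ncol(lik) != length(p)) stop("likelihood/prior category mismatch")
  W <- sweep(lik, 2, p, "*")
  rs <- rowSums(W)
  if (any(rs == 0)) stop("posterior undefined: all-zero product at some site")
  out <- W / rs
  if (vec) out[1, ] else out
}
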