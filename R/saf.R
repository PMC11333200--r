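# Site-allele-frequency (SAF) likelihood vectors.
#
# L(k) = sum over assignments of exactly k minor alleles to the n non-missing
# individuals of the product of their per-allele likelihoods — computed with
# the standard O(n^2) dynamic programming over individuals, never by
# enumeration.

#' SAF vector for one site
#'
#' @param lik_major,lik_minor per-individual linear likelihoods of carrying
#'   the major / minor allele; NA marks a missing individual (skipped: it
#'   contributes no allele).
#' @return numeric vector of length `n_present + 1` giving the likelihood of
#'   each minor-allele count `k = 0..n_present`, normalized so the maximum
#'   is 1 (max log-likelihood 0).
#' @export
saf_vector <- function(lik_major, lik_minor) {
  stopifnot(length(lik_major) == length(lik_minor))
  present <- !is.na(lik_major) & !is.na(lik_minor)
  a <- lik_major[present]
  b <- lik_minor[present]
  n <- length(a)
  if (n < 2) stop("SAF needs >= 2 non-missing individuals")
  h <- c(1, numeric(n))
  for (i in seq_len(n)) {
    h[2:(i + 1)] <- h[2:(i + 1)] * a[i] + h[1:i] * b[i]
    h[1] <- h[1] * a[i]
    h <- h / max(h)
  }
  h / max(h)
}

#' SAF matrix for all sites of a group of individuals
#'
#' Vectorized dynamic programming across sites. Sites missing in more than
#' `max_missing_fraction` of the group are discarded. The remaining
#' missing individuals are handled by one of two policies:
#'
#' * `"impute"` (default): an individual without surviving reads has a
#'   flat likelihood over the allele pair — the exact likelihood of "no
#'   data" — so every site keeps the full sample size `n = N` and the SFS
#'   prior resolves the unknown alleles downstream.
#' * `"project"`: missing individuals are skipped (each site's support is
#'   `0..n_present`) and all surviving sites are hypergeometrically
#'   down-projected to the common minimum sample size
#'   (see [project_saf()]), bounded below by `min_project_n`.
#'
#' @param gla a [gl_array()].
#' @param mm major/minor table from [infer_major_minor()] (site order must
#'   match `gla`).
#' @param individuals subset of sample ids forming the group (default all).
#' @param max_missing_fraction per-site missingness tolerance.
#' @param missing missing-data policy, `"impute"` or `"project"`.
#' @param min_project_n lower bound on the projected sample size under
#'   `"project"`; sites with fewer non-missing individuals are dropped
#'   rather than allowed to drag the common n below it.
#' @return list of class `saf_set`: `saf` (sites x (n+1) linear likelihood
#'   matrix, rows scaled to max 1), `n` (common haploid sample size),
#'   `sites` (site table with `site_i` into `gla`), `n_present` (per site).
#' @export
saf_matrix <- function(gla, mm, individuals = NULL,
                       max_missing_fraction = 1 / 3,
                       missing = c("impute", "project"),
                       min_project_n = 2) {
  missing <- match.arg(missing)
  idx <- if (is.null(individuals)) seq_along(gla$samples)
         else match(individuals, gla$samples)
  if (anyNA(idx)) stop("unknown individuals")
  N <- length(idx)
  n_site <- dim(gla$ll)[1]
  stopifnot(nrow(mm) == n_site)

  # per-individual likelihoods of the site's major / minor allele
  maj_i <- match(mm$major, .BASES)
  min_i <- match(mm$minor_base, .BASES)
  La <- matrix(NA_real_, n_site, N)
  Lb <- matrix(NA_real_, n_site, N)
  for (j in seq_len(N)) {
    lj <- gla$ll[, idx[j], , drop = FALSE]
    dim(lj) <- c(n_site, 4)
    la <- lj[cbind(seq_len(n_site), maj_i)]
    lb <- lj[cbind(seq_len(n_site), min_i)]
    m <- pmax(la, lb)
    La[, j] <- exp(la - m)
    Lb[, j] <- exp(lb - m)
  }
  miss <- is.na(La)
  n_present <- N - rowSums(miss)
  if (missing == "impute") {
    # no data: both alleles equally likely
    La[miss] <- 1
    Lb[miss] <- 1
  } else {
    # skip update for missing individuals: multiply by 1, add 0
    La[miss] <- 1
    Lb[miss] <- 0
  }

  h <- matrix(0, n_site, N + 1)
  h[, 1] <- 1
  for (j in seq_len(N)) {
    h[, 2:(j + 1)] <- h[, 2:(j + 1), drop = FALSE] * La[, j] +
      h[, 1:j, drop = FALSE] * Lb[, j]
    h[, 1] <- h[, 1] * La[, j]
    h <- h / pmax(matrixMaxRow(h), 1e-300)
  }

  keep <- (N - n_present) / N <= max_missing_fraction
  if (missing == "project") {
    keep <- keep & n_present >= max(2, min(min_project_n, N))
  }
  sites <- data.table(gla$sites)[keep]
  h <- h[keep, , drop = FALSE]
  n_present <- n_present[keep]
  if (!nrow(sites)) stop("no sites survive the missingness rule")

  if (missing == "project") {
    n_common <- min(n_present)
    h <- project_saf(h, n_present, n_common)
  } else {
    n_common <- N
  }
  h <- h / pmax(matrixMaxRow(h), 1e-300)
  structure(list(saf = h, n = n_common, sites = sites, n_present = n_present),
            class = "saf_set")
}

# row maxima without matrixStats
matrixMaxRow <- function(m) {
  out <- m[, 1]
  for (j in 2:ncol(m)) out <- pmax(out, m[, j])
  out
}

#' Hypergeometric down-projection of SAF vectors
#'
#' Projects SAF support from each site's observed sample size to a common
#' smaller `n_to`: `L'(j) = sum_k L(k) P(j | k)` where `P(j | k)` is the
#' probability that a subsample of `n_to` of the `n_from` alleles contains
#' `j` of the `k` minor alleles (hypergeometric). Sites already at `n_to`
#' are unchanged, so the projection is exact in the absence of missingness.
#'
#' @param saf sites x (n_max+1) linear SAF matrix (support `0..n_present`).
#' @param n_present per-site sample size.
#' @param n_to target sample size (<= min(n_present)).
#' @return sites x (n_to+1) matrix.
#' @export
project_saf <- function(saf, n_present, n_to) {
  if (any(n_present < n_to)) stop("cannot project upward")
  out <- matrix(0, nrow(saf), n_to + 1)
  for (nf in sort(unique(n_present))) {
    rows <- which(n_present == nf)
    if (nf == n_to) {
      out[rows, ] <- saf[rows, 1:(n_to + 1), drop = FALSE]
    } else {
      H <- outer(0:nf, 0:n_to, function(k, j) dhyper(j, k, nf - k, n_to))
      out[rows, ] <- saf[rows, 1:(nf + 1), drop = FALSE] %*% H
    }
  }
  out
}
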