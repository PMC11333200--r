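# Empirical-Bayes window estimates of diversity and the neutrality test.

#' Per-category estimator weights for a folded spectrum
#'
#' For folded category `j` of haploid sample size `n` (true minor count `j`
#' or `n - j`, both giving the same pairwise-heterozygosity weight):
#' `w_pi(j) = j (n - j) / C(n, 2)`; the probability that the site segregates
#' is `1 - post_0`, contributing `1 / a1` to Watterson's theta.
#'
#' @param n haploid sample size (>= 2).
#' @return list `w_pi` (length floor(n/2)+1) and `a1`.
#' @export
folded_theta_weights <- function(n) {
  j <- 0:floor(n / 2)
  list(w_pi = j * (n - j) / choose(n, 2), a1 = harmonic_a1(n))
}

#' Window sums of theta-pi and theta-W from per-site posteriors
#'
#' Each site contributes its posterior-expected pairwise diversity and its
#' posterior probability of segregating divided by `a1`; window values are
#' sums over sites, and per-site means divide by `n_sites` (the number of
#' callable sites in the window, including invariant ones).
#'
#' @param post sites x categories folded posterior matrix (rows sum to 1).
#' @param n haploid sample size.
#' @param window_id per-site window assignment (integer vector).
#' @param n_sites named vector (or single number) of callable sites per
#'   window, used for the per-site means.
#' @return data.table: `window_id`, `theta_pi`, `theta_w` (window sums),
#'   `S` (posterior-expected segregating sites), `pi_site`, `theta_w_site`
#'   (per-site means), `n_var` (variant sites contributing).
#' @export
window_thetas <- function(post, n, window_id, n_sites) {
  if (is.null(dim(post))) post <- matrix(post, nrow = 1)
  stopifnot(n >= 2, nrow(post) == length(window_id))
  w <- folded_theta_weights(n)
  if (ncol(post) != length(w$w_pi)) stop("posterior has wrong category count")
  pi_site <- as.vector(post %*% w$w_pi)
  pseg <- 1 - post[, 1]
  dt <- data.table(window_id = window_id, pi = pi_site, pseg = pseg)
  agg <- dt[, .(theta_pi = sum(pi), S = sum(pseg), n_var = .N),
            by = window_id]
  agg[, theta_w := S / w$a1]
  ns <- if (length(n_sites) == 1) rep(n_sites, nrow(agg))
        else n_sites[as.character(agg$window_id)]
  agg[, `:=`(pi_site = theta_pi / ns, theta_w_site = theta_w / ns)]
  setcolorder(agg, c("window_id", "theta_pi", "theta_w", "S", "pi_site",
                     "theta_w_site", "n_var"))
  setorder(agg, window_id)
  agg[]
}

#' Tajima (1989) constants
#'
#' @param n haploid sample size (>= 4 so the variance terms are defined).
#' @return named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D for a window
#'
#' `D = (theta_pi - theta_w) / sqrt(e1 S + e2 S (S - 1))` with the 1989
#' constants computed from `n`; under the empirical-Bayes pipeline `S` is
#' the posterior-expected number of segregating sites in the window.
#' `S = 0` yields a masked (NA) value, not zero.
#'
#' @param theta_pi,theta_w window sums of the two estimators.
#' @param S (expected) segregating sites in the window.
#' @param n haploid sample size.
#' @return numeric (vectorized over windows).
#' @export
tajimas_d <- function(theta_pi, theta_w, S, n) {
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * pmax(S - 1, 0)
  out <- (theta_pi - theta_w) / sqrt(v)
  out[S <= 0 | v <= 0] <- NA_real_
  out
}

#' Per-window diversity scan for one species
#'
#' Chains the whole empirical-Bayes stack for the individuals of one
#' species: major/minor inference, SAF vectors with the missingness rule
#' and common-n projection, genome-wide folded EM SFS (the prior), per-site
#' posteriors, and per-window theta-pi, theta-W and Tajima's D.
#'
#' @param gla [gl_array()] over all samples and candidate variant sites.
#' @param metadata sample metadata (sample_id, species, ...).
#' @param species focal species id.
#' @param windows window table ([make_windows()]).
#' @param max_missing_fraction site missingness tolerance within the species.
#' @param tol,max_iter EM controls for the SFS prior.
#' @return list: `windows` (data.table with window_id, theta_pi, theta_w,
#'   tajima_d, S, pi_site, theta_w_site, n_var), `sfs` (the prior), `n`
#'   (projected haploid sample size).
#' @export
species_theta_scan <- function(gla, metadata, species, windows,
                               max_missing_fraction = 1 / 3,
                               tol = 1e-8, max_iter = 500) {
  samp <- metadata$sample_id[metadata$species == species]
  if (length(samp) < 4) stop("need >= 4 samples for Tajima's D: ", species)
  mm <- infer_major_minor(gla, individuals = samp)
  saf <- saf_matrix(gla, mm, individuals = samp,
                    max_missing_fraction = max_missing_fraction)
  sfs <- em_sfs(saf, tol = tol, max_iter = max_iter)
  lik_f <- fold_saf(saf_to_likelihood(saf$saf, saf$n), saf$n)
  post <- posterior_site_spectrum(lik_f, sfs)
  wid <- assign_windows(windows, saf$sites$scaffold, saf$sites$pos)
  ok <- !is.na(wid)
  L <- windows$end[1] - windows$start[1]
  th <- window_thetas(post[ok, , drop = FALSE], saf$n, wid[ok], L)
  th[, tajima_d := tajimas_d(theta_pi, theta_w, S, saf$n)]
  # windows with no variant sites: zero diversity, masked D
  missing_w <- setdiff(windows$window_id, th$window_id)
  if (length(missing_w)) {
    th <- rbind(th, data.table(window_id = missing_w, theta_pi = 0,
                               theta_w = 0, S = 0, pi_site = 0,
                               theta_w_site = 0, n_var = 0L,
                               tajima_d = NA_real_))
  }
  setorder(th, window_id)
  th[, species := species]
  list(windows = th[], sfs = sfs, n = saf$n)
}
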