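# Reynolds-type method-of-moments FST for haploid samples.
#
# Alleles of haploid individuals are treated directly as the sampled
# alleles. Per-site variance components follow the method-of-moments
# algebra with finite-sample correction:
#   a     = (p1 - p2)^2 - p1 q1 / (n1 - 1) - p2 q2 / (n2 - 1)
#   a + b = a + p1 q1 n1 / (n1 - 1) + p2 q2 n2 / (n2 - 1)
# so a fixed difference gives a/(a+b) = 1 exactly for any sample size, and
# the expectation of `a` vanishes for equal allele frequencies. Windowed and
# genome-wide estimates are ratios of summed components (weighted FST),
# never means of per-site ratios. Negative per-window values are retained,
# not clipped.

#' Per-site FST variance components from allele frequencies
#'
#' @param p1,p2 sample minor-allele frequencies in the two groups.
#' @param n1,n2 haploid sample sizes (>= 2).
#' @return list of vectors `a` (numerator) and `ab` (denominator a+b).
#' @export
fst_components <- function(p1, p2, n1, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  q1 <- 1 - p1; q2 <- 1 - p2
  a <- (p1 - p2)^2 - p1 * q1 / (n1 - 1) - p2 * q2 / (n2 - 1)
  ab <- a + p1 * q1 * n1 / (n1 - 1) + p2 * q2 * n2 / (n2 - 1)
  list(a = a, ab = ab)
}

#' Posterior-expected FST components over a folded 2D spectrum
#'
#' Under the empirical-Bayes machinery the per-site components are
#' posterior expectations over the (folded) 2D frequency grid; the Reynolds
#' components are invariant under the joint fold `(j,k) -> (nA-j, nB-k)`,
#' so representatives of folded categories can be used directly.
#'
#' @param post sites x categories posterior matrix (rows sum to 1).
#' @param sfs2d the 2D `glscape_sfs` object providing `rep_j`, `rep_k`, `n`.
#' @return list of vectors `a`, `ab` (one entry per site).
#' @export
fst_components_posterior <- function(post, sfs2d) {
  stopifnot(inherits(sfs2d, "glscape_sfs"), sfs2d$dim == 2L)
  comp <- fst_components(sfs2d$rep_j / sfs2d$n[1], sfs2d$rep_k / sfs2d$n[2],
                         sfs2d$n[1], sfs2d$n[2])
  list(a = as.vector(post %*% comp$a), ab = as.vector(post %*% comp$ab))
}

#' Weighted FST as a ratio of summed components
#'
#' @param a,ab per-site (or per-window) numerator and denominator
#'   components.
#' @return `sum(a) / sum(ab)`; NA when every denominator is zero.
#' @export
weighted_fst <- function(a, ab) {
  sa <- sum(a, na.rm = TRUE)
  sab <- sum(ab, na.rm = TRUE)
  if (sab == 0) return(NA_real_)
  sa / sab
}

#' Per-window and genome-wide FST for a species pair
#'
#' Infers the shared biallelic pair on the pooled individuals, builds SAF
#' vectors per species on the common surviving sites, fits the folded 2D
#' SFS prior by EM, and accumulates posterior-expected Reynolds components
#' per window. The genome-wide estimate is the ratio of the genome-wide
#' component sums.
#'
#' @param gla [gl_array()] over all samples.
#' @param metadata sample metadata.
#' @param species_a,species_b the pair.
#' @param windows window table.
#' @param max_missing_fraction per-species site missingness tolerance.
#' @param tol,max_iter EM controls.
#' @return list: `windows` (window_id, fst, fst_num, fst_denom, n_var),
#'   `genome_fst`, `sfs2d`.
#' @export
pair_fst_scan <- function(gla, metadata, species_a, species_b, windows,
                          max_missing_fraction = 1 / 3,
                          tol = 1e-8, max_iter = 500) {
  sa <- metadata$sample_id[metadata$species == species_a]
  sb <- metadata$sample_id[metadata$species == species_b]
  stopifnot(length(sa) >= 2, length(sb) >= 2)
  mm <- infer_major_minor(gla, individuals = c(sa, sb))
  safA <- saf_matrix(gla, mm, individuals = sa,
                     max_missing_fraction = max_missing_fraction)
  safB <- saf_matrix(gla, mm, individuals = sb,
                     max_missing_fraction = max_missing_fraction)
  common <- fintersect(safA$sites[, .(scaffold, pos)],
                       safB$sites[, .(scaffold, pos)])
  ia <- safA$sites[, which(paste(scaffold, pos) %in% common[, paste(scaffold, pos)])]
  ib <- safB$sites[, which(paste(scaffold, pos) %in% common[, paste(scaffold, pos)])]
  safA$saf <- safA$saf[ia, , drop = FALSE]; safA$sites <- safA$sites[ia]
  safB$saf <- safB$saf[ib, , drop = FALSE]; safB$sites <- safB$sites[ib]
  sfs2 <- em_sfs_2d(safA, safB, folded = TRUE, tol = tol, max_iter = max_iter)
  pl <- .pair_lik(safA$saf, safB$saf, folded = TRUE)
  post <- posterior_site_spectrum(pl$lik, sfs2)
  comp <- fst_components_posterior(post, sfs2)
  wid <- assign_windows(windows, safA$sites$scaffold, safA$sites$pos)
  dt <- data.table(window_id = wid, a_comp = comp$a, ab_comp = comp$ab)
  dt <- dt[!is.na(window_id)]
  agg <- dt[, .(fst_num = sum(a_comp), fst_denom = sum(ab_comp), n_var = .N),
            by = window_id]
  agg[, fst := fifelse(fst_denom > 0, fst_num / fst_denom, NA_real_)]
  missing_w <- setdiff(windows$window_id, agg$window_id)
  if (length(missing_w)) {
    agg <- rbind(agg, data.table(window_id = missing_w, fst_num = 0,
                                 fst_denom = 0, n_var = 0L, fst = NA_real_))
  }
  setorder(agg, window_id)
  list(windows = agg[], genome_fst = weighted_fst(comp$a, comp$ab),
       sfs2d = sfs2)
}

#' Between-species population-pair FST tracks from simulated truth
#'
#' Builds the per-window FST table consumed by
#' [sympatric_allopatric_contrast()] for every between-species population
#' pair, using the certainty-limit frequency route on the simulated
#' haplotypes.
#'
#' @param sim a `sim_dataset`.
#' @return data.table `window_id`, `sp1`, `pop1`, `sp2`, `pop2`, `fst`.
#' @export
truth_pop_fst_table <- function(sim) {
  tf <- truth_allele_freqs(sim, by = "population")
  meta <- unique(data.table(sim$metadata)[, .(population, species)])
  wid <- assign_windows(sim$windows, tf$sites$scaffold, tf$sites$pos)
  pops <- colnames(tf$freq)
  out <- list()
  for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
    spi <- meta[population == pops[i], species]
    spj <- meta[population == pops[j], species]
    if (spi == spj) next
    sc <- freq_fst_scan(tf$freq, tf$n, pops[i], pops[j], wid)
    out[[length(out) + 1L]] <- data.table(
      window_id = sc$window_id, sp1 = spi, pop1 = pops[i],
      sp2 = spj, pop2 = pops[j], fst = sc$fst)
  }
  rbindlist(out)
}

#' Truth-based per-window FST between two sample groups
#'
#' Computes Reynolds components directly from known (simulated) allele
#' frequencies — the certainty-limit route, useful for population-level
#' contrasts where the full empirical-Bayes machinery is unnecessarily
#' expensive.
#'
#' @param freq site x group matrix of derived-allele frequencies.
#' @param n named vector of group sample sizes.
#' @param g1,g2 group (column) names.
#' @param window_id per-site window assignment.
#' @return data.table `window_id`, `fst`, `fst_num`, `fst_denom`.
#' @export
freq_fst_scan <- function(freq, n, g1, g2, window_id) {
  comp <- fst_components(freq[, g1], freq[, g2], n[[g1]], n[[g2]])
  dt <- data.table(window_id = window_id, a_comp = comp$a, ab_comp = comp$ab)
  agg <- dt[, .(fst_num = sum(a_comp), fst_denom = sum(ab_comp)),
            by = window_id]
  agg[, fst := fifelse(fst_denom > 0, fst_num / fst_denom, NA_real_)]
  setorder(agg, window_id)
  agg[]
}
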