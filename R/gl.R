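# Haploid genotype likelihoods from pileup observations.
#
# Model: reads are independent; a read with error probability eps supports
# its own base with probability 1 - eps and each other base with eps/3.
# Mapping quality enters as a per-read weight (1 - 10^(-MAPQ/10)) on the
# log-likelihood, a soft down-weighting of possibly misplaced reads.

#' Haploid genotype likelihood for one individual at one site
#'
#' `log L(a) = sum_r w_r * log((1 - eps_r) if base_r == a else eps_r / 3)`
#' over the four nucleotides, with `w_r = 1 - 10^(-MAPQ_r/10)` (1 when
#' `mapq` is NULL). Zero reads yield a missing individual (all-NA vector),
#' not an error.
#'
#' @param bases character vector of observed read bases.
#' @param eps per-read error probabilities in (0, 0.5].
#' @param mapq optional per-read Phred mapping qualities.
#' @return named numeric vector of log-likelihoods for A, C, G, T.
#' @export
haploid_site_gl <- function(bases, eps, mapq = NULL) {
  if (length(bases) == 0) {
    return(stats::setNames(rep(NA_real_, 4), .BASES))
  }
  stopifnot(length(eps) == length(bases) || length(eps) == 1)
  eps <- rep_len(eps, length(bases))
  if (any(eps <= 0 | eps > 0.5)) stop("error probabilities must be in (0, 0.5]")
  w <- if (is.null(mapq)) rep(1, length(bases)) else 1 - phred_to_prob(mapq)
  l1 <- log1p(-eps)
  l0 <- log(eps / 3)
  vapply(.BASES, function(b) sum(w * ifelse(bases == b, l1, l0)), 0)
}

#' Genotype likelihood table for a filtered pileup
#'
#' Vectorized version of [haploid_site_gl()] over every (site, individual)
#' with at least one read. Error probabilities come from the Phred base
#' quality of each read.
#'
#' @param pileup filtered pileup data.table (`scaffold`, `pos`, `sample_id`,
#'   `base`, `bq`, `mapq`).
#' @return data.table with per-base log-likelihood columns `llA`, `llC`,
#'   `llG`, `llT` and `depth`, keyed by (`scaffold`, `pos`, `sample_id`).
#' @export
pileup_gl <- function(pileup) {
  dt <- data.table(pileup)
  dt[, w := 1 - phred_to_prob(mapq)]
  eps <- phred_to_prob(dt$bq)
  dt[, wl1 := w * log1p(-eps)]
  dt[, wl0 := w * log(eps / 3)]
  gl <- dt[, .(
    llA = sum(fifelse(base == "A", wl1, wl0)),
    llC = sum(fifelse(base == "C", wl1, wl0)),
    llG = sum(fifelse(base == "G", wl1, wl0)),
    llT = sum(fifelse(base == "T", wl1, wl0)),
    depth = .N
  ), by = .(scaffold, pos, sample_id)]
  setkey(gl, scaffold, pos, sample_id)
  gl[]
}

#' Arrange genotype likelihoods as a sites x samples x bases array
#'
#' Missing (site, sample) combinations (no surviving reads) are NA.
#'
#' @param gl output of [pileup_gl()].
#' @param samples character vector fixing individual order.
#' @param sites data.table (`scaffold`, `pos`) fixing site order; defaults
#'   to the distinct sites of `gl`.
#' @return list of class `gl_array` with `ll` (array), `depth` (matrix),
#'   `samples`, `sites`.
#' @export
gl_array <- function(gl, samples, sites = NULL) {
  gl <- data.table(gl)
  if (is.null(sites)) {
    sites <- unique(gl[, .(scaffold, pos)])
    setorder(sites, scaffold, pos)
  } else {
    sites <- data.table(sites)[, .(scaffold, pos)]
  }
  sites[, site_i := .I]
  gl <- gl[sample_id %in% samples]
  gl <- sites[gl, on = c("scaffold", "pos"), nomatch = NULL]
  si <- gl$site_i
  pi <- match(gl$sample_id, samples)
  n_site <- nrow(sites)
  n_samp <- length(samples)
  ll <- array(NA_real_, c(n_site, n_samp, 4),
              dimnames = list(NULL, samples, .BASES))
  for (b in seq_along(.BASES)) {
    ll[cbind(si, pi, b)] <- gl[[paste0("ll", .BASES[b])]]
  }
  depth <- matrix(0L, n_site, n_samp, dimnames = list(NULL, samples))
  depth[cbind(si, pi)] <- gl$depth
  structure(list(ll = ll, depth = depth, samples = samples,
                 sites = sites[, .(scaffold, pos, site_i)]),
            class = "gl_array")
}

#' Infer the major/minor allele pair and its ML frequency
#'
#' For each site, every unordered base pair is scored by the site
#' log-likelihood maximized over the minor-allele frequency with EM over
#' individuals (`L_i(f) = (1-f) L_i(major) + f L_i(minor)`); the best pair
#' is retained (ties broken by lexicographic pair order). Individuals with
#' flat likelihoods contribute no information to the frequency. The minor
#' allele is the lower-frequency member of the pair; an exact 50/50 tie
#' keeps the lexicographically first base as major.
#'
#' @param gla a [gl_array()].
#' @param individuals optional subset of sample ids.
#' @param max_iter,tol EM controls.
#' @return data.table `site_i`, `major`, `minor`, `freq_minor`, `n_used`;
#'   `minor` is NA when the site is monomorphic with certainty
#'   (`freq_minor == 0`).
#' @export
infer_major_minor <- function(gla, individuals = NULL, max_iter = 30,
                              tol = 1e-6) {
  idx <- if (is.null(individuals)) seq_along(gla$samples)
         else match(individuals, gla$samples)
  if (anyNA(idx)) stop("unknown individuals")
  ll <- gla$ll[, idx, , drop = FALSE]
  n_site <- dim(ll)[1]
  n_ind <- dim(ll)[2]
  if (n_ind < 2) stop("need >= 2 individuals")
  # per-individual linear likelihoods normalized to max 1
  lmax <- pmax(ll[, , 1, drop = FALSE], ll[, , 2, drop = FALSE],
               ll[, , 3, drop = FALSE], ll[, , 4, drop = FALSE])
  dim(lmax) <- c(n_site, n_ind)
  P <- exp(ll - as.vector(lmax))   # recycles over base dim
  pairs <- utils::combn(4, 2)
  best_ll <- rep(-Inf, n_site)
  best_pair <- matrix(1L, n_site, 2)
  best_f <- numeric(n_site)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    La <- P[, , a, drop = FALSE]; dim(La) <- c(n_site, n_ind)
    Lb <- P[, , b, drop = FALSE]; dim(Lb) <- c(n_site, n_ind)
    f <- rep(0.5, n_site)
    for (it in seq_len(max_iter)) {
      den <- (1 - f) * La + f * Lb + 1e-300
      ratio <- (f * Lb) / den
      f_new <- rowMeans(ratio, na.rm = TRUE)
      f_new[is.nan(f_new)] <- 0
      delta <- max(abs(f_new - f), na.rm = TRUE)
      f <- f_new
      if (delta < tol) break
    }
    lp <- rowSums(log((1 - f) * La + f * Lb + 1e-300), na.rm = TRUE)
    upd <- lp > best_ll + 1e-12
    best_ll[upd] <- lp[upd]
    best_pair[upd, 1] <- a
    best_pair[upd, 2] <- b
    best_f[upd] <- f[upd]
  }
  n_used <- rowSums(!is.na(P[, , 1, drop = FALSE]))
  swap <- best_f > 0.5
  major <- ifelse(swap, best_pair[, 2], best_pair[, 1])
  minor <- ifelse(swap, best_pair[, 1], best_pair[, 2])
  fmin <- pmin(best_f, 1 - best_f)
  fmin[fmin < 1e-8] <- 0   # monomorphic with certainty
  data.table(
    site_i = seq_len(n_site),
    major = .BASES[major],
    minor = ifelse(fmin > 0, .BASES[minor], NA_character_),
    minor_base = .BASES[minor],
    freq_minor = fmin,
    n_used = as.integer(n_used)
  )
}
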