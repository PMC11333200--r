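# Infinite-sites mutation model and low-coverage read sampler.

#' Deterministic reference sequence for one window
#'
#' The background (ancestral) sequence of a window is generated from a seed
#' derived from the master seed and the window id, so it can be
#' rematerialized at any time without being stored.
#'
#' @param config a [sim_config()] object.
#' @param window_index window id.
#' @return character vector of single bases, length `window_length`.
#' @export
window_reference <- function(config, window_index) {
  set.seed(derive_seed(config$seed, 2L, as.integer(window_index)))
  sample(.BASES, config$window_length, replace = TRUE)
}

# tip descendants of every node of a phylo tree (list indexed by node id)
.tip_descendants <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Drop mutations on a genealogy and sample sequencing reads
#'
#' Mutations are Poisson with rate `mutation_rate * window_length *
#' total branch length`, placed on branches proportionally to length and on
#' positions uniformly (infinite sites: positions hit twice are redrawn, so
#' every variant is biallelic). Each sample then receives Poisson(depth_mean)
#' reads per emitted site; a read reports the true base flipped with its
#' error probability to a uniformly chosen other base, a Phred base quality
#' consistent with that error probability, and a mapping quality. A fraction
#' `filtered_read_frac` of reads is emitted with base quality 20, mapping
#' quality 30, or SAM-style flag 256 (one of the three, uniformly) so that
#' the default read filters are exercised; such reads carry the error rate
#' implied by their quality.
#'
#' @param genealogy gene tree from [simulate_window_genealogy()].
#' @param config a [sim_config()] object.
#' @param window_index window id (defaults to the genealogy attribute).
#' @return list with elements `variants` (data.table: scaffold, pos, ref,
#'   derived, window_id), `haplotypes` (character matrix sites x samples) and
#'   `pileup` (data.table: scaffold, pos, sample_id, base, bq, mapq, flag).
#' @export
mutate_and_sample_reads <- function(genealogy, config,
                                    window_index = attr(genealogy, "window_index")) {
  stopifnot(inherits(config, "sim_config"))
  w <- as.integer(window_index)
  win <- config$windows[window_id == w]
  L <- config$window_length
  ref <- window_reference(config, w)
  set.seed(derive_seed(config$seed, 3L, w))

  samples <- config$metadata$sample_id
  tree_tips <- genealogy$tip.label
  elen <- genealogy$edge.length
  total_len <- sum(elen)
  n_mut <- stats::rpois(1, config$mutation_rate * L * total_len)
  n_mut <- min(n_mut, L)

  if (n_mut == 0) {
    variants <- data.table(scaffold = character(0), pos = integer(0),
                           ref = character(0), derived = character(0),
                           window_id = integer(0))
    hap <- matrix(character(0), nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples))
    pile <- .sample_reads(variants, hap, config, w)
    return(list(variants = variants, haplotypes = hap, pileup = pile))
  }

  edges <- sample.int(nrow(genealogy$edge), n_mut, replace = TRUE,
                      prob = elen)
  pos_local <- sample.int(L, n_mut, replace = TRUE)
  while (anyDuplicated(pos_local)) {
    dup <- duplicated(pos_local)
    pos_local[dup] <- sample.int(L, sum(dup), replace = TRUE)
  }
  ord <- order(pos_local)
  pos_local <- pos_local[ord]
  edges <- edges[ord]

  anc <- ref[pos_local]
  derived <- vapply(anc, function(b) sample(setdiff(.BASES, b), 1), "")

  desc <- .tip_descendants(genealogy)
  hap <- matrix(rep(anc, length(samples)), nrow = n_mut,
                dimnames = list(NULL, samples))
  for (m in seq_len(n_mut)) {
    carriers <- tree_tips[desc[[genealogy$edge[edges[m], 2]]]]
    hap[m, carriers] <- derived[m]
  }

  variants <- data.table(
    scaffold = win$scaffold,
    pos = as.integer(win$start + pos_local),  # 1-based within scaffold
    ref = anc,
    derived = derived,
    window_id = w
  )
  pile <- .sample_reads(variants, hap, config, w, ref = ref, win = win)
  list(variants = variants, haplotypes = hap, pileup = pile)
}

# Poisson read sampler over emitted sites. Emits variant sites only, or all
# positions when config$pileup_scope == "all".
.sample_reads <- function(variants, hap, config, w, ref = NULL, win = NULL) {
  set.seed(derive_seed(config$seed, 4L, w))
  samples <- config$metadata$sample_id
  if (config$pileup_scope == "all") {
    if (is.null(ref)) ref <- window_reference(config, w)
    if (is.null(win)) win <- config$windows[window_id == w]
    pos <- as.integer(win$start + seq_len(config$window_length))
    truth <- matrix(rep(ref, length(samples)), ncol = length(samples),
                    dimnames = list(NULL, samples))
    if (nrow(hap)) truth[variants$pos - win$start, ] <- hap
    scaf <- win$scaffold
  } else {
    pos <- variants$pos
    truth <- hap
    scaf <- if (nrow(variants)) variants$scaffold[1] else character(0)
  }
  n_sites <- length(pos)
  if (n_sites == 0) {
    return(data.table(scaffold = character(0), pos = integer(0),
                      sample_id = character(0), base = character(0),
                      bq = integer(0), mapq = integer(0), flag = integer(0)))
  }
  depth <- stats::rpois(n_sites * length(samples), config$depth_mean)
  site_i <- rep(rep(seq_len(n_sites), length(samples)), depth)
  samp_i <- rep(rep(seq_along(samples), each = n_sites), depth)
  n_reads <- length(site_i)

  good_bq <- as.integer(round(prob_to_phred(max(config$base_error, 1e-9))))
  bq <- rep(good_bq, n_reads)
  mapq <- rep(60L, n_reads)
  flag <- rep(0L, n_reads)
  if (config$filtered_read_frac > 0 && n_reads > 0) {
    u <- stats::runif(n_reads)
    badkind <- sample.int(3L, n_reads, replace = TRUE)
    bad <- u < config$filtered_read_frac
    bq[bad & badkind == 1L] <- 20L
    mapq[bad & badkind == 2L] <- 30L
    flag[bad & badkind == 3L] <- 256L
  }
  eps <- phred_to_prob(bq)
  truth_base <- truth[cbind(site_i, samp_i)]
  err <- stats::runif(n_reads) < eps
  obs <- truth_base
  if (any(err)) {
    shift <- sample.int(3L, sum(err), replace = TRUE)
    obs[err] <- .BASES[((match(truth_base[err], .BASES) - 1L + shift) %% 4L) + 1L]
  }
  out <- data.table(
    scaffold = scaf,
    pos = pos[site_i],
    sample_id = samples[samp_i],
    base = obs,
    bq = bq,
    mapq = mapq,
    flag = flag
  )
  setorder(out, pos, sample_id)
  out[]
}
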