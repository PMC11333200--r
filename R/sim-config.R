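#' Default sampling locations
#'
#' Named geographic locations (decimal degrees) used by the simulator when
#' assigning populations to places: central Norway, central Austria, central
#' Germany, plus two spares for configurations with more locations.
#' @keywords internal
.SIM_LOCATIONS <- data.frame(
  location = c("L1", "L2", "L3", "L4", "L5"),
  lat = c(63.43, 47.12, 51.00, 60.39, 48.21),
  lon = c(10.40, 13.80, 10.00, 5.32, 16.37),
  stringsAsFactors = FALSE
)

#' Caterpillar species tree with evenly spaced divergence times
#'
#' Builds a rooted, ultrametric, fully pectinate (caterpillar) species tree
#' over `n_species` tips with branch lengths in generations. The most recent
#' split sits at `t_first * base_Ne` generations and successive splits are
#' `t_step * base_Ne` generations apart, so internal branches are `t_step`
#' coalescent units long at the baseline population size. Short internal
#' branches (relative to local Ne) generate incomplete lineage sorting.
#'
#' @param n_species number of tips (>= 2).
#' @param base_Ne haploid effective population size used to scale times.
#' @param t_first time of the shallowest split, in units of `base_Ne`
#'   generations.
#' @param t_step spacing between successive splits, same units.
#' @return an [ape::phylo] tree with tip labels `sp01`, `sp02`, ...
#' @export
caterpillar_species_tree <- function(n_species, base_Ne = 10000,
                                     t_first = 0.4, t_step = 0.3) {
  stopifnot(n_species >= 2)
  tips <- sprintf("sp%02d", seq_len(n_species))
  times <- (t_first + t_step * (seq_len(n_species - 1) - 1)) * base_Ne
  # nest from the shallowest pair outward
  nwk <- sprintf("%s:%g", tips[1], times[1])
  nwk <- sprintf("(%s,%s:%g)", nwk, tips[2], times[1])
  if (n_species > 2) {
    for (k in 3:n_species) {
      dt <- times[k - 1] - times[k - 2]
      nwk <- sprintf("(%s:%g,%s:%g)", nwk, dt, tips[k], times[k - 1])
    }
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Default heterogeneous gene-density profile
#'
#' A smooth deterministic profile in `[0.02, 0.98]` (one full sine period per
#' scaffold) so that linked-selection signals have a wide dynamic range while
#' remaining reproducible without randomness.
#'
#' @param windows_per_scaffold windows on each scaffold.
#' @param n_scaffolds number of scaffolds.
#' @return numeric vector of length `windows_per_scaffold * n_scaffolds`.
#' @export
gene_density_profile_default <- function(windows_per_scaffold, n_scaffolds = 1) {
  i <- seq_len(windows_per_scaffold) - 1
  one <- 0.5 + 0.48 * sin(2 * pi * i / max(windows_per_scaffold, 2))
  rep(one, n_scaffolds)
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' the species tree (branch lengths in generations), per-population sampling
#' design, mutation and sequencing-noise model, the per-window gene-density
#' profile and the linked-selection proxy `s_link` that locally rescales
#' effective population size.
#'
#' @param n_species number of species; ignored when `species_tree` is given.
#' @param samples_per_population haploid samples in each population.
#' @param n_locations geographic locations; each species has one population
#'   per location (so per-species sample size is
#'   `samples_per_population * n_locations`).
#' @param species_tree rooted ultrametric [ape::phylo] with branch lengths in
#'   generations; default [caterpillar_species_tree()].
#' @param base_Ne baseline haploid effective population size.
#' @param mutation_rate per-base per-generation mutation rate.
#' @param migration_rate pulse-admixture probability between sympatric
#'   populations (0 disables; see the methods vignette).
#' @param migration_windows integer window ids where migration applies
#'   (empty = all windows when `migration_rate > 0`).
#' @param n_scaffolds,windows_per_scaffold,window_length genome layout;
#'   scaffolds tile exactly into nonoverlapping windows.
#' @param gene_density_profile per-window genic fraction in `[0,1]`, recycled
#'   across scaffolds if shorter than the window count.
#' @param s_link linked-selection strength (>= 0) scaling local Ne reduction.
#' @param ne_floor lower bound on the Ne scaling factor (default 0.05).
#' @param depth_mean expected sequencing reads per sample per site.
#' @param base_error per-read error probability for standard reads.
#' @param filtered_read_frac fraction of reads emitted with qualities or
#'   flags at or below the default filtering thresholds (they exercise the
#'   read filters and are discarded before likelihood computation).
#' @param pileup_scope `"variant"` emits reads at segregating sites only
#'   (invariant positions are implicitly reference-certain); `"all"` emits
#'   reads at every position (small configurations only).
#' @param seed master integer seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 12,
                       samples_per_population = 2,
                       n_locations = 2,
                       species_tree = NULL,
                       base_Ne = 10000,
                       mutation_rate = 2.5e-7,
                       migration_rate = 0,
                       migration_windows = integer(0),
                       n_scaffolds = 2,
                       windows_per_scaffold = 10,
                       window_length = 1e5,
                       gene_density_profile = NULL,
                       s_link = 0,
                       ne_floor = 0.05,
                       depth_mean = 6,
                       base_error = 0.002,
                       filtered_read_frac = 0.05,
                       pileup_scope = c("variant", "all"),
                       seed = 1L) {
  pileup_scope <- match.arg(pileup_scope)
  if (is.null(species_tree)) {
    species_tree <- caterpillar_species_tree(n_species, base_Ne)
  }
  if (!inherits(species_tree, "phylo")) stop("species_tree must be a phylo object")
  if (!ape::is.rooted(species_tree)) stop("species_tree must be rooted")
  if (!ape::is.ultrametric(species_tree, tol = 1e-6)) {
    stop("species_tree must be ultrametric")
  }
  n_species <- length(species_tree$tip.label)
  n_windows <- n_scaffolds * windows_per_scaffold
  if (is.null(gene_density_profile)) {
    gene_density_profile <- gene_density_profile_default(windows_per_scaffold,
                                                         n_scaffolds)
  }
  gene_density_profile <- rep_len(gene_density_profile, n_windows)

  stopifnot(
    window_length > 0,
    samples_per_population >= 1,
    n_locations >= 1, n_locations <= nrow(.SIM_LOCATIONS),
    base_Ne > 0,
    mutation_rate > 0,
    depth_mean > 0,
    n_scaffolds >= 1, windows_per_scaffold >= 1
  )
  if (s_link < 0) stop("s_link must be >= 0")
  if (any(gene_density_profile < 0 | gene_density_profile > 1)) {
    stop("gene_density_profile values must lie in [0, 1]")
  }
  if (base_error < 0 || base_error >= 0.5) stop("base_error must be in [0, 0.5)")
  if (migration_rate < 0 || migration_rate > 1) stop("migration_rate in [0,1]")

  species <- sort(species_tree$tip.label)
  locs <- .SIM_LOCATIONS[seq_len(n_locations), ]
  metadata <- do.call(rbind, lapply(species, function(sp) {
    do.call(rbind, lapply(seq_len(n_locations), function(l) {
      data.frame(
        sample_id = sprintf("%s_%s_i%d", sp, locs$location[l],
                            seq_len(samples_per_population)),
        species = sp,
        population = sprintf("%s_%s", sp, locs$location[l]),
        location = locs$location[l],
        lat = locs$lat[l], lon = locs$lon[l],
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(metadata) <- NULL

  scaffolds <- data.frame(
    scaffold = sprintf("scaf%02d", seq_len(n_scaffolds)),
    length = windows_per_scaffold * window_length,
    stringsAsFactors = FALSE
  )
  windows <- make_windows(stats::setNames(scaffolds$length, scaffolds$scaffold),
                          window_length)
  windows$gene_density <- gene_density_profile

  cfg <- list(
    n_species = n_species,
    samples_per_population = samples_per_population,
    n_locations = n_locations,
    species_tree = species_tree,
    base_Ne = base_Ne,
    mutation_rate = mutation_rate,
    migration_rate = migration_rate,
    migration_windows = as.integer(migration_windows),
    n_scaffolds = n_scaffolds,
    windows_per_scaffold = windows_per_scaffold,
    window_length = as.integer(window_length),
    gene_density_profile = gene_density_profile,
    s_link = s_link,
    ne_floor = ne_floor,
    depth_mean = depth_mean,
    base_error = base_error,
    filtered_read_frac = filtered_read_frac,
    pileup_scope = pileup_scope,
    seed = as.integer(seed),
    metadata = metadata,
    scaffolds = scaffolds,
    windows = windows
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d species, %d samples each, %d windows of %d bp, s_link=%g, seed=%d\n",
    x$n_species, x$samples_per_population * x$n_locations,
    nrow(x$windows), x$window_length, x$s_link, x$seed))
  invisible(x)
}

#' Local effective population size under the gene-density proxy
#'
#' Linked selection removes diversity near selection targets; the simulator
#' proxies this with a deterministic reduction of the local effective
#' population size proportional to the genic fraction of the window:
#' `Ne_local = base_Ne * max(f_min, 1 - s_link * gene_density)`.
#' The reduction is monotone non-increasing in gene density.
#'
#' @param gene_density genic fraction of the window, in `[0, 1]`.
#' @param base_Ne baseline haploid Ne.
#' @param s_link selection-strength scaling (>= 0).
#' @param f_min floor on the scaling factor.
#' @return local haploid Ne (numeric, same length as `gene_density`).
#' @export
scale_ne_by_gene_density <- function(gene_density, base_Ne, s_link,
                                     f_min = 0.05) {
  if (any(s_link < 0)) stop("s_link must be >= 0")
  if (any(gene_density < 0 | gene_density > 1)) {
    stop("gene_density must lie in [0, 1]")
  }
  base_Ne * pmax(f_min, 1 - s_link * gene_density)
}
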