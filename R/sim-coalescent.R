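# Multispecies-coalescent genealogy simulator.
#
# Times are measured in generations, populations are haploid, and the
# pairwise coalescence rate inside a population of size N is 1/N per
# generation (so one coalescent unit = N generations). Local Ne for a
# window is obtained from scale_ne_by_gene_density() and applied uniformly
# to every branch of the species tree, including ancestral populations.

#' Node times of a rooted tree (tips at time 0)
#' @keywords internal
.node_times <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

# Run the Kingman coalescent for one species-tree branch.
# env holds the growing gene tree: $time (node times), $left/$right
# (children), $count (next node id). Returns surviving lineage ids.
.coalesce_branch <- function(env, lineages, t_from, t_to, N) {
  k <- length(lineages)
  t <- t_from
  while (k >= 2) {
    rate <- k * (k - 1) / 2 / N
    t <- t + stats::rexp(1, rate)
    if (t >= t_to) break
    pick <- sample.int(k, 2)
    id <- env$count <- env$count + 1L
    env$time[id] <- t
    env$left[id] <- lineages[pick[1]]
    env$right[id] <- lineages[pick[2]]
    lineages <- c(lineages[-pick], id)
    k <- k - 1L
  }
  lineages
}

#' Simulate one gene genealogy under the multispecies coalescent
#'
#' Samples a genealogy for all configured samples in one genomic window.
#' Within each species-tree branch, lineages coalesce at rate
#' `choose(k,2)/Ne_local`; unresolved lineages are handed to the parent
#' population at speciation times, and remaining lineages coalesce freely
#' above the root. When `migration_rate > 0` and the window is eligible, a
#' pulse admixture step at sampling time moves each lineage from a sympatric
#' population into a uniformly chosen other species at the same location
#' with probability `migration_rate`.
#'
#' @param config a [sim_config()] object.
#' @param window_index window id (1-based) selecting gene density and seed.
#' @return an [ape::phylo] gene tree over all sample ids, with branch
#'   lengths in generations and attributes `local_Ne` and `window_index`.
#' @export
simulate_window_genealogy <- function(config, window_index) {
  stopifnot(inherits(config, "sim_config"))
  w <- as.integer(window_index)
  gd <- config$gene_density_profile[w]
  N <- scale_ne_by_gene_density(gd, config$base_Ne, config$s_link,
                                config$ne_floor)
  set.seed(derive_seed(config$seed, 1L, w))

  sptree <- config$species_tree
  n_sp <- length(sptree$tip.label)
  times <- .node_times(sptree)
  meta <- config$metadata

  # species membership of each sample lineage, with optional pulse admixture
  sample_species <- meta$species
  names(sample_species) <- meta$sample_id
  migrate <- config$migration_rate > 0 &&
    (length(config$migration_windows) == 0 || w %in% config$migration_windows)
  if (migrate) {
    for (i in seq_len(nrow(meta))) {
      if (stats::runif(1) < config$migration_rate) {
        others <- unique(meta$species[meta$location == meta$location[i] &
                                        meta$species != meta$species[i]])
        if (length(others)) {
          sample_species[meta$sample_id[i]] <- others[sample.int(length(others), 1)]
        }
      }
    }
  }

  n_samples <- nrow(meta)
  max_nodes <- 2L * n_samples
  env <- new.env()
  env$time <- numeric(max_nodes)
  env$left <- integer(max_nodes)
  env$right <- integer(max_nodes)
  env$count <- n_samples

  # lineages waiting in each species-tree node's subtending branch
  lin <- vector("list", n_sp + sptree$Nnode)
  for (s in seq_len(n_sp)) {
    sp <- sptree$tip.label[s]
    lin[[s]] <- which(sample_species == sp)
  }
  node_order <- order(times[(n_sp + 1):(n_sp + sptree$Nnode)]) + n_sp
  parent_of <- integer(n_sp + sptree$Nnode)
  parent_of[sptree$edge[, 2]] <- sptree$edge[, 1]
  root <- n_sp + 1L

  for (v in node_order) {
    ch <- sptree$edge[sptree$edge[, 1] == v, 2]
    pooled <- integer(0)
    for (c in ch) {
      pooled <- c(pooled, .coalesce_branch(env, lin[[c]], times[c], times[v], N))
    }
    lin[[v]] <- pooled
  }
  surv <- .coalesce_branch(env, lin[[root]], times[root], Inf, N)
  stopifnot(length(surv) == 1)

  # assemble newick bottom-up (merge events are already in time order)
  lab <- character(env$count)
  lab[seq_len(n_samples)] <- meta$sample_id
  if (env$count > n_samples) {
    for (id in (n_samples + 1L):env$count) {
      l <- env$left[id]; r <- env$right[id]
      lab[id] <- sprintf("(%s:%.8f,%s:%.8f)", lab[l], env$time[id] - env$time[l],
                         lab[r], env$time[id] - env$time[r])
    }
  }
  tree <- ape::read.tree(text = paste0(lab[surv], ";"))
  attr(tree, "local_Ne") <- N
  attr(tree, "window_index") <- w
  tree
}

#' Simulate genealogies for a set of windows
#'
#' @param config a [sim_config()] object.
#' @param windows integer window ids; default all windows in the config.
#' @return list of gene trees (one per window), named by window id.
#' @export
simulate_window_genealogies <- function(config, windows = NULL) {
  if (is.null(windows)) windows <- config$windows$window_id
  out <- lapply(windows, function(w) simulate_window_genealogy(config, w))
  names(out) <- as.character(windows)
  out
}
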