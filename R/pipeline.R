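# End-to-end orchestration: observable inputs -> per-window statistic
# tracks -> landscape summaries.

#' Analyze a dataset from the pileup level upward
#'
#' Runs the full analysis chain on observable inputs: read/site filtering,
#' haploid genotype likelihoods, per-species empirical-Bayes diversity
#' scans, per-pair 2D-SFS FST scans, EBD consensus and dXY, neighbor-
#' joining window trees scored against the species tree, gene-density
#' tracks, and the Spearman correlation structure of the mean landscapes.
#'
#' @param pileup pileup data.table (`scaffold`, `pos`, `sample_id`, `base`,
#'   `bq`, `mapq`, `flag`).
#' @param metadata sample metadata (`sample_id`, `species`, `population`,
#'   `location`, optional `lat`/`lon`).
#' @param windows window table from [make_windows()].
#' @param species_tree species-labelled [ape::phylo] (used for the
#'   discordance scan; NULL skips trees).
#' @param genes gene intervals (0-based half-open) or NULL.
#' @param filters a [filter_config()].
#' @param em_tol,em_max_iter EM controls passed to the SFS fits.
#' @param tree_distance distance model for [nj_tree()].
#' @param boot_se bootstrap resamples for [correlation_structure()].
#' @param seed seed for the seeded downstream statistics.
#' @return list with `theta` (long per species), `fst` (long per pair),
#'   `dxy` (long per pair), `discordance`, `pinf` (parsimony-informative
#'   counts), `gene_track`, `tracks` (merged mean per-window tracks),
#'   `correlation` (correlation_structure output), `genome_fst` (matrix),
#'   `pca` (landscape PCA per statistic), `n_sites_used`.
#' @export
analyze_dataset <- function(pileup, metadata, windows, species_tree = NULL,
                            genes = NULL, filters = filter_config(),
                            em_tol = 1e-8, em_max_iter = 500,
                            tree_distance = "raw", boot_se = 200,
                            seed = 1) {
  metadata <- as.data.frame(metadata)
  species <- sort(unique(metadata$species))
  win <- data.table(windows)
  L <- win$end[1] - win$start[1]

  filt <- filter_observations(pileup, filters, samples = metadata$sample_id)
  gl <- pileup_gl(filt$pileup)
  gla <- gl_array(gl, metadata$sample_id)

  theta <- list(); sfs_list <- list()
  for (sp in species) {
    sc <- species_theta_scan(gla, metadata, sp, win,
                             max_missing_fraction = filters$max_missing_fraction,
                             tol = em_tol, max_iter = em_max_iter)
    theta[[sp]] <- sc$windows
    sfs_list[[sp]] <- sc$sfs
  }
  theta <- rbindlist(theta)

  pairs <- t(utils::combn(species, 2))
  fst_long <- list()
  genome_fst <- matrix(NA_real_, length(species), length(species),
                       dimnames = list(species, species))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    sc <- pair_fst_scan(gla, metadata, a, b, win,
                        max_missing_fraction = filters$max_missing_fraction,
                        tol = em_tol, max_iter = em_max_iter)
    dtp <- sc$windows
    dtp[, `:=`(sp1 = a, sp2 = b)]
    fst_long[[p]] <- dtp
    genome_fst[a, b] <- genome_fst[b, a] <- sc$genome_fst
  }
  fst_long <- rbindlist(fst_long)

  cons <- consensus_matrix(filt$pileup, metadata$sample_id, gla$sites)
  dxy_long <- dxy_scan(cons, gla$sites, metadata, win)

  disc <- NULL; pinf <- NULL
  if (!is.null(species_tree)) {
    wid <- assign_windows(win, gla$sites$scaffold, gla$sites$pos)
    sp_ref <- ape::unroot(species_tree)
    trees <- vector("list", nrow(win))
    names(trees) <- as.character(win$window_id)
    pinf <- data.table(window_id = win$window_id, pinf = NA_integer_)
    for (k in seq_len(nrow(win))) {
      rows <- which(wid == win$window_id[k])
      if (length(rows) < 2) next
      sub <- t(cons[rows, , drop = FALSE])  # samples x sites
      pinf$pinf[k] <- parsimony_informative_sites(sub)
      tr <- try(nj_tree(sub, distance = tree_distance, total_length = L),
                silent = TRUE)
      if (inherits(tr, "try-error")) next
      trees[[k]] <- prune_to_species(tr, metadata)
    }
    disc <- discordance_scan(trees, sp_ref)
  }

  gene_track <- gene_density_track(genes, win)

  # mean per-window tracks across species / pairs
  tracks <- data.table(window_id = win$window_id)
  tracks <- merge(tracks,
                  theta[, .(pi = mean(pi_site),
                            tajima_d = mean(tajima_d, na.rm = TRUE)),
                        by = window_id], by = "window_id", all.x = TRUE)
  tracks <- merge(tracks,
                  fst_long[, .(fst = mean(fst, na.rm = TRUE)), by = window_id],
                  by = "window_id", all.x = TRUE)
  tracks <- merge(tracks,
                  dxy_long[, .(dxy = mean(dxy, na.rm = TRUE)), by = window_id],
                  by = "window_id", all.x = TRUE)
  tracks <- merge(tracks, gene_track, by = "window_id", all.x = TRUE)
  if (!is.null(disc)) {
    tracks <- merge(tracks, disc[, .(window_id, discordance = score)],
                    by = "window_id", all.x = TRUE)
  }
  corr_cols <- setdiff(names(tracks), "window_id")
  corr <- correlation_structure(tracks[, corr_cols, with = FALSE],
                                n_boot = boot_se, seed = seed)

  pca <- list()
  pca$pi <- try(landscape_pca(build_landscape_matrix(
    theta[, .(window_id, column = species, value = pi_site)])), silent = TRUE)
  pca$fst <- try(landscape_pca(build_landscape_matrix(
    fst_long[, .(window_id, column = paste(sp1, sp2, sep = ":"),
                 value = fst)])), silent = TRUE)
  pca$dxy <- try(landscape_pca(build_landscape_matrix(
    dxy_long[, .(window_id, column = paste(sp1, sp2, sep = ":"),
                 value = dxy)])), silent = TRUE)

  list(theta = theta, fst = fst_long, dxy = dxy_long, discordance = disc,
       pinf = pinf, gene_track = gene_track, tracks = tracks,
       correlation = corr, genome_fst = genome_fst, pca = pca,
       n_sites_used = nrow(gla$sites))
}

#' Demo pipeline configuration
#'
#' A small self-contained configuration (4 species, 2 populations of 2
#' samples each, 40 windows of 2 kb, moderate linked selection) that runs
#' the full pipeline in well under a minute.
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1) {
  sim_config(
    n_species = 4, samples_per_population = 2, n_locations = 2,
    base_Ne = 8000, mutation_rate = 3e-7,
    n_scaffolds = 2, windows_per_scaffold = 20, window_length = 2000,
    s_link = 0.8, depth_mean = 6, base_error = 0.002, seed = seed
  )
}

#' Run the full pipeline from a configuration
#'
#' Stages: simulate -> filter/GL -> per-species and per-pair scans ->
#' consensus/dXY -> window trees and discordance -> landscapes and
#' correlation structure -> spatial autocorrelation. Outputs are written
#' as fixed-column-order TSVs plus a JSON run manifest (configuration
#' snapshot, seeds, stage timings, output registry with MD5 checksums).
#' Masked values are written as ".".
#'
#' @param config a [sim_config()], or a path to a YAML file whose keys are
#'   [sim_config()] arguments (plus optional `lag`, `n_perm`).
#' @param out_dir output directory.
#' @param lag autocorrelation lag in windows.
#' @param n_perm permutations for the autocorrelation null.
#' @return (invisibly) the `analyze_dataset()` result.
#' @export
run_pipeline <- function(config, out_dir, lag = 3, n_perm = 200) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    lag <- args$lag %||% lag
    n_perm <- args$n_perm %||% n_perm
    args <- args[intersect(names(args), names(formals(sim_config)))]
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()

  sim <- simulate_dataset(config)
  timings$simulate <- proc.time()[["elapsed"]] - t0

  res <- analyze_dataset(sim$pileup, sim$metadata, sim$windows,
                         species_tree = sim$species_tree, genes = sim$genes,
                         em_tol = 1e-6, em_max_iter = 200,
                         seed = config$seed)
  timings$analyze <- proc.time()[["elapsed"]] - t0 - timings$simulate

  ac <- autocorr_permutation_null(
    merge(sim$windows[, .(window_id, scaffold, index)],
          res$tracks[, .(window_id, value = pi)], by = "window_id"),
    lag = lag, n_perm = max(n_perm, 100), seed = derive_seed(config$seed, 9L))
  timings$autocorr <- proc.time()[["elapsed"]] - t0 - timings$simulate -
    timings$analyze

  paths <- c(tracks = file.path(out_dir, "window_tracks.tsv"),
             theta = file.path(out_dir, "theta_by_species.tsv"),
             fst = file.path(out_dir, "fst_by_pair.tsv"),
             dxy = file.path(out_dir, "dxy_by_pair.tsv"),
             autocorr = file.path(out_dir, "autocorrelation.tsv"),
             correlation = file.path(out_dir, "correlation_structure.tsv"))
  w_na <- function(dt, path) fwrite(dt, path, sep = "\t", na = ".")
  w_na(res$tracks, paths[["tracks"]])
  w_na(res$theta, paths[["theta"]])
  w_na(res$fst, paths[["fst"]])
  w_na(res$dxy, paths[["dxy"]])
  w_na(ac$result, paths[["autocorr"]])
  rmat <- res$correlation$r
  w_na(data.table(statistic = rownames(rmat), rmat), paths[["correlation"]])

  manifest <- list(
    package = "glscape",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config),
                            c("species_tree", "metadata", "scaffolds",
                              "windows"))],
    species_tree = ape::write.tree(config$species_tree),
    lag = lag, n_perm = n_perm,
    timings_sec = lapply(timings, round, 2),
    outputs = lapply(as.list(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
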