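# End-to-end synthetic dataset generation with ground truth.

#' Realize a gene annotation from the gene-density profile
#'
#' Each window receives `round(density * window_length / gene_length)`
#' nonoverlapping genes of fixed length, spaced evenly, so the realized
#' per-window coverage approximates the configured profile and gene count
#' co-varies with gene density.
#'
#' @param config a [sim_config()] object.
#' @param gene_length gene size in bp (default `window_length / 20`).
#' @return data.table of 0-based half-open gene intervals
#'   (`scaffold`, `start`, `end`, `gene_id`).
#' @export
realize_gene_annotation <- function(config, gene_length = NULL) {
  L <- config$window_length
  if (is.null(gene_length)) gene_length <- max(20L, L %/% 20L)
  out <- list()
  for (i in seq_len(nrow(config$windows))) {
    win <- config$windows[i]
    f <- config$gene_density_profile[win$window_id]
    n_genes <- round(f * L / gene_length)
    if (n_genes == 0) next
    gap <- (L - n_genes * gene_length) / n_genes
    starts <- win$start + floor((seq_len(n_genes) - 1) * (gene_length + gap) +
                                  gap / 2)
    out[[length(out) + 1L]] <- data.table(
      scaffold = win$scaffold,
      start = as.integer(starts),
      end = as.integer(starts + gene_length),
      gene_id = sprintf("gene_%d_%d", win$window_id, seq_len(n_genes))
    )
  }
  if (!length(out)) {
    return(data.table(scaffold = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0)))
  }
  rbindlist(out)
}

#' Simulate a complete multispecies dataset with known truth
#'
#' Runs the multispecies coalescent for every window, drops infinite-sites
#' mutations, samples noisy low-coverage reads, and realizes the gene
#' annotation. The returned bundle carries both the observable data (pileup,
#' annotation, metadata, species tree) and the simulation truth (gene trees,
#' local Ne, haplotypes) used by parameter-recovery tests.
#'
#' @param config a [sim_config()] object.
#' @param windows optional subset of window ids.
#' @return list of class `sim_dataset` with elements `config`, `metadata`,
#'   `species_tree`, `windows` (incl. gene_density and local_Ne), `genes`,
#'   `variants`, `haplotypes` (site x sample character matrix), `pileup`,
#'   and `gene_trees`.
#' @export
simulate_dataset <- function(config, windows = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(windows)) windows <- config$windows$window_id
  gts <- vector("list", length(windows))
  vars <- vector("list", length(windows))
  haps <- vector("list", length(windows))
  piles <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[i]
    gt <- simulate_window_genealogy(config, w)
    mm <- mutate_and_sample_reads(gt, config, w)
    gts[[i]] <- gt
    vars[[i]] <- mm$variants
    haps[[i]] <- mm$haplotypes
    piles[[i]] <- mm$pileup
  }
  win <- data.table(config$windows)[window_id %in% windows]
  win[, local_Ne := scale_ne_by_gene_density(gene_density, config$base_Ne,
                                             config$s_link, config$ne_floor)]
  structure(list(
    config = config,
    metadata = config$metadata,
    species_tree = config$species_tree,
    windows = win,
    genes = realize_gene_annotation(config),
    variants = rbindlist(vars),
    haplotypes = do.call(rbind, haps),
    pileup = rbindlist(piles),
    gene_trees = stats::setNames(gts, as.character(windows))
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d samples, %d windows, %d variant sites, %d reads\n",
              nrow(x$metadata), nrow(x$windows), nrow(x$variants),
              nrow(x$pileup)))
  invisible(x)
}

#' True derived-allele frequencies per group
#'
#' Computes, from the simulated haplotype matrix, the derived-allele sample
#' frequency of every variant site in each species or population. Used for
#' truth-based estimator checks and for fast differentiation scans that
#' bypass the read level.
#'
#' @param sim a [simulate_dataset()] result.
#' @param by `"species"` or `"population"`.
#' @return list with `freq` (site x group matrix), `n` (samples per group),
#'   and `sites` (the variants table).
#' @export
truth_allele_freqs <- function(sim, by = c("species", "population")) {
  by <- match.arg(by)
  groups <- split(sim$metadata$sample_id, sim$metadata[[by]])
  der <- sim$haplotypes == sim$variants$derived
  freq <- vapply(groups, function(s) rowMeans(der[, s, drop = FALSE]),
                 numeric(nrow(sim$variants)))
  if (nrow(sim$variants) == 1) freq <- matrix(freq, nrow = 1,
                                              dimnames = list(NULL, names(groups)))
  list(freq = freq, n = vapply(groups, length, 1L), sites = sim$variants)
}

#' Materialize full per-window alignments from the simulation truth
#'
#' @param sim a [simulate_dataset()] result.
#' @param window_index window id.
#' @return character matrix samples x positions (true haplotype sequences).
#' @export
true_window_alignment <- function(sim, window_index) {
  cfg <- sim$config
  win <- cfg$windows[window_id == as.integer(window_index)]
  ref <- window_reference(cfg, win$window_id)
  samples <- sim$metadata$sample_id
  aln <- matrix(rep(ref, each = length(samples)), nrow = length(samples),
                dimnames = list(samples, NULL))
  v <- sim$variants[window_id == win$window_id]
  if (nrow(v)) {
    idx <- v$pos - win$start
    sel <- which(sim$variants$window_id == win$window_id)
    aln[, idx] <- t(sim$haplotypes[sel, , drop = FALSE])
  }
  aln
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the complete file set the analysis pipeline consumes: the pileup
#' GL TSV, a per-window multi-FASTA of true haplotype alignments, the BED
#' gene annotation, the Newick species tree, the sample metadata TSV, and a
#' JSON truth file (gene trees, local Ne, gene-density profile). All files
#' round-trip losslessly through the package readers.
#'
#' @param config a [sim_config()] object (or an existing `sim_dataset`).
#' @param output_dir writable directory (created if needed).
#' @return (invisibly) named character vector of the files written.
#' @export
write_fixture_bundle <- function(config, output_dir) {
  sim <- if (inherits(config, "sim_dataset")) config else simulate_dataset(config)
  cfg <- sim$config
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output_dir: ", output_dir)
  paths <- c(
    pileup = file.path(output_dir, "pileup.tsv"),
    metadata = file.path(output_dir, "metadata.tsv"),
    species_tree = file.path(output_dir, "species_tree.nwk"),
    genes = file.path(output_dir, "genes.bed"),
    truth = file.path(output_dir, "truth.json")
  )
  write_gl_tsv(sim$pileup, paths[["pileup"]])
  fwrite(data.table(sim$metadata), paths[["metadata"]], sep = "\t")
  ape::write.tree(sim$species_tree, file = paths[["species_tree"]])
  write_bed(sim$genes, paths[["genes"]])
  win_dir <- file.path(output_dir, "windows")
  dir.create(win_dir, showWarnings = FALSE)
  fasta_paths <- character(0)
  for (w in sim$windows$window_id) {
    win <- sim$windows[window_id == w]
    aln <- true_window_alignment(sim, w)
    fp <- file.path(win_dir, sprintf("%s_%d_%d.fasta", win$scaffold,
                                     win$start, win$end))
    write_window_fasta(aln, fp)
    fasta_paths <- c(fasta_paths, fp)
  }
  truth <- list(
    seed = cfg$seed,
    base_Ne = cfg$base_Ne,
    mutation_rate = cfg$mutation_rate,
    s_link = cfg$s_link,
    window_length = cfg$window_length,
    gene_density = cfg$gene_density_profile,
    local_Ne = sim$windows$local_Ne,
    gene_trees = vapply(sim$gene_trees, ape::write.tree, "")
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(c(paths, stats::setNames(fasta_paths, basename(fasta_paths))))
}
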