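test_that("local Ne scaling follows the gene-density proxy", {
  expect_equal(scale_ne_by_gene_density(0, 10000, 2), 10000)
  expect_equal(scale_ne_by_gene_density(0.9, 10000, 0), 10000)
  expect_equal(scale_ne_by_gene_density(0.5, 10000, 1, f_min = 0.05), 5000)
  expect_equal(scale_ne_by_gene_density(1, 10000, 5, f_min = 0.05), 500)
  gd <- seq(0, 1, by = 0.1)
  ne <- scale_ne_by_gene_density(gd, 10000, 0.8)
  expect_true(all(diff(ne) <= 0))
  expect_error(scale_ne_by_gene_density(0.5, 10000, -1), "s_link")
  expect_error(scale_ne_by_gene_density(1.5, 10000, 1), "gene_density")
})

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(base_error = 0.6), "base_error")
  expect_error(sim_config(gene_density_profile = c(0.5, 1.2)), "gene_density")
  expect_error(sim_config(s_link = -0.1), "s_link")
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:2);")  # not ultrametric
  expect_error(sim_config(species_tree = tr), "ultrametric")
})

test_that("genealogy simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_species = 4, samples_per_population = 2,
                    n_locations = 2, n_scaffolds = 1,
                    windows_per_scaffold = 5, window_length = 1000, seed = 42)
  g1 <- simulate_window_genealogies(cfg)
  g2 <- simulate_window_genealogies(cfg)
  expect_identical(vapply(g1, ape::write.tree, ""),
                   vapply(g2, ape::write.tree, ""))
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pileup, s2$pileup)
  expect_identical(s1$haplotypes, s2$haplotypes)
})

test_that("deep species divergence leaves no ILS", {
  # 3 species, internal branch of 8 coalescent units: discordance ~ e^-8
  N <- 5000
  tr <- ape::read.tree(text = sprintf(
    "((A:%d,B:%d):%d,C:%d);", N, N, 8 * N, 9 * N))
  cfg <- sim_config(species_tree = tr, samples_per_population = 1,
                    n_locations = 1, base_Ne = N, n_scaffolds = 1,
                    windows_per_scaffold = 50, window_length = 100, seed = 3)
  for (w in 1:50) {
    gt <- simulate_window_genealogy(cfg, w)
    d <- ape::cophenetic.phylo(gt)
    labs <- sub("_L1_i1", "", rownames(d))
    rownames(d) <- colnames(d) <- labs
    expect_true(d["A", "B"] < d["A", "C"] & d["A", "B"] < d["B", "C"])
  }
})

test_that("3-taxon topology frequencies match the coalescent closed form", {
  # P(concordant) = 1 - (2/3) exp(-T), T in coalescent units
  N <- 10000
  for (T in c(0.1, 0.5, 2)) {
    tr <- ape::read.tree(text = sprintf(
      "((A:%f,B:%f):%f,C:%f);", 0.5 * N, 0.5 * N, T * N, (0.5 + T) * N))
    cfg <- sim_config(species_tree = tr, samples_per_population = 1,
                      n_locations = 1, base_Ne = N, n_scaffolds = 1,
                      windows_per_scaffold = 3000, window_length = 100,
                      seed = 1)
    conc <- 0L
    for (w in 1:3000) {
      gt <- simulate_window_genealogy(cfg, w)
      d <- ape::cophenetic.phylo(gt)
      labs <- sub("_L1_i1", "", rownames(d))
      rownames(d) <- colnames(d) <- labs
      conc <- conc + (d["A", "B"] <= d["A", "C"] &
                        d["A", "B"] <= d["B", "C"])
    }
    expect_lt(abs(conc / 3000 - (1 - (2 / 3) * exp(-T))), 0.03)
  }
})

test_that("segregating-site density matches the Watterson expectation", {
  # E[S] = theta * a1 * L with theta = 2 Ne mu per site
  cfg <- sim_config(n_species = 2, samples_per_population = 5,
                    n_locations = 1, base_Ne = 10000,
                    mutation_rate = 1.25e-7, n_scaffolds = 1,
                    windows_per_scaffold = 500, window_length = 1000,
                    depth_mean = 1, seed = 8,
                    species_tree = caterpillar_species_tree(
                      2, 10000, t_first = 4))
  sim <- simulate_dataset(cfg)
  n <- 5
  a1 <- sum(1 / seq_len(n - 1))
  theta <- 2 * cfg$base_Ne * cfg$mutation_rate
  est <- vapply(c("sp01", "sp02"), function(sp) {
    samp <- sim$metadata$sample_id[sim$metadata$species == sp]
    seg <- apply(sim$haplotypes[, samp], 1,
                 function(z) length(unique(z)) > 1)
    sum(seg) / 500 / (a1 * cfg$window_length)
  }, 0)
  expect_lt(abs(mean(est) / theta - 1), 0.05)
})

test_that("read sampler honours the certainty limit and single samples", {
  tr <- ape::read.tree(text = "(A:5000,B:5000);")
  cfg <- sim_config(species_tree = tr, samples_per_population = 1,
                    n_locations = 1, base_Ne = 5000, mutation_rate = 1e-6,
                    n_scaffolds = 1, windows_per_scaffold = 2,
                    window_length = 500, depth_mean = 50,
                    base_error = 1e-9, filtered_read_frac = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  # majority pileup base equals the true haplotype at every site
  pl <- sim$pileup
  key <- paste(pl$scaffold, pl$pos, pl$sample_id)
  maj <- tapply(pl$base, key, function(b) names(which.max(table(b))))
  vkey <- paste(sim$variants$scaffold, sim$variants$pos)
  for (s in sim$metadata$sample_id) {
    kk <- paste(vkey, s)
    got <- maj[kk]
    expect_true(all(got == sim$haplotypes[, s], na.rm = TRUE))
  }
  # a single haploid sample has zero segregating sites within itself
  expect_true(all(apply(sim$haplotypes[, 1, drop = FALSE], 1,
                        function(z) length(unique(z))) == 1))
})

test_that("fixture bundle round-trips through the package readers", {
  cfg <- sim_config(n_species = 2, samples_per_population = 2,
                    n_locations = 1, n_scaffolds = 1,
                    windows_per_scaffold = 3, window_length = 300,
                    gene_density_profile = c(0, 1, 0), seed = 4)
  dir <- withr::local_tempdir()
  files <- write_fixture_bundle(cfg, dir)
  sim <- simulate_dataset(cfg)

  pl <- read_gl_tsv(files[["pileup"]])
  orig <- data.table::copy(sim$pileup)
  data.table::setorder(orig, scaffold, pos, sample_id)
  data.table::setorder(pl, scaffold, pos, sample_id)
  expect_equal(pl$pos, orig$pos)
  expect_equal(pl$base, orig$base)

  md <- read_metadata_tsv(files[["metadata"]])
  expect_equal(md$sample_id, sim$metadata$sample_id)

  tr <- ape::read.tree(files[["species_tree"]])
  expect_equal(sort(tr$tip.label), sort(cfg$species_tree$tip.label))

  genes <- read_annotation(files[["genes"]])
  gd <- gene_density_track(genes, sim$windows)
  expect_equal(gd$gene_density, c(0, 1, 0), tolerance = 1e-9)

  # one FASTA record per sample in every window file
  fa <- list.files(file.path(dir, "windows"), full.names = TRUE)
  expect_length(fa, 3)
  for (f in fa) {
    aln <- read_window_fasta(f)
    expect_equal(nrow(aln), nrow(sim$metadata))
    expect_equal(ncol(aln), cfg$window_length)
  }

  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, cfg$seed)
  expect_length(truth$gene_trees, 3)
})
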