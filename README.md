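# glscape

Correlated genomic landscapes from haploid genotype likelihoods.

`glscape` is an R package for population-genomic landscape analysis in
haploid species sequenced at low depth, where genotypes cannot be called
reliably and inference must run on genotype likelihoods. It asks the
question posed by multi-species resequencing studies of clades with
conserved genome architecture: are the genomic landscapes of diversity,
divergence and differentiation correlated across species, and are they
structured by gene density in the way recurrent linked selection
predicts?

From pileup-level observations the package computes, per species and per
100-kb-style nonoverlapping window:

* haploid genotype likelihoods (independent-error model, mapping-quality
  weighting) with the standard exclusive quality filters (MAPQ ≤ 30,
  BQ ≤ 20, flag ≥ 256, per-individual depth outside [2, 100], sites
  missing in more than ⅓ of individuals);
* site-allele-frequency (SAF) vectors by the O(n²) dynamic programming,
  maximum-likelihood **folded 1D and 2D site-frequency spectra** by EM,
  and empirical-Bayes per-site posteriors under the genome-wide SFS
  prior;
* window **θπ, θW** as linear functions of the folded posteriors and
  **Tajima's D** = (θπ − θW)/√(e₁S + e₂S(S−1));
* **weighted FST** from posterior-expected method-of-moments components
  (haploid Reynolds-type algebra; ratio of summed components);
* effective-base-depth (EBD) **consensus sequences**, per-window
  multi-sample alignments, and **dXY** with pairwise N-masking;
* neighbor-joining **window trees** (or externally supplied Newick),
  pruned to one sample per species and scored against the species tree
  with the **Robinson–Foulds partition metric** (0 … 2(L−3)), with >2 SD
  outlier flagging and parsimony-informative-site controls;
* **landscape PCA** (windows × species or × the 66 pairs of 12 species;
  PC1 variance fraction and loadings, sign-anchored to the mean
  landscape), Spearman **correlation structure** with Benjamini–Hochberg
  adjustment, lagged **spatial autocorrelation** with a 1000-permutation
  null, **Mantel tests**, and the **sympatric–allopatric FST contrast**
  summarized by PCA.

A multispecies-coalescent simulator with gene-density-modulated local Ne
(`sim_config()`, `simulate_dataset()`, `write_fixture_bundle()`)
generates genome-scale haploid datasets with known truth — species tree
with incomplete lineage sorting, per-window gene trees, local-Ne
profile, haplotypes, noisy low-coverage reads — so the whole chain is
testable against oracles.

## Worked example

Simulate 4 species × 4 haploid samples on 100 windows with strong
linked selection (`s_link = 0.8`), then run the full analysis from the
read level:

```r
library(glscape)
cfg <- sim_config(n_species = 4, samples_per_population = 2,
                  n_locations = 2, base_Ne = 10000,
                  mutation_rate = 2.5e-7, n_scaffolds = 2,
                  windows_per_scaffold = 50, window_length = 4000,
                  s_link = 0.8, depth_mean = 6, seed = 1)
sim <- simulate_dataset(cfg)
#> sim_dataset: 16 samples, 100 windows, 9347 variant sites, 898934 reads
res <- analyze_dataset(sim$pileup, sim$metadata, sim$windows,
                       species_tree = sim$species_tree, genes = sim$genes,
                       em_tol = 1e-6, em_max_iter = 300, boot_se = 0)
head(res$tracks[, c("window_id", "pi", "tajima_d", "fst", "dxy",
                    "gene_density", "discordance")], 4)
#>    window_id          pi    tajima_d       fst         dxy gene_density discordance
#> 1:         1 0.003358787  0.26442609 0.4825581 0.006666055         0.50           0
#> 2:         2 0.003265441  0.18494307 0.4957738 0.006713891         0.55           2
#> 3:         3 0.002754306 -0.56131289 0.7075358 0.010996178         0.60           0
#> 4:         4 0.001677631 -0.05909004 0.6364609 0.004198132         0.70           2
```

`pi` and `dxy` are per-site means over species/pairs, `fst` the mean
per-window weighted FST over the 6 species pairs, `discordance` the
partition-metric score of the window tree against the species tree.
The linked-selection sign structure comes out of the correlation
structure (Spearman r with BH-adjusted p):

```r
round(res$correlation$r[c("pi", "fst", "dxy", "discordance"),
                        "gene_density"], 2)
#>          pi         fst         dxy discordance
#>       -0.85        0.78       -0.61       -0.18
signif(res$correlation$p_adj[c("pi", "fst", "dxy", "discordance"),
                             "gene_density"], 2)
#>          pi         fst         dxy discordance
#>     1.0e-28     3.3e-21     3.4e-11     8.8e-02
```

Diversity falls and differentiation rises with gene density, divergence
falls with it — the fingerprint of recurrent linked selection (the
discordance signal strengthens with more species and windows; see the
acceptance suite). The FST landscapes of the 6 pairs are strongly
correlated:

```r
res$pca$fst
#> landscape PCA: 100 windows x 6 columns; PC1 explains 61.7%; r_S(PC1, mean) = 0.999
```

`run_pipeline(cfg, out_dir)` wraps the same chain and writes
fixed-column TSV tracks plus a JSON run manifest;
`inst/cli/glscape.R` is a thin command-line wrapper
(`Rscript inst/cli/glscape.R demo --out out/`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "glscape",
                               load_package = "installed")'
```

The suite covers: the simulator's coalescent calibration (3-taxon ILS
closed form, Watterson expectation), certainty-limit equivalence of the
whole GL→SFS→θ stack with textbook estimators, brute-force oracles for
the SAF dynamic programming (2ⁿ enumeration) and the partition metric
(graph-deletion bipartition enumeration, plus phangorn as an independent
cross-check), neutral calibration of θ̂ and Tajima's D, sign-structure
recovery under linked selection, landscape-PCA behaviour, and the
calibration of the permutation machinery (type-I error, Mantel p
uniformity).

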