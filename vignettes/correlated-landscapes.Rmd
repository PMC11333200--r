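---
title: "Correlated genomic landscapes from haploid genotype likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated genomic landscapes from haploid genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In clades with conserved genome architecture, the density of selection
targets (genes) is expected to shape diversity along the genome the same
way in every species: recurrent linked selection (background selection
and sweeps) locally depresses effective population size where genes are
dense. The observable consequence is a set of *correlated landscapes*:
within-species nucleotide diversity ($\pi$) and Tajima's $D$, between-
species divergence ($d_{XY}$), and differentiation ($F_{ST}$) co-vary
along the genome, with

$$\rho(\pi, \text{gene density}) < 0,\quad
  \rho(d_{XY}, \text{gene density}) < 0,\quad
  \rho(F_{ST}, \text{gene density}) > 0,\quad
  \rho(F_{ST}, \pi) < 0,$$

and phylogenetic discordance (a measure of incomplete lineage sorting,
ILS) lower where local $N_e$ is lower. `glscape` implements the full
chain from low-coverage haploid sequencing observations to these
landscape-level statistics, plus a coalescent simulator that generates
genome-scale data with known truth so every link of the chain can be
tested against an oracle.

The package targets haploid organisms (e.g. bryophyte gametophytes)
sequenced at low depth, where genotype calling is unreliable and all
inference is carried out on genotype likelihoods.

## Genotype likelihoods and filtering

Reads are consumed as a pileup-like TSV (`scaffold, pos, sample_id,
base, bq, mapq, flag`). Filtering follows standard low-coverage practice
and is applied *exclusively*: reads with MAPQ $\le 30$, base quality
$\le 20$ or flag $\ge 256$ are discarded; an individual is dropped from
a site when its filtered depth falls outside $[2, 100]$; a site is
dropped when more than $1/3$ of the individuals are missing. All
thresholds live in `filter_config()`.

The haploid genotype likelihood of allele $a$ for one individual is the
independent-error product over its reads,
$\log L(a) = \sum_r w_r \log\left[(1-\varepsilon_r)\,\mathbb{1}(b_r = a)
+ \tfrac{\varepsilon_r}{3}\,\mathbb{1}(b_r \ne a)\right]$,
with $\varepsilon_r$ from the Phred base quality and a mapping-quality
weight $w_r = 1 - 10^{-\mathrm{MAPQ}/10}$. Base alignment quality (BAQ)
recomputation is out of scope; this simplified model is the documented
contract. The biallelic (major, minor) pair at each site is the pair
maximizing the site likelihood over the minor-allele frequency (EM over
individuals; individuals with flat likelihoods contribute nothing; ties
break lexicographically).

## SAF vectors, EM spectra and empirical-Bayes windows

The site-allele-frequency (SAF) vector collects, for each possible
minor-allele count $k \in \{0..n\}$, the sum over allele assignments
with exactly $k$ minor alleles of the product of individual
likelihoods, computed by the standard $O(n^2)$ dynamic programming
(`saf_vector()`, `saf_matrix()`). Two numerical conventions matter:

* **Missing individuals.** The default policy (`missing = "impute"`) is
  to give a zero-read individual a flat likelihood over the allele pair —
  the exact likelihood of "no data" — so every site keeps the full
  sample size $n$. The alternative (`missing = "project"`)
  hypergeometrically down-projects each site to a common smaller $n$;
  it is retained because projection is a widely used device, but it
  discards information, and in our neutral calibration the flat-
  likelihood policy is what recovers $2 N_e \mu$ without bias.
* **Assignment sums vs likelihoods.** The SAF entries are assignment
  *sums*; the probability of the data given $k$ under exchangeable
  assignments is the sum divided by $\binom{n}{k}$
  (`saf_to_likelihood()`). Mixture fits use the corrected form. For
  data-certain sites the correction cancels in the per-site
  normalization, so exact counting is unaffected; for smeared sites it
  prevents mid-frequency categories from being overweighted — without
  it, the neutral calibration overestimates $\theta_W$ by several
  percent and drags mean Tajima's $D$ negative.

The genome-wide folded site-frequency spectrum is the maximizer of
$\sum_\text{sites} \log \sum_k p_k L_\text{site}(k)$, fitted by plain EM
(`em_sfs()`, monotone log-likelihood, tolerance $10^{-8}$ on the
parameters, cap 500 iterations — the cap and tolerance are
implementation policy, stated here because upstream methods leave them
unspecified). Folding merges categories $k$ and $n-k$ by summation; the
middle category at even $n$ is counted once. The 2D spectrum over a
species pair uses the product likelihood on the
$(n_A+1)\times(n_B+1)$ grid with joint folding
($(j,k) \sim (n_A - j, n_B - k)$).

Per-window estimates are empirical Bayes: each site's posterior over
folded categories uses the genome-wide spectrum as prior
(`posterior_site_spectrum()`, with $10^{-12}$ pseudo-mass where the
prior is empty), and windows sum per-site posterior expectations:
$\theta_\pi$ with weights $j(n-j)/\binom{n}{2}$, $\theta_W$ as
$P(\text{segregating})/a_1$, and Tajima's
$D = (\theta_\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$ with the 1989
constants and $S$ the posterior-expected number of segregating sites
(the folded-posterior analogue of the classic count; in the certainty
limit the whole stack reduces exactly to the textbook estimators, which
the test suite asserts at $10^{-8}$).

$F_{ST}$ uses method-of-moments variance components for haploid allele
counts,
$a = (p_1-p_2)^2 - \tfrac{p_1 q_1}{n_1-1} - \tfrac{p_2 q_2}{n_2-1}$ and
$a + b = a + \tfrac{p_1 q_1 n_1}{n_1-1} + \tfrac{p_2 q_2 n_2}{n_2-1}$,
posterior-averaged over the folded 2D grid (the components are
invariant under the joint fold) and combined as ratios of sums
(weighted $F_{ST}$), per window and genome-wide. A fixed difference
gives exactly 1 at any sample size; slightly negative per-window values
are retained, not clipped.

## Consensus, divergence and window trees

Per-sample consensus bases maximize the effective base depth
$\mathrm{EBD}(b) = \sum_{r: b_r = b} (1-10^{-\mathrm{MAPQ}_r/10})
(1-10^{-\mathrm{BQ}_r/10})$, with lexicographic tie-breaking and `N`
where no reads survive. $d_{XY}$ is the mean over between-species
sequence pairs of differences per compared site, `N` excluded pairwise.
Window trees are neighbor-joining on observed-proportion or
Jukes-Cantor distances (saturated JC pairs fall back to the observed
proportion with a warning); NJ exists so the pipeline is self-contained —
externally inferred Newick trees can be supplied instead, since the
package's contribution is the scan, not tree inference. Trees are
pruned to one sample per species (alphabetically first by default;
most-complete-sequence as an option) and scored against the species
tree with the Robinson–Foulds partition metric: the count of
non-trivial bipartitions present in exactly one tree, 0 for identical
topologies up to $2(L-3)$ for maximally different resolved trees on $L$
leaves (18 for 12 species). Windows deviating from the genome-wide mean
score by more than 2 SD are flagged as outliers, and the number of
parsimony-informative sites is reported as a technical control.

## Landscape summaries

Per-window values across species (or the 66 pairs of 12 species) form
a windows × columns matrix. PCA summarizes how correlated the
landscapes are: the PC1 variance fraction is the strength of the shared
landscape and the PC1 window scores are its shape. Columns are centered
and, by default, standardized (correlation-matrix PCA) because pair
landscapes live on different scales; raw-covariance mode is a flag.
The PC1 sign is fixed against the row-mean landscape (PCA signs are
arbitrary). Rows with missing cells are dropped listwise for PCA and
pairwise for correlations. The mean landscape is used as the canonical
track downstream; at high shared signal it is rank-identical to the PC1
scores (the test suite checks $r_S > 0.99$).

The correlation structure across tracks ($\pi$, $D$, $d_{XY}$,
$F_{ST}$, gene density, gene count, discordance) uses Spearman
correlations with average-rank ties, t-approximation p-values,
Benjamini–Hochberg adjustment over the whole family in one batch, and
seeded bootstrap standard errors.

## Spatial tests

*Autocorrelation.* For lag $L$ (3–10 windows by default, i.e. 0.3–1 Mb
at 100-kb windows), the per-focal-window coefficient is the Spearman
correlation between the adjacent non-overlapping blocks $[i, i+L)$ and
$[i+L, i+2L)$; blocks never span scaffolds. Significance comes from a
pooled null built by genome-wide permutation (default 1000 permutations)
with the two-sided add-one rule. This per-window construction is
deliberately conservative — block rank-patterns of a stationary process
carry little long-range information, which is exactly why most windows
are expected to be non-significant. A whole-scaffold lag-shift mode
(`lag_shift_autocorrelation()`) is provided as the sensitive
alternative: it directly measures process autocorrelation and is the
mode in which a track smoothed over $k$ windows shows elevated
coefficients at lags below $k$.

*Mantel test.* Pearson correlation of lower-triangle entries with joint
row/column permutations (999 by default) and the one-sided add-one
p-value, which never returns 0; great-circle distances between group
centroids come from decimal-degree coordinates in the metadata.

*Sympatric–allopatric contrast.* For every species pair and window, the
mean $F_{ST}$ over sympatric population pairs minus the mean over
allopatric pairs; the difference tracks across pairs are summarized by
the landscape PCA. A small PC1 fraction indicates no shared
geography-of-gene-flow signal; window-localized gene flow between
sympatric populations raises it.

## The simulator

`sim_config()` + `simulate_dataset()` generate haploid multispecies
data under the multispecies coalescent: within each species-tree branch
lineages coalesce at rate $\binom{k}{2}/N_e^\text{local}$, with

$$N_e^\text{local}(w) = N_e \cdot \max(f_\text{min},\,
  1 - s_\text{link} \cdot \text{gene density}(w)),$$

a deterministic linked-selection proxy applied to *all* populations,
ancestral ones included. This is not a mechanistic selection model; it
is the cheapest monotone device that produces every sign prediction
listed above, because the landscape claims are about covariation, not
about a specific selection model. The magnitude of along-genome $N_e$
variation is a free parameter (`s_link`); real landscapes do not pin it
down, so it is documented rather than estimated.

Mutations are infinite-sites (collisions redrawn, so every variant is
biallelic), placed on branches proportionally to length. Reads are
Poisson per sample and site with per-read errors at `base_error`; a
configurable fraction of reads carries at-threshold qualities (BQ 20,
MAPQ 30 or flag 256) purely so the filters are exercised. Migration,
when enabled, is a pulse admixture: at sampling time a lineage in a
sympatric population jumps to another species at the same location with
probability `migration_rate`, optionally only in selected windows —
adequate for contrast-machinery tests, not a continuous gene-flow model.

What the generator emulates: ILS in proportions matching the 3-taxon
closed form $1 - \tfrac{2}{3}e^{-T}$; Watterson-consistent segregating
site densities; gene-density-modulated local $N_e$; low-coverage noise
with missingness; geographic population structure in the metadata. What
it does not emulate: recombination within windows (windows are single
genealogies), alignment artefacts, diploid genotypes, explicit
selection, or real base-composition. Passing tests therefore show the
estimator chain is correct under the model's assumptions, not that real
data meet them.

## Problem sizes and numerical choices

The bundled analyses run at desk scale: windows of 2–5 kb with mutation
rates scaled so per-site diversity ($\sim 0.0025$–$0.005$) matches the
biological order of magnitude, 2–6 species with 4–10 haploid samples
each, and 200–500 windows per run; the window length is a pure scale
factor for the per-site estimators, so none of the contracts depend on
it. Calibration checks average over hundreds of windows because the
no-recombination coalescent variance per window is irreducible
(genealogical CV $\approx 0.5$). EM tolerances, the 500-iteration cap,
the $10^{-12}$ posterior pseudo-mass, lexicographic tie-breaks in
consensus and allele-pair choice, clamping of negative NJ branch
lengths, and the masked (`NA`, written as ".") treatment of undefined
statistics ($D$ at $S=0$, $F_{ST}$ with empty denominators, windows
without trees) are all deliberate, documented defaults rather than
tuned values.

## Known limitations

* The GL model omits BAQ and treats mapping quality as a soft weight;
  with systematically misaligned reads the likelihoods are optimistic.
* Consensus-based $d_{XY}$ ignores within-sample base uncertainty below
  the EBD argmax; at depth $\lesssim 2$ it is noisy and the `N` rate
  grows.
* The per-window adjacent-block autocorrelation has low power by
  construction; use the lag-shift mode for detection questions.
* The 2D-SFS EM is the cost bottleneck (grid size grows with both
  sample sizes); the iteration cap bounds runtime at a small accuracy
  cost flagged by a convergence warning.
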