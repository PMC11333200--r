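test_that("window theta sums follow the folded linear estimators", {
  # one certain singleton site, n = 4: thetaW = 1/a1, thetaPi = 3/C(4,2)
  post <- matrix(c(0, 1, 0), 1)  # folded categories 0, 1, 2
  th <- window_thetas(post, n = 4, window_id = 1L, n_sites = 100)
  a1 <- 1 + 1 / 2 + 1 / 3
  expect_equal(th$theta_w, 1 / a1)
  expect_equal(th$theta_pi, 1 * 3 / choose(4, 2))
  expect_equal(th$pi_site, th$theta_pi / 100)

  # monomorphic-certain window: both estimators zero
  post0 <- matrix(c(1, 0, 0), 5, 3, byrow = TRUE)
  th0 <- window_thetas(post0, n = 4, window_id = rep(1L, 5), n_sites = 100)
  expect_equal(th0$theta_pi, 0)
  expect_equal(th0$theta_w, 0)
})

test_that("certainty-limit windows equal the classic estimators", {
  cfg <- sim_config(n_species = 2, samples_per_population = 3,
                    n_locations = 2, base_Ne = 10000,
                    mutation_rate = 2.5e-7, n_scaffolds = 1,
                    windows_per_scaffold = 50, window_length = 1000,
                    depth_mean = 1, seed = 21)
  sim <- simulate_dataset(cfg)
  gl <- certain_gl_table(sim$variants, sim$haplotypes,
                         sim$metadata$sample_id)
  gla <- gl_array(gl, sim$metadata$sample_id)
  for (sp in c("sp01", "sp02")) {
    sc <- species_theta_scan(gla, sim$metadata, sp, sim$windows)
    samp <- sim$metadata$sample_id[sim$metadata$species == sp]
    for (w in sim$windows$window_id) {
      sel <- sim$variants$window_id == w
      oracle <- classic_window_stats(
        sim$haplotypes[sel, samp, drop = FALSE])
      row <- sc$windows[sc$windows$window_id == w, ]
      expect_equal(row$theta_pi, oracle$theta_pi, tolerance = 1e-8)
      expect_equal(row$theta_w, oracle$theta_w, tolerance = 1e-8)
      expect_equal(row$S, oracle$S, tolerance = 1e-8)
      if (oracle$S > 0) {
        expect_equal(row$tajima_d,
                     tajima_d_oracle(oracle$theta_pi, oracle$theta_w,
                                     oracle$S, oracle$n),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("Tajima's D matches an independent constant computation", {
  expect_equal(tajimas_d(3.2, 3.2, 10, 10), 0)
  expect_true(is.na(tajimas_d(1, 2, 0, 10)))
  for (n in c(4, 10, 25)) {
    for (S in c(3, 16, 40)) {
      tp <- 1.7 * S / 10; tw <- S / sum(1 / seq_len(n - 1))
      expect_equal(tajimas_d(tp, tw, S, n), tajima_d_oracle(tp, tw, S, n),
                   tolerance = 1e-10)
    }
  }
  expect_equal(sign(tajimas_d(2, 1, 5, 10)), 1)
  expect_equal(sign(tajimas_d(1, 2, 5, 10)), -1)
})

test_that("Reynolds components behave at the boundary cases", {
  # equal frequencies, large n: numerator vanishes
  c1 <- fst_components(0.3, 0.3, 1e6, 1e6)
  expect_lt(abs(c1$a), 1e-6)
  # fixed difference: FST exactly 1 for any sample size
  for (n in c(2, 5, 50)) {
    cc <- fst_components(0, 1, n, n)
    expect_equal(cc$a / cc$ab, 1)
  }
  # weighted (ratio-of-sums) vs naive mean of ratios
  expect_equal(weighted_fst(c(1, 1), c(2, 4)), 2 / 6)
  expect_equal(weighted_fst(c(1, 0), c(2, 2)), 0.25)
  expect_true(is.na(weighted_fst(0, 0)))
})

test_that("null and structured FST match a Hudson-estimator oracle", {
  set.seed(77)
  # identical populations: FST ~ 0
  p <- runif(1000, 0.05, 0.95)
  n <- 20
  p1 <- rbinom(1000, n, p) / n
  p2 <- rbinom(1000, n, p) / n
  cc <- fst_components(p1, p2, n, n)
  expect_lt(abs(weighted_fst(cc$a, cc$ab)), 0.02)

  # two diverged demes: agreement with the Hudson estimator within 0.05
  pa <- pmin(pmax(p + rnorm(1000, 0, 0.25), 0), 1)
  pb <- pmin(pmax(p + rnorm(1000, 0, 0.25), 0), 1)
  s1 <- rbinom(1000, n, pa) / n
  s2 <- rbinom(1000, n, pb) / n
  cc2 <- fst_components(s1, s2, n, n)
  hud_num <- (s1 - s2)^2 - s1 * (1 - s1) / (n - 1) - s2 * (1 - s2) / (n - 1)
  hud_den <- s1 * (1 - s2) + s2 * (1 - s1)
  keep <- hud_den > 0
  hudson <- sum(hud_num[keep]) / sum(hud_den[keep])
  expect_lt(abs(weighted_fst(cc2$a, cc2$ab) - hudson), 0.05)
})

test_that("EBD consensus picks the highest effective base depth", {
  expect_equal(ebd_call("A", 30, 60), "A")
  expect_equal(ebd_call(character(0), integer(0), integer(0)), "N")
  # two weaker reads can outvote one strong read
  expect_equal(ebd_call(c("A", "C", "C"), c(37, 30, 30), c(60, 60, 60)), "C")
  # exact tie: lexicographic winner
  expect_equal(ebd_call(c("C", "A"), c(30, 30), c(60, 60)), "A")

  pile <- data.table::data.table(
    pos = c(5L, 5L, 7L), base = c("A", "A", "G"),
    bq = c(30L, 30L, 37L), mapq = c(60L, 60L, 60L))
  cons <- ebd_consensus(pile, list(start = 0L, end = 10L))
  expect_equal(cons[5], "A")
  expect_equal(cons[7], "G")
  expect_equal(sum(cons == "N"), 8)
})

test_that("window slicing tiles scaffolds and matches substrings", {
  set.seed(11)
  seqs <- vapply(1:3, function(i)
    paste0(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
           collapse = ""), "")
  names(seqs) <- paste0("s", 1:3)
  sl <- slice_windows(seqs, 100)
  expect_length(sl, 2)  # trailing 50 bp dropped
  expect_equal(names(sl), c("0_100", "100_200"))
  for (i in 1:2) expect_equal(rownames(sl[[i]]), names(seqs))
  # direct substring oracle
  expect_equal(paste0(sl[[2]]["s2", ], collapse = ""),
               substr(seqs[["s2"]], 101, 200))
  # concatenating slices reproduces the input prefix
  expect_equal(paste0(c(sl[[1]]["s1", ], sl[[2]]["s1", ]), collapse = ""),
               substr(seqs[["s1"]], 1, 200))
  expect_error(slice_windows(c(a = "ACGT", b = "ACG"), 2), "mismatch")
})

test_that("dxy counts pairwise differences with N-masking", {
  aln <- rbind(
    a1 = strsplit("AAAAAAAAAA", "")[[1]],
    b1 = strsplit("AAACCCAAAA", "")[[1]])
  grp <- c(a1 = "A", b1 = "B")
  expect_equal(dxy(aln, grp, c("A", "B")), 0.3)
  expect_equal(dxy(aln, grp, c("B", "A")), 0.3)  # symmetric
  expect_equal(dxy(rbind(a1 = aln[1, ], b1 = aln[1, ]), grp, c("A", "B")), 0)
  # N positions excluded pairwise
  aln2 <- aln; aln2[2, 1:5] <- "N"
  expect_equal(dxy(aln2, grp, c("A", "B")), 1 / 5)
})

test_that("vectorized dxy scan equals the direct per-window oracle", {
  cfg <- sim_config(n_species = 3, samples_per_population = 2,
                    n_locations = 1, base_Ne = 8000, mutation_rate = 5e-7,
                    n_scaffolds = 1, windows_per_scaffold = 10,
                    window_length = 500, depth_mean = 30,
                    base_error = 1e-6, filtered_read_frac = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  filt <- filter_observations(sim$pileup, samples = sim$metadata$sample_id)
  gla <- gl_array(pileup_gl(filt$pileup), sim$metadata$sample_id)
  cons <- consensus_matrix(filt$pileup, sim$metadata$sample_id, gla$sites)
  scan <- dxy_scan(cons, gla$sites, sim$metadata, sim$windows)
  for (w in sim$windows$window_id) {
    aln <- true_window_alignment(sim, w)
    for (pp in list(c("sp01", "sp02"), c("sp02", "sp03"))) {
      got <- scan[scan$window_id == w & scan$sp1 == pp[1] &
                    scan$sp2 == pp[2], ]$dxy
      want <- dxy(aln, sim$metadata, pp)
      # high depth, near-zero error: consensus ~ truth
      expect_equal(got, want, tolerance = 0.01)
    }
  }
})

test_that("gene density merges overlaps and counts boundary-spanning genes", {
  win <- make_windows(c(s = 200000), 100000)
  expect_equal(gene_density_track(NULL, win)$gene_density, c(0, 0))

  g1 <- data.table::data.table(scaffold = "s", start = 10000L, end = 60000L,
                               gene_id = "g1")
  gd <- gene_density_track(g1, win)
  expect_equal(gd$gene_density, c(0.5, 0))
  expect_equal(gd$gene_count, c(1L, 0L))

  # overlapping genes are merged for density but both are counted
  g2 <- data.table::data.table(
    scaffold = "s", start = c(0L, 25000L), end = c(50000L, 100000L),
    gene_id = c("g1", "g2"))
  gd2 <- gene_density_track(g2, win)
  expect_equal(gd2$gene_density[1], 1)
  expect_equal(gd2$gene_count[1], 2L)

  # a gene spanning two windows counts in both
  g3 <- data.table::data.table(scaffold = "s", start = 90000L,
                               end = 110000L, gene_id = "g3")
  gd3 <- gene_density_track(g3, win)
  expect_equal(gd3$gene_count, c(1L, 1L))
  expect_equal(gd3$gene_density, c(0.1, 0.1))
})

test_that("windows drop incomplete scaffold tails and short scaffolds", {
  win <- make_windows(c(a = 250000, b = 90000), 100000)
  expect_equal(nrow(win), 2)
  expect_true(all(win$scaffold == "a"))
  win2 <- make_windows(c(a = 250000, b = 3e6), 100000,
                       min_scaffold_length = 2e6)
  expect_true(all(win2$scaffold == "b"))
  expect_equal(assign_windows(win, "a", 1L), 1L)
  expect_equal(assign_windows(win, "a", 100000L), 1L)
  expect_equal(assign_windows(win, "a", 100001L), 2L)
  expect_true(is.na(assign_windows(win, "a", 200001L)))
})
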