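make_track <- function(values, scaffold = "s") {
  data.table::data.table(scaffold = scaffold,
                         index = seq_along(values), value = values)
}

test_that("block autocorrelation handles deterministic tracks", {
  # strictly increasing track: every eligible coefficient is 1
  tr <- make_track(seq_len(40))
  ac <- lagged_autocorrelation(tr, lag = 3)
  eligible <- !is.na(ac$coefficient)
  expect_equal(sum(eligible), 40 - 2 * 3 + 1)
  expect_true(all(ac$coefficient[eligible] == 1))

  # rank-based: invariant under strictly monotone transforms
  set.seed(71)
  v <- rnorm(60)
  a1 <- lagged_autocorrelation(make_track(v), lag = 4)
  a2 <- lagged_autocorrelation(make_track(exp(3 * v)), lag = 4)
  expect_equal(a1$coefficient, a2$coefficient, tolerance = 1e-12)

  # blocks never span scaffolds; short scaffolds fully masked
  tr2 <- rbind(make_track(rnorm(10), "a"), make_track(rnorm(4), "b"))
  ac2 <- lagged_autocorrelation(tr2, lag = 3)
  expect_true(all(is.na(ac2$coefficient[ac2$scaffold == "b"])))
})

test_that("smoothing is detected at short lags more than long lags", {
  set.seed(73)
  raw <- rnorm(1200)
  sm <- stats::filter(raw, rep(1 / 5, 5), sides = 1)
  v <- as.numeric(sm)[6:1200]
  # whole-scaffold lag-shift mode: 5-window smoothing leaves positive
  # autocorrelation below the smoothing scale and none above it
  m3 <- lag_shift_autocorrelation(make_track(v), 3)$coefficient
  m10 <- lag_shift_autocorrelation(make_track(v), 10)$coefficient
  expect_gt(m3, 0.2)
  expect_gt(m3, m10)
  expect_lt(abs(m10), 0.1)
})

test_that("the permutation null is seeded, reproducible and add-one", {
  set.seed(79)
  tr <- make_track(rnorm(80))
  r1 <- autocorr_permutation_null(tr, lag = 3, n_perm = 100, seed = 5)
  r2 <- autocorr_permutation_null(tr, lag = 3, n_perm = 100, seed = 5)
  expect_identical(r1$result$p_value, r2$result$p_value)
  expect_true(all(r1$result$p_value > 0, na.rm = TRUE))
  expect_true(all(r1$result$p_value <= 1, na.rm = TRUE))
  # storage order of windows does not change the result
  shuf <- tr[sample.int(nrow(tr))]
  r3 <- autocorr_permutation_null(shuf, lag = 3, n_perm = 100, seed = 5)
  expect_equal(sort(r3$result$p_value), sort(r1$result$p_value))
})

test_that("Mantel test recovers identity, nulls and monotone structure", {
  set.seed(83)
  n <- 10
  m <- matrix(runif(n * n), n); m <- m + t(m); diag(m) <- 0
  res <- mantel_test(m, m, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)  # beyond all permutations: add-one minimum

  # power: distances monotone in each other plus noise
  d <- as.matrix(dist(runif(12)))
  f <- d^1.3 + matrix(rnorm(144, 0, 0.02), 12)
  f <- (f + t(f)) / 2; diag(f) <- 0
  res2 <- mantel_test(f, d, n_perm = 999, seed = 2)
  expect_gt(res2$r, 0.8)
  expect_lt(res2$p, 0.01)

  expect_error(mantel_test(m, m[1:9, 1:9]), "dimensions")
  rownames(m) <- colnames(m) <- letters[1:10]
  m2 <- m; rownames(m2) <- colnames(m2) <- LETTERS[1:10]
  expect_error(mantel_test(m, m2), "labels")
})

test_that("great-circle species distances are geographically sane", {
  md <- data.frame(species = rep(c("x", "y"), each = 2),
                   lat = c(63.4, 63.5, 47.1, 47.2),
                   lon = c(10.4, 10.5, 13.8, 13.9))
  d <- geo_distance_matrix(md)
  expect_equal(d["x", "x"], 0)
  expect_equal(d, t(d))
  expect_gt(d["x", "y"], 1500)  # Trondheim-ish to Austrian Alps
  expect_lt(d["x", "y"], 2200)
})

test_that("sympatric-allopatric contrast nulls out symmetric FST", {
  set.seed(89)
  sp <- sprintf("sp%02d", 1:4)
  pops <- data.table::CJ(species = sp, location = c("L1", "L2"))
  pops[, population := paste(species, location, sep = "_")]
  md <- data.frame(sample_id = pops$population, species = pops$species,
                   population = pops$population, location = pops$location)
  pairs <- t(utils::combn(sp, 2))
  rows <- list()
  for (w in 1:30) for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    ppair <- data.table::CJ(pop1 = pops[species == a, population],
                            pop2 = pops[species == b, population])
    base <- runif(1, 0.4, 0.9)  # same FST for every population pair
    rows[[length(rows) + 1L]] <- data.table::data.table(
      window_id = w, sp1 = a, pop1 = ppair$pop1, sp2 = b,
      pop2 = ppair$pop2, fst = base)
  }
  ct <- sympatric_allopatric_contrast(data.table::rbindlist(rows), md)
  expect_true(all(abs(ct$contrast$difference) < 1e-12))
})

test_that("contrast PCA separates the no-gene-flow null from localized flow", {
  mkcfg <- function(m, mw = integer(0))
    sim_config(n_species = 7, samples_per_population = 2, n_locations = 2,
               base_Ne = 8000, mutation_rate = 4e-7, n_scaffolds = 1,
               windows_per_scaffold = 300, window_length = 1500,
               migration_rate = m, migration_windows = mw,
               depth_mean = 1, seed = 31)
  # no migration: difference tracks are noise, PC1 fraction stays small
  sim0 <- simulate_dataset(mkcfg(0))
  ct0 <- sympatric_allopatric_contrast(truth_pop_fst_table(sim0),
                                       sim0$metadata)
  expect_lt(ct0$pca$pc1_variance_fraction, 0.25)

  # sympatric-only pulse migration in selected windows: those windows
  # load strongly on PC1 and the explained fraction rises above the null
  mw <- 1:40
  simM <- simulate_dataset(mkcfg(0.5, mw))
  ctM <- sympatric_allopatric_contrast(truth_pop_fst_table(simM),
                                       simM$metadata)
  expect_gt(ctM$pca$pc1_variance_fraction, ct0$pca$pc1_variance_fraction)
  lo <- ctM$pca$pc1_loadings
  in_mw <- names(lo) %in% as.character(mw)
  expect_gt(mean(abs(lo[in_mw])), 2 * mean(abs(lo[!in_mw])))
  # gene flow depresses sympatric relative to allopatric FST there
  diffs <- ctM$contrast
  expect_lt(mean(diffs$difference[diffs$window_id %in% mw], na.rm = TRUE),
            mean(diffs$difference[!diffs$window_id %in% mw], na.rm = TRUE))
})
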