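test_that("haploid genotype likelihoods follow the independent-error model", {
  # single read: L(A) = 1 - eps, others eps/3
  gl <- haploid_site_gl("A", 0.001)
  expect_equal(gl[["A"]], log(0.999))
  expect_equal(gl[["C"]], log(0.001 / 3))
  expect_equal(gl[["G"]], gl[["T"]])

  # conflicting reads with equal error: symmetric likelihoods
  gl2 <- haploid_site_gl(c("A", "C"), 0.01)
  expect_equal(gl2[["A"]], gl2[["C"]])

  # 5 concordant reads: closed-form log-likelihood difference
  gl5 <- haploid_site_gl(rep("G", 5), 0.01)
  expect_equal(gl5[["G"]] - gl5[["A"]], 5 * (log(0.99) - log(0.01 / 3)),
               tolerance = 1e-12)

  # zero reads: missing individual, not an error
  expect_true(all(is.na(haploid_site_gl(character(0), numeric(0)))))

  # mapping quality down-weights reads
  glw <- haploid_site_gl("A", 0.01, mapq = 10)
  expect_equal(glw[["A"]], (1 - 0.1) * log(0.99))
})

make_gla <- function(hap, samples = colnames(hap)) {
  v <- data.table::data.table(
    scaffold = "s", pos = seq_len(nrow(hap)))
  gl <- certain_gl_table(v, hap, samples)
  gl_array(gl, samples)
}

test_that("major/minor inference matches certainty and EM fixed points", {
  # all individuals certain A
  hap <- matrix("A", 5, 6, dimnames = list(NULL, paste0("i", 1:6)))
  mm <- infer_major_minor(make_gla(hap))
  expect_true(all(mm$major == "A"))
  expect_true(all(is.na(mm$minor)))
  expect_true(all(mm$freq_minor == 0))

  # half A, half C: frequency 1/2, lexicographic major
  hap2 <- matrix(rep(c("A", "C"), each = 3), 1, 6,
                 dimnames = list(NULL, paste0("i", 1:6)), byrow = TRUE)
  mm2 <- infer_major_minor(make_gla(hap2))
  expect_equal(mm2$major, "A")
  expect_equal(mm2$minor, "C")
  expect_equal(mm2$freq_minor, 0.5, tolerance = 1e-6)

  # 8 certain A, 2 certain C, 2 flat: EM fixed point f = 2/10
  v <- data.table::data.table(scaffold = "s", pos = 1L)
  samples <- paste0("i", 1:12)
  hap3 <- matrix(c(rep("A", 8), rep("C", 4)), 1, 12,
                 dimnames = list(NULL, samples))
  gl <- certain_gl_table(v, hap3, samples)
  flat <- c("i11", "i12")
  for (bb in c("llA", "llC", "llG", "llT")) {
    gl[[bb]][gl$sample_id %in% flat] <- 0
  }
  mm3 <- infer_major_minor(gl_array(gl, samples))
  expect_equal(sort(c(mm3$major, mm3$minor)), c("A", "C"))
  # 1-D grid-search oracle over the frequency
  P <- ifelse(hap3[1, ] == "C", 1, exp(-30)); P[flat] <- 1
  Q <- ifelse(hap3[1, ] == "A", 1, exp(-30)); Q[flat] <- 1
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(f) sum(log((1 - f) * Q + f * P)), 0)
  expect_equal(mm3$freq_minor, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(mm3$freq_minor, 0.2, tolerance = 1e-3)
})

test_that("SAF dynamic programming equals brute-force enumeration", {
  # certainty: 3 of 8 carry the minor -> point mass at k = 3
  la <- c(rep(1, 5), rep(1e-12, 3))
  lb <- c(rep(1e-12, 5), rep(1, 3))
  saf <- saf_vector(la, lb)
  expect_equal(which.max(saf), 4L)
  expect_lt(sum(saf[-4]) / saf[4], 1e-10)

  # one flat individual among certain carriers: 1:1 mass on k = j, j + 1
  la2 <- c(rep(1, 4), rep(1e-12, 3), 1)
  lb2 <- c(rep(1e-12, 4), rep(1, 3), 1)
  saf2 <- saf_vector(la2, lb2)
  expect_equal(saf2[4], saf2[5], tolerance = 1e-9)

  # 20 random sites, n = 8: DP equals the 2^8 enumeration oracle
  set.seed(101)
  for (r in 1:20) {
    la <- runif(8); lb <- runif(8)
    expect_equal(saf_vector(la, lb), saf_bruteforce(la, lb),
                 tolerance = 1e-10)
  }
})

test_that("EM SFS reproduces exact counting in the certainty limit", {
  set.seed(7)
  n <- 8
  k_true <- sample(0:n, 400, replace = TRUE)
  saf <- matrix(1e-300, 400, n + 1)
  saf[cbind(seq_len(400), k_true + 1)] <- 1
  sfs <- em_sfs(saf, n = n, folded = TRUE)
  hist_f <- tabulate(pmin(k_true, n - k_true) + 1, nbins = n / 2 + 1) / 400
  expect_equal(sfs$probs, hist_f, tolerance = 1e-6)
  # log-likelihood is non-decreasing across iterations
  expect_true(all(diff(sfs$loglik_trace) > -1e-9))

  # single site: point mass at its argmax category
  one <- em_sfs(saf[1, , drop = FALSE], n = n, folded = TRUE)
  expect_equal(which.max(one$probs), min(k_true[1], n - k_true[1]) + 1)
  expect_gt(max(one$probs), 1 - 1e-6)

  expect_error(em_sfs(saf[0, , drop = FALSE], n = n), "empty")
})

test_that("folded and unfolded EM agree after projection", {
  set.seed(12)
  n <- 6
  k_true <- sample(0:n, 600, replace = TRUE, prob = c(4, 2, 1, 1, 1, 2, 4))
  saf <- matrix(1e-300, 600, n + 1)
  saf[cbind(seq_len(600), k_true + 1)] <- 1
  # smear 30% of sites to exercise the mixture
  sm <- sample(600, 180)
  saf[sm, ] <- saf[sm, ] + 0.2
  f_u <- em_sfs(saf, n = n, folded = FALSE, max_iter = 2000)
  f_f <- em_sfs(saf, n = n, folded = TRUE, max_iter = 2000)
  folded_from_u <- as.vector(f_u$probs %*% fold_map(n))
  expect_lt(sum(abs(folded_from_u - f_f$probs)) / 2, 0.02)
})

test_that("outputs are invariant to individual order", {
  set.seed(33)
  samples <- paste0("i", 1:8)
  hap <- matrix(sample(c("A", "G"), 40 * 8, replace = TRUE), 40, 8,
                dimnames = list(NULL, samples))
  gla1 <- make_gla(hap)
  perm <- sample(samples)
  gla2 <- make_gla(hap, samples = perm)
  mm1 <- infer_major_minor(gla1)
  mm2 <- infer_major_minor(gla2)
  expect_equal(mm1$major, mm2$major)
  expect_equal(mm1$freq_minor, mm2$freq_minor, tolerance = 1e-9)
  s1 <- saf_matrix(gla1, mm1)
  s2 <- saf_matrix(gla2, mm2)
  expect_equal(s1$saf, s2$saf, tolerance = 1e-9)
  expect_equal(em_sfs(s1)$probs, em_sfs(s2)$probs, tolerance = 1e-8)
})

test_that("neutral certain data recover the 1/k + 1/(n-k) spectrum shape", {
  set.seed(5)
  n <- 10
  w <- 1 / (1:(n - 1)) + 1 / ((n - 1):1)
  kf <- pmin(1:(n - 1), n - 1:(n - 1))
  probs_f <- tapply(w, kf, sum)
  probs_f <- probs_f / sum(probs_f)
  k_draw <- sample(seq_along(probs_f), 5000, replace = TRUE, prob = probs_f)
  saf <- matrix(1e-300, 5000, n + 1)
  saf[cbind(seq_len(5000), k_draw + 1)] <- 1
  sfs <- em_sfs(saf, n = n, folded = TRUE)
  est_seg <- sfs$probs[-1] / sum(sfs$probs[-1])
  obs <- est_seg * 5000
  expected <- probs_f * 5000
  chi <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, df = length(expected) - 1, lower.tail = FALSE),
            0.01)
})

test_that("2D EM reproduces joint counting and degenerate supports", {
  set.seed(9)
  nA <- 4; nB <- 4
  mkset <- function(k, n) {
    saf <- matrix(1e-300, length(k), n + 1)
    saf[cbind(seq_along(k), k + 1)] <- 1
    structure(list(saf = saf, n = n,
                   sites = data.table::data.table(
                     scaffold = "s", pos = seq_along(k),
                     site_i = seq_along(k)),
                   n_present = rep(n, length(k))), class = "saf_set")
  }
  kA <- sample(0:nA, 300, replace = TRUE)
  kB <- sample(0:nB, 300, replace = TRUE)
  s2 <- em_sfs_2d(mkset(kA, nA), mkset(kB, nB))
  # fold the joint counts like the estimator folds the grid
  fm <- fold_map_2d(nA, nB)
  cell <- kA + kB * (nA + 1) + 1
  cnt <- tabulate(fm$group[cell], nbins = max(fm$group)) / 300
  expect_equal(s2$probs, cnt, tolerance = 1e-6)

  # monomorphic species B: mass confined to the k_B = 0 column (folded)
  s2b <- em_sfs_2d(mkset(kA, nA), mkset(rep(0L, 300), nB))
  on_col <- s2b$rep_k == 0 | s2b$rep_k == nB
  expect_lt(sum(s2b$probs[!on_col]), 1e-9)

  # diverged populations: all fixed differences -> corner categories
  s2c <- em_sfs_2d(mkset(rep(0L, 100), nA), mkset(rep(nB, 100), nB))
  corner <- (s2c$rep_j == 0 & s2c$rep_k == nB) |
    (s2c$rep_j == nA & s2c$rep_k == 0)
  expect_gt(sum(s2c$probs[corner]), 1 - 1e-9)

  # mismatched site sets are rejected
  bad <- mkset(kB[1:299], nB)
  expect_error(em_sfs_2d(mkset(kA, nA), bad), "same sites")
})

test_that("posterior spectra follow Bayes' rule", {
  # flat prior: posterior proportional to likelihood
  lik <- c(0.2, 0.5, 0.3)
  post <- posterior_site_spectrum(lik, rep(1 / 3, 3))
  expect_equal(post, lik / sum(lik), tolerance = 1e-9)

  # hand-computed example
  post2 <- posterior_site_spectrum(c(0.1, 0.1, 0.8), c(0.7, 0.2, 0.1))
  expect_equal(post2, c(0.07, 0.02, 0.08) / 0.17, tolerance = 1e-9)

  # certain site: point mass survives any positive prior
  post3 <- posterior_site_spectrum(c(0, 0, 1, 0), c(0.97, 0.01, 0.01, 0.01))
  expect_equal(post3[3], 1)
})
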