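# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately written as direct enumerations / textbook
# formulas, independent of the package's vectorized code paths.

# Certainty-limit GL table from a haplotype matrix (sites x samples).
certain_gl_table <- function(variants, hap, samples, ll_off = -30) {
  gl <- data.table::data.table(
    scaffold = rep(variants$scaffold, length(samples)),
    pos = rep(variants$pos, length(samples)),
    sample_id = rep(samples, each = nrow(variants))
  )
  b <- as.vector(hap[, samples])
  for (bb in c("A", "C", "G", "T")) {
    gl[[paste0("ll", bb)]] <- ifelse(b == bb, 0, ll_off)
  }
  gl$depth <- 10L
  gl
}

# Brute-force SAF oracle: enumerate all 2^n allele assignments.
saf_bruteforce <- function(lik_major, lik_minor) {
  n <- length(lik_major)
  out <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    k <- sum(bits)
    out[k + 1] <- out[k + 1] +
      prod(ifelse(bits == 1, lik_minor, lik_major))
  }
  out / max(out)
}

# Textbook Tajima's D oracle (independent reimplementation).
tajima_d_oracle <- function(theta_pi, theta_w, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Classic window estimators computed directly from a haplotype matrix.
classic_window_stats <- function(hap) {
  n <- ncol(hap)
  counts <- apply(hap, 1, function(z) {
    tab <- sort(table(z), decreasing = TRUE)
    if (length(tab) == 1) 0L else as.integer(sum(tab[-1]))
  })
  seg <- counts > 0
  theta_pi <- sum(counts * (n - counts)) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  list(S = sum(seg), theta_pi = theta_pi, theta_w = sum(seg) / a1, n = n)
}

# Brute-force bipartition enumeration by graph edge deletion (independent
# of the package's postorder tip-set route): delete each internal edge of
# the tree graph and collect the resulting leaf components.
bipartitions_graph_oracle <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  n <- length(labs)
  edges <- tree$edge
  adj <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (a <= n || b <= n) next  # trivial split
    # BFS from b avoiding the deleted edge
    seen <- rep(FALSE, n + tree$Nnode)
    seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if ((v == b && u == a) || (v == a && u == b)) next
        if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
      }
    }
    side <- sort(labs[which(seen[seq_len(n)])])
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (labs[order(labs)][1] %in% side) side <- sort(setdiff(labs, side))
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

rf_oracle <- function(t1, t2) {
  b1 <- bipartitions_graph_oracle(t1)
  b2 <- bipartitions_graph_oracle(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Random fully-resolved unrooted topology over given labels.
random_topology <- function(labels) {
  ape::unroot(ape::rtree(length(labels), tip.label = sample(labels)))
}

# Two fully resolved 12-leaf trees sharing no non-trivial bipartition:
# a caterpillar and a caterpillar over an interleaved leaf order, verified
# by the graph oracle in the tests that use them.
max_distant_trees <- function(n = 12) {
  labs <- sprintf("t%02d", seq_len(n))
  cat_tree <- function(ord) {
    nwk <- sprintf("(%s,%s)", ord[1], ord[2])
    for (k in 3:length(ord)) nwk <- sprintf("(%s,%s)", nwk, ord[k])
    ape::unroot(ape::read.tree(text = paste0(nwk, ";")))
  }
  t1 <- cat_tree(labs)
  # interleave: t01 t07 t02 t08 ... destroys every contiguous split
  ord2 <- as.vector(rbind(labs[1:(n / 2)], labs[(n / 2 + 1):n]))
  t2 <- cat_tree(ord2)
  list(t1 = t1, t2 = t2)
}
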