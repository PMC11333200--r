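# Window trees and topological discordance against a species tree.

#' Pairwise distance matrix from a window alignment
#'
#' Observed-proportion (p) distances with pairwise deletion of `N`
#' positions, optionally Jukes-Cantor corrected. When the alignment holds
#' only variant columns, `total_length` supplies the number of additional
#' invariant (identical, comparable) positions per pair. Saturated pairs
#' (p >= 0.75) fall back to the observed proportion under JC, with a
#' warning.
#'
#' @param aln character matrix samples x positions.
#' @param distance `"raw"` or `"JC"`.
#' @param total_length total compared length per pair including invariant
#'   positions (default: `ncol(aln)`).
#' @return a `dist`-convertible symmetric matrix.
#' @export
alignment_distances <- function(aln, distance = c("raw", "JC"),
                                total_length = ncol(aln)) {
  distance <- match.arg(distance)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  extra <- total_length - ncol(aln)
  saturated <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] != "N" & aln[j, ] != "N"
    comp <- sum(ok) + extra
    if (comp < 1) stop("no comparable sites between ", rownames(aln)[i],
                       " and ", rownames(aln)[j])
    p <- sum(aln[i, ok] != aln[j, ok]) / comp
    if (distance == "JC" && p < 0.75) {
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    } else {
      if (distance == "JC" && p >= 0.75) saturated <- TRUE
      d[i, j] <- d[j, i] <- p
    }
  }
  if (saturated) warning("saturated JC distance; observed proportion used")
  d
}

#' Neighbor-joining tree for a window alignment
#'
#' Standard neighbor joining on [alignment_distances()]; negative branch
#' lengths are clamped to zero (the topology is unaffected); the returned
#' tree is unrooted. Determinism follows from the deterministic distance
#' matrix and NJ's deterministic agglomeration (ties resolved by leaf
#' order).
#'
#' @inheritParams alignment_distances
#' @return an unrooted [ape::phylo].
#' @export
nj_tree <- function(aln, distance = c("raw", "JC"),
                    total_length = ncol(aln)) {
  if (nrow(aln) < 4) stop("neighbor joining needs >= 4 sequences")
  d <- alignment_distances(aln, distance, total_length)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Prune a tree to one leaf per species
#'
#' Keeps, for each species, either the alphabetically first sample
#' (default) or the most complete sequence (fewest `N`s, when `aln` is
#' given), relabels the kept leaves by species id, and suppresses the
#' resulting degree-2 nodes.
#'
#' @param tree [ape::phylo] with sample-labelled leaves.
#' @param sample_species named character vector sample -> species (or a
#'   metadata data.frame).
#' @param rule `"alphabetical"` or `"most_complete"`.
#' @param aln optional alignment for the `"most_complete"` rule.
#' @return pruned tree with species-labelled leaves.
#' @export
prune_to_species <- function(tree, sample_species,
                             rule = c("alphabetical", "most_complete"),
                             aln = NULL) {
  rule <- match.arg(rule)
  if (is.data.frame(sample_species)) {
    sample_species <- stats::setNames(sample_species$species,
                                      sample_species$sample_id)
  }
  spp <- sample_species[tree$tip.label]
  if (anyNA(spp)) stop("samples without species assignment: ",
                       paste(tree$tip.label[is.na(spp)], collapse = ", "))
  keep <- vapply(split(tree$tip.label, spp), function(tips) {
    if (rule == "alphabetical" || is.null(aln)) {
      sort(tips)[1]
    } else {
      tips[order(rowSums(aln[tips, , drop = FALSE] == "N"),
                 tips)][1]
    }
  }, "")
  absent <- setdiff(unique(sample_species), names(keep))
  if (length(absent)) stop("species absent from tree: ",
                           paste(absent, collapse = ", "))
  pruned <- ape::keep.tip(tree, unname(keep))
  pruned$tip.label <- names(keep)[match(pruned$tip.label, keep)]
  pruned
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalized
#' as the side not containing the alphabetically first leaf and encoded as
#' a sorted comma-joined label string. Multifurcating trees contribute only
#' their resolved bipartitions.
#'
#' @param tree [ape::phylo].
#' @return character vector of canonical split keys (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  n <- length(labs)
  desc <- .tip_descendants(tree)
  anchor <- labs[order(labs)][1]
  keys <- character(0)
  internal <- (n + 1):(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (!(ch %in% internal)) next
    side <- labs[desc[[ch]]]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (anchor %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

#' Robinson-Foulds partition metric between two unrooted topologies
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees — the number of contraction/decontraction steps needed to
#' interconvert them. Identical topologies score 0; two fully resolved
#' trees on `L` shared leaves score at most `2 (L - 3)`.
#'
#' @param tree_a,tree_b [ape::phylo] objects over the same leaf set.
#' @return even non-negative integer.
#' @export
partition_metric <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label)
  lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) stop("partition_metric: leaf sets differ")
  ba <- tree_bipartitions(tree_a)
  bb <- tree_bipartitions(tree_b)
  length(setdiff(ba, bb)) + length(setdiff(bb, ba))
}

#' Parsimony-informative sites of an alignment
#'
#' Columns with at least two distinct states each carried by at least two
#' sequences; `N` and gap characters are not states.
#'
#' @param aln character matrix samples x positions.
#' @return integer count.
#' @export
parsimony_informative_sites <- function(aln) {
  count <- 0L
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j]
    col <- col[col %in% .BASES]
    if (length(col) < 4) next
    tab <- table(col)
    if (sum(tab >= 2) >= 2) count <- count + 1L
  }
  count
}

#' Discordance scan over window trees
#'
#' Scores every window tree against the species tree with the partition
#' metric (after both are pruned/relabelled to one leaf per species by the
#' caller), computes the genome-wide mean and SD, and flags windows whose
#' score deviates from the mean by more than `sd_factor` SDs. Windows
#' without a tree get a masked record.
#'
#' @param window_trees named list of [ape::phylo] (names = window ids) or
#'   NULL entries for missing windows.
#' @param species_tree species-labelled reference topology.
#' @param sd_factor outlier threshold in SD units (default 2).
#' @return data.table `window_id`, `score`, `outlier`.
#' @export
discordance_scan <- function(window_trees, species_tree, sd_factor = 2) {
  ids <- as.integer(names(window_trees))
  score <- vapply(window_trees, function(tr) {
    if (is.null(tr)) return(NA_integer_)
    as.integer(partition_metric(tr, species_tree))
  }, 1L)
  mu <- mean(score, na.rm = TRUE)
  sdev <- stats::sd(score, na.rm = TRUE)
  out <- data.table(window_id = ids, score = score)
  out[, outlier := !is.na(score) & sdev > 0 & abs(score - mu) > sd_factor * sdev]
  setorder(out, window_id)
  out[]
}
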