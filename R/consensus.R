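# Effective-base-depth (EBD) consensus calling and window slicing.

#' EBD-weighted consensus base from a stack of reads
#'
#' The effective base depth of base `b` is the sum, over reads carrying
#' `b`, of `(1 - 10^(-MAPQ/10)) * (1 - 10^(-BQ/10))` — the joint
#' probability that the read is correctly mapped and correctly called. The
#' base with the highest EBD is emitted; exact ties break lexicographically
#' (A < C < G < T); no surviving reads yield `N`.
#'
#' @param bases read bases.
#' @param bq,mapq Phred base and mapping qualities.
#' @return single character.
#' @export
ebd_call <- function(bases, bq, mapq) {
  if (length(bases) == 0) return("N")
  w <- (1 - phred_to_prob(mapq)) * (1 - phred_to_prob(bq))
  ebd <- vapply(.BASES, function(b) sum(w[bases == b]), 0)
  .BASES[which.max(ebd)]  # which.max takes the first maximum: lexicographic
}

#' Per-sample consensus sequence for one window
#'
#' Applies [ebd_call()] position-wise to a (pre-filtered) pileup restricted
#' to one sample; positions without surviving reads are `N`.
#'
#' @param pileup pileup rows for a single sample (`pos`, `base`, `bq`,
#'   `mapq`), positions 1-based within the scaffold.
#' @param window one-row window table (`start`, `end`).
#' @return character vector of length `end - start` over `{A,C,G,T,N}`.
#' @export
ebd_consensus <- function(pileup, window) {
  L <- window$end - window$start
  out <- rep("N", L)
  dt <- data.table(pileup)[pos > window$start & pos <= window$end]
  if (nrow(dt) == 0) return(out)
  dt[, w := (1 - phred_to_prob(mapq)) * (1 - phred_to_prob(bq))]
  agg <- dt[, .(ebd = sum(w)), by = .(pos, base)]
  setorder(agg, pos, -ebd, base)   # ties: lexicographically first base wins
  top <- agg[!duplicated(pos)]
  out[top$pos - window$start] <- top$base
  out
}

#' Consensus base matrix at candidate variant sites for all samples
#'
#' Vectorized EBD consensus over an entire (filtered) pileup, returning one
#' call per (site, sample): the scalable path for divergence and window
#' trees when invariant positions are implicitly reference-certain.
#'
#' @param pileup filtered pileup data.table.
#' @param samples character vector fixing column order.
#' @param sites data.table (`scaffold`, `pos`) fixing row order.
#' @return character matrix sites x samples over `{A,C,G,T,N}`.
#' @export
consensus_matrix <- function(pileup, samples, sites) {
  sites <- data.table(sites)[, .(scaffold, pos)]
  sites[, site_i := .I]
  dt <- data.table(pileup)[sample_id %in% samples]
  dt <- sites[dt, on = c("scaffold", "pos"), nomatch = NULL]
  out <- matrix("N", nrow(sites), length(samples),
                dimnames = list(NULL, samples))
  if (nrow(dt) == 0) return(out)
  dt[, w := (1 - phred_to_prob(mapq)) * (1 - phred_to_prob(bq))]
  agg <- dt[, .(ebd = sum(w)), by = .(site_i, sample_id, base)]
  setorder(agg, site_i, sample_id, -ebd, base)
  top <- agg[!duplicated(paste(site_i, sample_id))]
  out[cbind(top$site_i, match(top$sample_id, samples))] <- top$base
  out
}

#' Slice whole-scaffold sequences into nonoverlapping window alignments
#'
#' @param seqs named character vector of per-sample scaffold sequences
#'   (all the same length), or a samples x positions character matrix.
#' @param window_length window size in bp; incomplete terminal windows are
#'   dropped.
#' @return list of character matrices (samples x window_length), one per
#'   window, named `start_end` with 0-based half-open coordinates; record
#'   order follows the input order.
#' @export
slice_windows <- function(seqs, window_length) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      bad <- names(seqs)[which(lens != max(lens))]
      stop("sequence length mismatch for sample(s): ",
           paste(bad, collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  L <- ncol(mat)
  n_win <- floor(L / window_length)
  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    s <- (i - 1) * window_length
    out[[i]] <- mat[, (s + 1):(s + window_length), drop = FALSE]
    names(out)[i] <- sprintf("%d_%d", s, s + window_length)
  }
  out
}
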