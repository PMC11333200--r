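#' Nucleotide alphabet used throughout
#' @keywords internal
.BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed from a master seed
#'
#' Every randomized stage consumes an explicit seed derived from the master
#' seed, a stream label and an index, so that stages are reproducible in
#' isolation and insensitive to execution order. The result always fits in a
#' 32-bit signed integer.
#'
#' @param seed master seed (integer-like scalar).
#' @param stream integer stream identifier (one per stage).
#' @param index per-item index within the stream (e.g. window number).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    as.numeric(stream) * 7919 +
    as.numeric(index) * 104729
  as.integer(s %% 2147483646) + 1L
}

#' Phred quality to error probability and back
#' @param q Phred-scaled quality score(s).
#' @return error probability `10^(-q/10)`.
#' @export
phred_to_prob <- function(q) 10^(-q / 10)

#' @rdname phred_to_prob
#' @param p error probability in (0, 1].
#' @export
prob_to_phred <- function(p) -10 * log10(p)

#' Harmonic-number constant a1 = sum_{i=1}^{n-1} 1/i
#' @param n haploid sample size.
#' @keywords internal
harmonic_a1 <- function(n) sum(1 / seq_len(n - 1))

.msg <- function(...) {
  if (isTRUE(getOption("glscape.verbose", FALSE))) message(sprintf(...))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the p-value comes from the usual
#' t approximation on `n - 2` degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors; pairs with any NA are dropped.
#' @return list with `estimate`, `p.value` and `n`.
#' @export
spearman_rs <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(estimate = NA_real_, p.value = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  if (is.na(r) || abs(r) >= 1) {
    p <- if (is.na(r)) NA_real_ else 0
    return(list(estimate = r, p.value = p, n = n))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(estimate = r, p.value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}
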