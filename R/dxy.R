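# Between-group sequence divergence (dXY).

#' dXY from a window alignment
#'
#' Mean over all between-group sequence pairs of
#' `differences / compared sites`, with positions carrying `N` in either
#' sequence excluded pairwise. Symmetric in the two groups.
#'
#' @param aln character matrix samples x positions over `{A,C,G,T,N}`.
#' @param groups named character vector mapping each row of `aln` to a group
#'   (e.g. species), or a metadata data.frame with `sample_id` and `species`.
#' @param pair length-2 character: the two group labels to compare.
#' @return per-site mean divergence (NA when no pair has comparable sites).
#' @export
dxy <- function(aln, groups, pair) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$species, groups$sample_id)
  }
  g <- groups[rownames(aln)]
  ra <- which(g == pair[1])
  rb <- which(g == pair[2])
  if (!length(ra) || !length(rb)) stop("pair groups absent from alignment")
  vals <- numeric(0)
  for (i in ra) for (j in rb) {
    ok <- aln[i, ] != "N" & aln[j, ] != "N"
    if (!any(ok)) next
    vals <- c(vals, sum(aln[i, ok] != aln[j, ok]) / sum(ok))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Per-window dXY scan for all species pairs
#'
#' Works from a consensus base matrix restricted to candidate variant sites
#' plus the window length: invariant positions are identical across samples
#' and comparable whenever called, so each sequence pair contributes
#' `(L - n_var_w) + comparable variant sites` compared positions and its
#' differences arise at variant sites only. When `invariant_callable` is
#' FALSE the denominator uses variant sites alone.
#'
#' @param cons character matrix sites x samples (variant sites).
#' @param sites data.table (`scaffold`, `pos`) matching `cons` rows.
#' @param metadata sample metadata with `sample_id`, `species`.
#' @param windows window table.
#' @param pairs optional 2-column matrix/data.frame of species pairs
#'   (default: all unordered pairs).
#' @param invariant_callable treat non-variant window positions as compared
#'   sites (default TRUE).
#' @return data.table `window_id`, `sp1`, `sp2`, `dxy`, `n_var`.
#' @export
dxy_scan <- function(cons, sites, metadata, windows, pairs = NULL,
                     invariant_callable = TRUE) {
  species <- sort(unique(metadata$species))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(species, 2))
  }
  wid <- assign_windows(windows, sites$scaffold, sites$pos)
  L <- windows$end[1] - windows$start[1]
  win_ids <- windows$window_id
  widx <- match(wid, win_ids)
  nvar_w <- tabulate(widx, nbins = length(win_ids))
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    spA <- pairs[p, 1]; spB <- pairs[p, 2]
    sa <- metadata$sample_id[metadata$species == spA]
    sb <- metadata$sample_id[metadata$species == spB]
    num <- den <- matrix(0, length(win_ids), length(sa) * length(sb))
    cp <- 0L
    for (i in sa) for (j in sb) {
      cp <- cp + 1L
      ok <- cons[, i] != "N" & cons[, j] != "N" & !is.na(widx)
      dif <- ok & (cons[, i] != cons[, j])
      num[, cp] <- tabulate(widx[dif], nbins = length(win_ids))
      den[, cp] <- tabulate(widx[ok], nbins = length(win_ids))
    }
    if (invariant_callable) {
      den <- den + (L - as.vector(nvar_w))
    }
    ratio <- num / den
    ratio[den == 0] <- NA
    out[[p]] <- data.table(window_id = win_ids, sp1 = spA, sp2 = spB,
                           dxy = rowMeans(ratio, na.rm = FALSE),
                           n_var = as.vector(nvar_w))
  }
  rbindlist(out)
}
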