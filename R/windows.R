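#' Tile scaffolds into nonoverlapping windows
#'
#' Windows are 0-based half-open `[start, end)` intervals of fixed length.
#' Scaffolds shorter than `min_scaffold_length` are excluded entirely;
#' incomplete terminal windows are dropped, not truncated, so per-window site
#' counts stay comparable.
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @param window_length window size in bp.
#' @param min_scaffold_length scaffolds below this length are skipped
#'   (e.g. 2e6 to restrict sliding statistics to scaffolds > 2 Mb).
#' @return a data.table with columns `window_id` (1-based, global),
#'   `scaffold`, `start`, `end`, `index` (1-based within scaffold).
#' @export
make_windows <- function(scaffold_lengths, window_length,
                         min_scaffold_length = 0) {
  stopifnot(window_length > 0, !is.null(names(scaffold_lengths)))
  keep <- scaffold_lengths >= min_scaffold_length
  scaffold_lengths <- scaffold_lengths[keep]
  out <- lapply(names(scaffold_lengths), function(sc) {
    n <- floor(scaffold_lengths[[sc]] / window_length)
    if (n == 0) return(NULL)
    data.table(
      scaffold = sc,
      start = as.integer((seq_len(n) - 1) * window_length),
      end = as.integer(seq_len(n) * window_length),
      index = seq_len(n)
    )
  })
  out <- rbindlist(out)
  if (nrow(out) == 0) stop("no complete windows; check window_length")
  out[, window_id := .I]
  setcolorder(out, c("window_id", "scaffold", "start", "end", "index"))
  out[]
}

#' Assign 1-based positions to windows
#'
#' @param windows window table from [make_windows()].
#' @param scaffold,pos vectors of scaffold names and 1-based positions.
#' @return integer window ids (NA for positions outside any window).
#' @export
assign_windows <- function(windows, scaffold, pos) {
  dt <- data.table(scaffold = scaffold, pos0 = as.integer(pos) - 1L)
  win <- data.table(windows)
  res <- win[dt, on = .(scaffold, start <= pos0, end > pos0),
             x.window_id, mult = "first"]
  res
}

#' Gene density and gene count per window
#'
#' Gene density is the fraction of window bases covered by (merged) gene
#' intervals; overlapping genes are merged before coverage is computed so a
#' base is never counted twice. Gene count is the number of genes whose
#' interval intersects the window, so a gene spanning a window boundary
#' counts in both windows. Intervals extending beyond the window universe
#' are clipped with a warning.
#'
#' @param genes data.frame/data.table with columns `scaffold`, `start`,
#'   `end` (0-based half-open), one row per gene.
#' @param windows window table from [make_windows()].
#' @return data.table `window_id`, `gene_density`, `gene_count`.
#' @export
gene_density_track <- function(genes, windows) {
  win <- data.table(windows)
  if (is.null(genes) || nrow(genes) == 0) {
    return(win[, .(window_id, gene_density = 0, gene_count = 0L)])
  }
  g <- data.table(genes)[, .(scaffold, start, end)]
  if (any(g$end <= g$start)) stop("gene intervals must satisfy start < end")
  scaf_len <- win[, .(len = max(end)), by = scaffold]
  g <- scaf_len[g, on = "scaffold"]
  if (any(is.na(g$len))) {
    g <- g[!is.na(len)]
  }
  if (any(g$start < 0 | g$end > g$len)) {
    warning("gene intervals outside scaffold bounds were clipped")
    g[, start := pmax(start, 0L)]
    g[, end := pmin(end, len)]
    g <- g[end > start]
  }
  gr <- GenomicRanges::GRanges(g$scaffold,
                               IRanges::IRanges(g$start + 1L, g$end))
  wr <- GenomicRanges::GRanges(win$scaffold,
                               IRanges::IRanges(win$start + 1L, win$end))
  merged <- GenomicRanges::reduce(gr)
  cov <- GenomicRanges::intersect(wr, merged)
  # per-window covered bases
  hits <- GenomicRanges::findOverlaps(wr, cov)
  covered <- rep(0, length(wr))
  if (length(hits)) {
    wdt <- data.table(
      qi = S4Vectors::queryHits(hits),
      width = IRanges::width(IRanges::pintersect(
        IRanges::ranges(wr)[S4Vectors::queryHits(hits)],
        IRanges::ranges(cov)[S4Vectors::subjectHits(hits)]))
    )
    agg <- wdt[, .(bp = sum(width)), by = qi]
    covered[agg$qi] <- agg$bp
  }
  cnt_hits <- GenomicRanges::countOverlaps(wr, gr)
  win[, .(window_id,
          gene_density = covered / (end - start),
          gene_count = as.integer(cnt_hits))]
}
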