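# Readers, writers, and read/site filtering.
#
# Internally all coordinates are 0-based half-open; TSV pileup positions and
# FASTA headers use 1-based coordinates, BED stays 0-based half-open.

#' Read/site filtering thresholds
#'
#' Defaults follow common low-coverage practice for quality filtering of
#' mapped reads: base quality and mapping quality thresholds are exclusive
#' ("at or below is discarded"), per-individual site depth must fall inside
#' `[depth_min, depth_max]`, SAM-style flags at or above 256 mark
#' secondary/poor alignments, and a site is discarded when more than
#' `max_missing_fraction` of the individuals are missing after filtering.
#'
#' @param min_mapq discard reads with MAPQ <= this value.
#' @param min_baseq discard reads with base quality <= this value.
#' @param flag_threshold discard reads with flag >= this value.
#' @param depth_min,depth_max retain an individual at a site only when its
#'   filtered depth lies in `[depth_min, depth_max]`.
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   individuals per site.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_mapq = 30, min_baseq = 20, flag_threshold = 256,
                          depth_min = 2, depth_max = 100,
                          max_missing_fraction = 1 / 3) {
  stopifnot(depth_min <= depth_max, max_missing_fraction >= 0,
            max_missing_fraction < 1)
  structure(list(min_mapq = min_mapq, min_baseq = min_baseq,
                 flag_threshold = flag_threshold,
                 depth_min = depth_min, depth_max = depth_max,
                 max_missing_fraction = max_missing_fraction),
            class = "filter_config")
}

#' Filter pileup observations
#'
#' Applies, in order: read-level filters (flag, mapping quality, base
#' quality), the per-individual depth window, and the per-site missingness
#' rule (an individual with no surviving reads at a site is missing; sites
#' missing in more than `max_missing_fraction` of `samples` are dropped).
#'
#' @param pileup data.table with columns `scaffold`, `pos`, `sample_id`,
#'   `base`, `bq`, `mapq` and optionally `flag`.
#' @param filters a [filter_config()].
#' @param samples character vector of all individuals in scope (defines the
#'   denominator of the missingness rule); defaults to the samples present
#'   anywhere in the pileup.
#' @return list with `pileup` (surviving rows), `site_depth` (per
#'   site/sample filtered depth) and `dropped_sites` (count).
#' @export
filter_observations <- function(pileup, filters = filter_config(),
                                samples = NULL) {
  dt <- data.table(pileup)
  req <- c("scaffold", "pos", "sample_id", "base", "bq", "mapq")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("pileup lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(samples)) samples <- unique(dt$sample_id)
  if (!"flag" %in% names(dt)) dt[, flag := 0L]
  n_total <- length(samples)

  dt <- dt[flag < filters$flag_threshold &
             mapq > filters$min_mapq &
             bq > filters$min_baseq]
  depth_tab <- dt[, .(depth = .N), by = .(scaffold, pos, sample_id)]
  good <- depth_tab[depth >= filters$depth_min & depth <= filters$depth_max]
  dt <- dt[good[, .(scaffold, pos, sample_id)],
           on = c("scaffold", "pos", "sample_id")]

  present <- good[, .(n_present = .N), by = .(scaffold, pos)]
  keep_sites <- present[(n_total - n_present) / n_total <=
                          filters$max_missing_fraction]
  dropped <- nrow(present) - nrow(keep_sites)
  dt <- dt[keep_sites[, .(scaffold, pos)], on = c("scaffold", "pos")]
  good <- good[keep_sites[, .(scaffold, pos)], on = c("scaffold", "pos")]
  .msg("filter_observations: %d sites dropped for missingness", dropped)
  list(pileup = dt, site_depth = good, dropped_sites = dropped)
}

#' Write / read the pileup GL TSV
#'
#' Tab-separated with fixed column order `scaffold, pos, sample_id, base,
#' bq, mapq, flag`; positions are 1-based.
#'
#' @param pileup pileup data.table.
#' @param path file path.
#' @export
write_gl_tsv <- function(pileup, path) {
  cols <- c("scaffold", "pos", "sample_id", "base", "bq", "mapq", "flag")
  dt <- data.table(pileup)
  if (!"flag" %in% names(dt)) dt[, flag := 0L]
  fwrite(dt[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_gl_tsv
#' @return `read_gl_tsv` returns the pileup data.table.
#' @export
read_gl_tsv <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("scaffold", "sample_id", "base"),
                                integer = c("pos", "bq", "mapq", "flag")))
  setorder(dt, scaffold, pos, sample_id)
  dt[]
}

#' Read a sample metadata TSV
#'
#' Expects columns `sample_id`, `species`, `population`, `location` and
#' optionally `lat`, `lon` (decimal degrees).
#' @param path file path.
#' @export
read_metadata_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  req <- c("sample_id", "species", "population", "location")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  as.data.frame(dt)
}

#' Write 0-based half-open intervals as BED
#' @param intervals data.table with `scaffold`, `start`, `end` and optional
#'   name column (4th column).
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  dt <- data.table(intervals)
  cols <- intersect(c("scaffold", "start", "end", "gene_id"), names(dt))
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (BED or GFF3)
#'
#' BED intervals are taken as already 0-based half-open. For GFF3, only
#' records with `type == "gene"` are retained and converted from 1-based
#' closed to 0-based half-open coordinates.
#'
#' @param path `.bed`, `.gff`, `.gff3` file.
#' @return data.table `scaffold`, `start`, `end`, `gene_id`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    dt <- fread(path, sep = "\t", header = FALSE)
    if (ncol(dt) < 3) stop("BED needs at least 3 columns: ", path)
    setnames(dt, seq_len(3), c("scaffold", "start", "end"))
    if (ncol(dt) >= 4) setnames(dt, 4, "gene_id")
    else dt[, gene_id := sprintf("gene%06d", .I)]
    return(dt[, .(scaffold = as.character(scaffold),
                  start = as.integer(start), end = as.integer(end),
                  gene_id = as.character(gene_id))])
  }
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID)
           else sprintf("gene%06d", seq_along(gr))
    return(data.table(scaffold = as.character(GenomicRanges::seqnames(gr)),
                      start = as.integer(GenomicRanges::start(gr)) - 1L,
                      end = as.integer(GenomicRanges::end(gr)),
                      gene_id = ids))
  }
  stop("unsupported annotation format: ", path)
}

#' Write / read a per-window multi-sample FASTA alignment
#'
#' One record per sample, record order preserved; sequences use the
#' `{A,C,G,T,N}` alphabet.
#'
#' @param aln character matrix samples x positions (rownames = sample ids)
#'   or a named character vector of sequences.
#' @param path file path.
#' @export
write_window_fasta <- function(aln, path) {
  if (is.matrix(aln)) {
    seqs <- apply(aln, 1, paste0, collapse = "")
  } else {
    seqs <- aln
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_window_fasta
#' @return `read_window_fasta` returns a character matrix samples x sites.
#' @export
read_window_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  mat <- t(vapply(as.character(ss),
                  function(s) strsplit(s, "", fixed = TRUE)[[1]],
                  character(Biostrings::width(ss)[1])))
  rownames(mat) <- names(ss)
  mat
}
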