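# Bundled example study design.

#' Example multi-species sampling design
#'
#' Per-population sample counts for a 12-species peatmoss resequencing
#' design spanning two Austrian (A1, A2), two Norwegian (N1, N2) and one
#' German (G) sampling location — the kind of sympatric/allopatric layout
#' the spatial contrasts in this package expect. Shipped as a plain TSV
#' under `inst/extdata`.
#'
#' @return data.frame with one row per species: per-location counts and
#'   the per-species `total`.
#' @export
read_sampling_design <- function() {
  path <- system.file("extdata", "sampling_design.tsv", package = "glscape")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  df
}

#' Bookkeeping totals of a sampling design
#'
#' @param design data.frame from [read_sampling_design()].
#' @return list: `per_species` (named vector summed over populations),
#'   `grand_total` (sum over species), `stated_total` (sum of the `total`
#'   column).
#' @export
sampling_totals <- function(design = read_sampling_design()) {
  pop_cols <- setdiff(names(design), c("species", "subgenus", "total"))
  per_species <- rowSums(design[, pop_cols])
  names(per_species) <- design$species
  list(per_species = per_species,
       grand_total = sum(per_species),
       stated_total = sum(design$total))
}
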