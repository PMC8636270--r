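#' Long-format taxon count table
#'
#' One row per sample/taxon with a category label: `organellar`
#' (chloroplast or mitochondrial 16S reads), `symbiont` (the
#' diazotroph-related reads, a subset of the bacterial reads), or
#' `bacterial` (all other bacteria). Category assignment comes from an
#' input mapping, not from taxonomy inference.
#'
#' @param df data frame with columns `sample_id`, `taxon_id`, `count`,
#'   `category`.
#' @return The validated data frame with class `taxon_count_table`.
#' @export
taxon_count_table <- function(df) {
  need <- c("sample_id", "taxon_id", "count", "category")
  if (!all(need %in% names(df))) {
    stop("taxon count table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$count < 0)) stop("counts must be non-negative")
  bad <- setdiff(unique(df$category), c("bacterial", "organellar", "symbiont"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  class(df) <- c("taxon_count_table", "data.frame")
  df
}

#' Organellar read fraction per sample
#'
#' Fraction of each sample's total reads classified as organellar
#' (chloroplast + mitochondria). A low fraction indicates that the root
#' material, and hence its endophytic community, is poorly represented in
#' the library.
#'
#' @param table a [taxon_count_table()].
#' @return Data frame with `sample_id`, `total_reads`, `organellar_reads`,
#'   `organellar_fraction` (NA for zero-read samples).
#' @export
organellar_fraction <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  tot <- tapply(table$count, table$sample_id, sum)
  org <- tapply(ifelse(table$category == "organellar", table$count, 0),
                table$sample_id, sum)
  data.frame(sample_id = names(tot),
             total_reads = as.vector(tot),
             organellar_reads = as.vector(org),
             organellar_fraction = ifelse(tot > 0, org / tot, NA_real_),
             row.names = NULL)
}

#' Exclude samples with too few organellar reads
#'
#' Samples below the minimum organellar-read fraction (default 10% of the
#' total reads) are excluded. The boundary is inclusive: a sample at
#' exactly the cut-off is retained ("a minimum of" semantics). Zero-read
#' samples are excluded with their own reason.
#'
#' @param table a [taxon_count_table()].
#' @param min_frac minimum organellar fraction (default 0.10).
#' @return List with `retained` (filtered table), `report` (per-sample
#'   fraction and decision), and `excluded` (sample ids with reasons).
#' @export
apply_qc <- function(table, min_frac = 0.10) {
  fr <- organellar_fraction(table)
  fr$retained <- !is.na(fr$organellar_fraction) &
    fr$organellar_fraction >= min_frac
  fr$reason <- ifelse(fr$retained, "",
                      ifelse(fr$total_reads == 0, "zero reads",
                             sprintf("organellar fraction below %.0f%%",
                                     100 * min_frac)))
  keep_ids <- fr$sample_id[fr$retained]
  retained <- table[table$sample_id %in% keep_ids, , drop = FALSE]
  class(retained) <- class(table)
  list(retained = retained, report = fr,
       excluded = fr[!fr$retained, c("sample_id", "reason")])
}

#' Symbiont-to-organellar read ratio per sample
#'
#' The ratio of symbiont reads to organellar reads; since the organellar
#' reads scale with the amount of root material in the library, the ratio
#' is a proxy for changes in the symbiont's absolute abundance between
#' plants (computed before organellar reads are discarded).
#'
#' @param table a [taxon_count_table()].
#' @return Data frame with `sample_id`, `symbiont_reads`,
#'   `organellar_reads`, `ratio` (NA and flagged when organellar reads are
#'   zero).
#' @export
symbiont_organellar_ratio <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  org <- tapply(ifelse(table$category == "organellar", table$count, 0),
                table$sample_id, sum)
  sym <- tapply(ifelse(table$category == "symbiont", table$count, 0),
                table$sample_id, sum)
  data.frame(sample_id = names(org),
             symbiont_reads = as.vector(sym),
             organellar_reads = as.vector(org),
             ratio = ifelse(org > 0, sym / org, NA_real_),
             undefined = as.vector(org) == 0,
             row.names = NULL)
}
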