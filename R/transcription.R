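#' Default housekeeping gene set
#'
#' Single-copy genes with stable constitutive transcription commonly used
#' to anchor relative transcription levels in bacteria.
#' @return Character vector of gene names.
#' @export
default_housekeeping_genes <- function() {
  c("rpoA", "rpoB", "ftsZ", "rho", "recN", "gyrB", "recA", "gyrA")
}

#' Transcripts per million (TPM)
#'
#' Per sample, `TPM_i = (c_i / l_i) * 1 / sum_j(c_j / l_j) * 10^6` with
#' counts `c` and feature lengths `l` in kilobases, so each sample's TPM
#' values sum to one million. Lengths supplied in base pairs (values
#' clearly too large for kb) must be converted by the caller; set
#' `length_in_bp = TRUE` to auto-convert with a message.
#'
#' @param table data frame with `feature_id`, `sample_id`, `count` and
#'   `length_kb` (or `length_bp` with `length_in_bp = TRUE`).
#' @param length_in_bp whether lengths are in bp and must be divided by
#'   1000.
#' @return The table with a `tpm` column appended; class `tpm_table`.
#' @export
tpm <- function(table, length_in_bp = FALSE) {
  stopifnot(is.data.frame(table))
  if (is.null(table$sample_id)) table$sample_id <- "sample_1"
  if (length_in_bp) {
    message("converting feature lengths from bp to kb")
    table$length_kb <- table$length_bp / 1000
  }
  need <- c("feature_id", "count", "length_kb")
  if (!all(need %in% names(table))) {
    stop("count table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(table$count < 0)) stop("counts must be non-negative")
  if (any(table$length_kb <= 0)) stop("feature lengths must be positive")
  table$tpm <- NA_real_
  for (s in unique(table$sample_id)) {
    sel <- table$sample_id == s
    rate <- table$count[sel] / table$length_kb[sel]
    if (sum(rate) == 0) {
      stop(sprintf("sample '%s' has no counts: TPM undefined", s))
    }
    table$tpm[sel] <- rate / sum(rate) * 1e6
  }
  class(table) <- c("tpm_table", "data.frame")
  table
}

#' Normalize TPM to the mean of housekeeping genes
#'
#' Per sample, divides each feature's TPM by the mean TPM of the
#' housekeeping set, yielding dimensionless transcription levels in which
#' 1.0 means "transcribed like an average housekeeping gene".
#'
#' @param tpm_table output of [tpm()].
#' @param hk_ids housekeeping feature ids
#'   (default [default_housekeeping_genes()]).
#' @return The table with an `hk_scaled` column appended.
#' @export
housekeeping_normalize <- function(tpm_table, hk_ids = default_housekeeping_genes()) {
  stopifnot(inherits(tpm_table, "tpm_table"))
  tpm_table$hk_scaled <- NA_real_
  for (s in unique(tpm_table$sample_id)) {
    sel <- tpm_table$sample_id == s
    ids <- tpm_table$feature_id[sel]
    miss <- setdiff(hk_ids, ids)
    if (length(miss)) {
      stop(sprintf("sample '%s' is missing housekeeping feature(s): %s",
                   s, paste(miss, collapse = ", ")))
    }
    hk_mean <- mean(tpm_table$tpm[sel][ids %in% hk_ids])
    if (hk_mean <= 0) {
      stop(sprintf("sample '%s' has zero mean housekeeping TPM", s))
    }
    tpm_table$hk_scaled[sel] <- tpm_table$tpm[sel] / hk_mean
  }
  tpm_table
}
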