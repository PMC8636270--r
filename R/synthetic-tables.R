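#' Simulate a feature count table for TPM normalization
#'
#' Feature lengths are log-normal around 1 kb and counts negative binomial,
#' loosely emulating prokaryotic gene lengths and transcript coverage. The
#' first features are named after the default housekeeping genes (when
#' `n_features` allows) so the housekeeping normalization is exercisable
#' out of the box.
#'
#' @param n_features number of features (>= 1).
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param mean_count negative-binomial mean count.
#' @return Long data frame with `feature_id`, `sample_id`, `count`,
#'   `length_kb`.
#' @export
gen_count_table <- function(n_features, n_samples = 1, seed = 1,
                            mean_count = 500) {
  stopifnot(n_features >= 1, n_samples >= 1)
  with_seed(seed, {
    hk <- default_housekeeping_genes()
    ids <- c(hk[seq_len(min(length(hk), n_features))],
             sprintf("gene_%04d", seq_len(max(0, n_features - length(hk)))))
    len_kb <- pmin(pmax(exp(stats::rnorm(n_features, 0, 0.5)), 0.2), 10)
    out <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
      data.frame(feature_id = ids,
                 sample_id = sprintf("sample_%d", s),
                 count = stats::rnbinom(n_features, mu = mean_count, size = 2),
                 length_kb = len_kb)
    }))
    # guarantee a defined normalization and positive housekeeping mean
    for (s in unique(out$sample_id)) {
      sel <- out$sample_id == s & out$feature_id %in% hk
      if (any(sel)) out$count[sel] <- pmax(out$count[sel], 1L)
      else {
        first <- which(out$sample_id == s)[1]
        out$count[first] <- max(out$count[first], 1L)
      }
    }
    out
  })
}

#' Simulate an amplicon taxon count table with known read fractions
#'
#' Per sample, reads are split between organellar taxa (chloroplast and
#' mitochondria), a symbiont taxon, and other bacterial taxa according to
#' the supplied expected fractions. With `stochastic = TRUE` the split is
#' multinomial; otherwise the expected counts are rounded, which realizes
#' the requested fractions exactly (useful for boundary tests of the QC
#' cut-off).
#'
#' @param n_samples number of samples.
#' @param organellar_fracs expected organellar read fraction per sample
#'   (recycled).
#' @param symbiont_fracs expected symbiont read fraction per sample
#'   (recycled); symbiont reads are bacterial, so
#'   `organellar + symbiont <= 1` is required.
#' @param seed RNG seed.
#' @param total_reads reads per sample.
#' @param stochastic multinomial draw (default) vs. exact expected counts.
#' @return A [taxon_count_table()]; the expected fractions are attached as
#'   attribute `truth`.
#' @export
gen_amplicon_table <- function(n_samples, organellar_fracs, symbiont_fracs,
                               seed = 1, total_reads = 10000,
                               stochastic = TRUE) {
  stopifnot(n_samples >= 1)
  of <- rep_len(organellar_fracs, n_samples)
  sf <- rep_len(symbiont_fracs, n_samples)
  if (any(of < 0 | of > 1 | sf < 0 | sf > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (any(of + sf > 1)) {
    stop("organellar + symbiont fractions exceed 1 for some sample")
  }
  with_seed(seed, {
    taxa <- c(chloroplast = "organellar", mitochondria = "organellar",
              Celerinatantimonas = "symbiont",
              bact_A = "bacterial", bact_B = "bacterial", bact_C = "bacterial")
    rows <- lapply(seq_len(n_samples), function(i) {
      other <- 1 - of[i] - sf[i]
      probs <- c(0.6 * of[i], 0.4 * of[i], sf[i],
                 other * c(0.5, 0.3, 0.2))
      counts <- if (stochastic) {
        as.vector(stats::rmultinom(1, total_reads, probs))
      } else {
        round(probs * total_reads)
      }
      data.frame(sample_id = sprintf("sample_%d", i),
                 taxon_id = names(taxa),
                 count = counts,
                 category = unname(taxa))
    })
    tab <- taxon_count_table(do.call(rbind, rows))
    attr(tab, "truth") <- data.frame(sample_id = sprintf("sample_%d", seq_len(n_samples)),
                                     organellar_frac = of, symbiont_frac = sf)
    tab
  })
}
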