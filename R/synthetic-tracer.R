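#' Ground truth for a synthetic 15N2 tracer incubation
#'
#' Defines the per-tissue true N2-fixation / N-transfer rates and the
#' incubation conditions emulated by [gen_tissue_isotopes()]. Defaults
#' reflect a typical whole-plant incubation: a 24-h incubation, eight
#' measured pieces per tissue, natural-abundance variability of 0.3 per mil
#' between pieces, and tissue N contents of roughly 1% (roots), 0.7%
#' (rhizomes) and 2% (leaves) of dry weight.
#'
#' @param rates named vector of true rates (µmol N gDW^-1 d^-1) for tissues
#'   `root`, `rhizome`, `leaf`.
#' @param pool_atpct at% 15N of the dissolved N2 pool (must exceed natural
#'   abundance).
#' @param na_mean,na_sd mean and s.d. of natural-abundance delta15N
#'   (per mil) across pieces.
#' @param n_pieces pieces measured per tissue (>= 1).
#' @param t incubation time in days (> 0).
#' @param n_content named per-tissue N content (µmol N gDW^-1).
#' @param dry_weight named per-tissue piece dry weight (g).
#' @param seed RNG seed.
#' @return List of class `rate_truth`.
#' @export
rate_truth <- function(rates = c(root = 0.5, rhizome = 0.05, leaf = 0.05),
                       pool_atpct = 5.4, na_mean = 2.4, na_sd = 0.3,
                       n_pieces = 8, t = 1,
                       n_content = c(root = 700, rhizome = 500, leaf = 1500),
                       dry_weight = c(root = 0.2, rhizome = 1.0, leaf = 0.5),
                       seed = 1) {
  stopifnot(n_pieces >= 1, t > 0, na_sd >= 0, all(rates >= 0))
  if (pool_atpct <= delta_to_atpct(na_mean)) {
    stop("pool_atpct must exceed the natural-abundance at%")
  }
  tissues <- names(rates)
  if (is.null(tissues) || !all(tissues %in% c("root", "rhizome", "leaf"))) {
    stop("rates must be named with tissues among root/rhizome/leaf")
  }
  structure(list(rates = rates, pool_atpct = pool_atpct, na_mean = na_mean,
                 na_sd = na_sd, n_pieces = as.integer(n_pieces), t = t,
                 n_content = n_content[tissues], dry_weight = dry_weight[tissues],
                 seed = as.integer(seed)),
            class = "rate_truth")
}

#' Simulate an EA-IRMS tissue isotope table
#'
#' Emulates the bulk measurements from a whole-plant 15N2 incubation: one
#' labelled plant plus one incubated control plant, each dissected into
#' `n_pieces` pieces per tissue. Each piece gets a natural-abundance
#' baseline `delta ~ N(na_mean, na_sd)`; labelled pieces additionally carry
#' the at% excess implied by the true rate,
#' `excess = rate * t / n_content * (at%_N2 - at%_NA)`, which is the exact
#' inverse of the tracer mass-balance rate equation, so with `na_sd = 0` the
#' downstream rate calculation recovers the truth exactly. Piece N content
#' and dry weight vary log-normally (10%) around the tissue means and the
#' realized values are recorded in the table.
#'
#' @param truth a [rate_truth()].
#' @param plant_id,control_id identifiers for the labelled and control plant.
#' @param campaign campaign label recorded on every row.
#' @return A data frame of class `tissue_isotope_table` with columns
#'   `plant_id`, `tissue`, `delta15N`, `n_content`, `dry_weight`,
#'   `labelled`, `t`, `campaign`; the `truth` is attached as an attribute.
#' @export
gen_tissue_isotopes <- function(truth, plant_id = "plant_1",
                                control_id = "control_1",
                                campaign = "sim") {
  stopifnot(inherits(truth, "rate_truth"))
  with_seed(truth$seed, {
    at_na_true <- delta_to_atpct(truth$na_mean)
    rows <- list()
    for (tis in names(truth$rates)) {
      for (lab in c(TRUE, FALSE)) {
        n <- truth$n_pieces
        base_delta <- stats::rnorm(n, truth$na_mean, truth$na_sd)
        nc <- truth$n_content[[tis]] * exp(stats::rnorm(n, 0, 0.1))
        dw <- truth$dry_weight[[tis]] * exp(stats::rnorm(n, 0, 0.1))
        at <- delta_to_atpct(base_delta)
        if (lab) {
          excess <- truth$rates[[tis]] * truth$t / nc *
            (truth$pool_atpct - at_na_true)
          at <- at + excess
        }
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = if (lab) plant_id else control_id,
          tissue = tis,
          delta15N = atpct_to_delta(at),
          n_content = nc,
          dry_weight = dw,
          labelled = lab,
          t = truth$t,
          campaign = campaign
        )
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    attr(tab, "truth") <- truth
    class(tab) <- c("tissue_isotope_table", "data.frame")
    tab
  })
}
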