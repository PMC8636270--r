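#' N2-pool enrichment of an incubation
#'
#' The at% 15N of the dissolved N2 pool, measured at the start and end of
#' the incubation and averaged. A dilution mode supports designs where a
#' single batch of enriched water is measured and a known fraction of the
#' incubation water is replaced with it (e.g. replacing about 40% of the
#' water): the final enrichment is the mixing value
#' `frac * batch + (1 - frac) * ambient`.
#'
#' @param atpct_start at% 15N at the start of the incubation.
#' @param atpct_end at% 15N at the end; when omitted the start value is used
#'   alone.
#' @param batch_atpct at% 15N of the enriched water batch (dilution mode).
#' @param dilution_frac fraction of incubation water replaced by the batch.
#' @param ambient_atpct at% 15N of the unenriched water (defaults to natural
#'   abundance).
#' @return List of class `pool_enrichment` with `atpct_start`, `atpct_end`,
#'   `atpct_mean`.
#' @export
pool_enrichment <- function(atpct_start = NULL, atpct_end = NULL,
                            batch_atpct = NULL, dilution_frac = NULL,
                            ambient_atpct = atpct_natural()) {
  if (!is.null(batch_atpct)) {
    stopifnot(!is.null(dilution_frac), dilution_frac > 0, dilution_frac <= 1)
    atpct_start <- dilution_frac * batch_atpct +
      (1 - dilution_frac) * ambient_atpct
    atpct_end <- NULL
  }
  if (is.null(atpct_start)) stop("atpct_start (or a batch measurement) required")
  vals <- c(atpct_start, atpct_end)
  if (any(vals <= atpct_natural() | vals > 100)) {
    stop("pool at% must lie in (natural abundance, 100]")
  }
  structure(list(atpct_start = atpct_start,
                 atpct_end = if (is.null(atpct_end)) atpct_start else atpct_end,
                 atpct_mean = mean(vals)),
            class = "pool_enrichment")
}

#' Detection limit from natural-abundance replicates
#'
#' The minimum resolvable change in delta15N is three times the standard
#' deviation of the natural-abundance measurements within a tissue type.
#' When fewer than two control rows are available the controls measured
#' under the nearest incubation conditions should be substituted (see
#' [compute_rates()]); here that case errors unless a fallback s.d. is
#' given. Propagating the minimum delta change through the rate equation
#' yields the rate-space limit of detection.
#'
#' @param control_delta natural-abundance delta15N values (per mil) of one
#'   tissue type.
#' @param fallback_sd s.d. (per mil) to use when fewer than two controls
#'   are supplied (with a warning).
#' @return `min_delta` in per mil (`3 * sd`).
#' @export
detection_limit <- function(control_delta, fallback_sd = NULL) {
  control_delta <- control_delta[is.finite(control_delta)]
  if (length(control_delta) < 2) {
    if (is.null(fallback_sd)) {
      stop("need >= 2 control rows (or a fallback_sd) for a detection limit")
    }
    warning("fewer than 2 controls: using fallback s.d.")
    return(3 * fallback_sd)
  }
  3 * stats::sd(control_delta)
}

#' Propagate a delta-space detection limit into rate space
#'
#' @param min_delta minimum resolvable delta15N change (per mil).
#' @param na_delta mean natural-abundance delta15N (per mil).
#' @param pool_atpct at% 15N of the N2 pool.
#' @param n_content tissue N content (µmol N gDW^-1).
#' @param t incubation time (d).
#' @return Rate-space LOD in µmol N gDW^-1 d^-1.
#' @export
rate_lod <- function(min_delta, na_delta, pool_atpct, n_content, t) {
  at_na <- delta_to_atpct(na_delta)
  at_min <- delta_to_atpct(na_delta + min_delta)
  (at_min - at_na) / (pool_atpct - at_na) * n_content / t
}

#' Bulk N2 fixation rate from tracer enrichment
#'
#' Standard 15N2 tracer mass balance: the fraction of tissue N derived from
#' the labelled pool times the N content, per unit incubation time:
#' `rate = (at%_sample - at%_NA) / (at%_N2 - at%_NA) * n_content / t`
#' in µmol N gDW^-1 d^-1. Negative rates and rates below the detection
#' limit are censored to zero.
#'
#' @param atpct_sample measured at% 15N of the labelled piece.
#' @param atpct_na natural-abundance background at% 15N.
#' @param pool_atpct at% 15N of the N2 pool (or a [pool_enrichment()]).
#' @param n_content tissue N content (µmol N gDW^-1).
#' @param t incubation time (d).
#' @param lod rate-space detection limit for censoring (default 0: only
#'   negative rates censored).
#' @return Data frame with `rate_raw` (uncensored), `rate` (censored),
#'   `detection_limit`, `censored`. Vectorized over samples.
#' @export
n2_fixation_rate <- function(atpct_sample, atpct_na, pool_atpct, n_content,
                             t, lod = 0) {
  if (inherits(pool_atpct, "pool_enrichment")) pool_atpct <- pool_atpct$atpct_mean
  if (any(pool_atpct <= atpct_na)) stop("pool at% must exceed the background (no tracer)")
  if (any(t <= 0)) stop("incubation time must be positive")
  raw <- (atpct_sample - atpct_na) / (pool_atpct - atpct_na) * n_content / t
  censored <- raw < 0 | raw < lod
  data.frame(rate_raw = raw, rate = ifelse(censored, 0, raw),
             detection_limit = rep_len(lod, length(raw)),
             censored = censored)
}

#' N transfer rate to unlabelled tissue
#'
#' Enrichment in tissue outside the tracer compartment (leaves, in a
#' root/rhizome incubation) can only come from fixed N transported within
#' the plant; the transfer rate therefore uses the identical tracer mass
#' balance and detection-limit treatment as [n2_fixation_rate()].
#'
#' @inheritParams n2_fixation_rate
#' @return See [n2_fixation_rate()].
#' @export
transfer_rate <- function(atpct_sample, atpct_na, pool_atpct, n_content,
                          t, lod = 0) {
  n2_fixation_rate(atpct_sample, atpct_na, pool_atpct, n_content, t, lod)
}

#' Per-piece rates, detection limits and censoring for a tissue table
#'
#' For each tissue type, the natural-abundance background is the mean of
#' the control (unlabelled) delta15N values and the detection limit is
#' three times their s.d.; tissues without controls fall back to the
#' controls of the nearest condition (here: all controls pooled, with a
#' warning). Rates for root and rhizome pieces are N2 fixation rates;
#' leaf pieces are outside the tracer compartment, so their rates are
#' transfer rates computed with the same equation.
#'
#' @param table a `tissue_isotope_table` (see [gen_tissue_isotopes()]):
#'   columns `plant_id`, `tissue`, `delta15N` (or `atpct`), `n_content`,
#'   `dry_weight`, `labelled`, `t`.
#' @param pool a [pool_enrichment()] or the pool at% 15N.
#' @return The labelled rows with columns `rate_raw`, `rate`,
#'   `detection_limit` (rate space), `min_delta` (per mil), `censored`
#'   appended; class `rate_table`.
#' @export
compute_rates <- function(table, pool) {
  stopifnot(is.data.frame(table))
  if (inherits(pool, "pool_enrichment")) pool <- pool$atpct_mean
  if (is.null(table$delta15N)) {
    table$delta15N <- atpct_to_delta(table$atpct)
  }
  lab <- table[table$labelled, , drop = FALSE]
  ctl <- table[!table$labelled, , drop = FALSE]
  if (nrow(ctl) == 0) stop("no control (unlabelled) rows in the table")
  out <- lab
  out$rate_raw <- NA_real_; out$rate <- NA_real_
  out$detection_limit <- NA_real_; out$min_delta <- NA_real_
  out$censored <- NA
  for (tis in unique(lab$tissue)) {
    cd <- ctl$delta15N[ctl$tissue == tis]
    if (length(cd) < 2) {
      warning(sprintf(
        "tissue '%s' has %d control rows: using controls from the nearest condition (all tissues pooled)",
        tis, length(cd)))
      cd <- ctl$delta15N
    }
    na_delta <- mean(cd)
    min_delta <- if (length(cd) >= 2) detection_limit(cd) else 0
    at_na <- delta_to_atpct(na_delta)
    sel <- out$tissue == tis
    lodv <- rate_lod(min_delta, na_delta, pool,
                     out$n_content[sel], out$t[sel])
    rr <- n2_fixation_rate(delta_to_atpct(out$delta15N[sel]), at_na, pool,
                           out$n_content[sel], out$t[sel], lod = lodv)
    out$rate_raw[sel] <- rr$rate_raw
    out$rate[sel] <- rr$rate
    out$detection_limit[sel] <- rr$detection_limit
    out$min_delta[sel] <- min_delta
    out$censored[sel] <- rr$censored
  }
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Classify a plant as N2-fixing or non-fixing
#'
#' A plant is N2-fixing when its average root-associated fixation rate
#' exceeds the average rate detection limit (0.01 µmol N gDW^-1 d^-1 as the
#' default threshold). The boundary case (rate equal to the threshold) is
#' non-fixing (strict `>`).
#'
#' @param root_rates censored root rates of one plant (µmol N gDW^-1 d^-1).
#' @param avg_lod classification threshold (default 0.01).
#' @param stat summary across root pieces (default [mean()]; configurable).
#' @return `"fixing"` or `"non_fixing"`.
#' @export
classify_plant <- function(root_rates, avg_lod = 0.01, stat = mean) {
  if (length(root_rates) < 1) stop("need at least one root rate")
  if (stat(root_rates) > avg_lod) "fixing" else "non_fixing"
}

#' Fraction of freshly fixed N allocated to leaves
#'
#' Per tissue, the excess 15N mass is the excess at% (as a fraction) times
#' the N content times the dry weight; the leaf allocation is the leaf
#' share of the total over root, rhizome and leaf, in percent.
#'
#' @param excess_n named vector (root, rhizome, leaf) of excess 15N masses
#'   (µmol), or computed from `tissues`/`excess_atpct`/`n_content`/
#'   `dry_weight` vectors.
#' @param tissues,excess_atpct,n_content,dry_weight alternative per-piece
#'   specification; masses are summed per tissue.
#' @return Leaf allocation in percent.
#' @export
leaf_allocation_fraction <- function(excess_n = NULL, tissues = NULL,
                                     excess_atpct = NULL, n_content = NULL,
                                     dry_weight = NULL) {
  if (is.null(excess_n)) {
    stopifnot(!is.null(tissues), !is.null(excess_atpct),
              !is.null(n_content), !is.null(dry_weight))
    mass <- excess_atpct / 100 * n_content * dry_weight
    excess_n <- tapply(mass, tissues, sum)
  }
  total <- sum(excess_n)
  if (total <= 0) stop("total excess 15N mass is zero: fraction undefined")
  leaf <- if (!is.null(names(excess_n))) excess_n[["leaf"]] else excess_n[3]
  unname(leaf / total * 100)
}

#' N-supported carbon production budget
#'
#' Scales tissue rates to an areal carbon production: per-shoot N supply is
#' the sum over tissues of rate times biomass; multiplied by shoot density
#' it becomes an areal N supply, and each tissue's N is converted to carbon
#' with its molar C:N ratio. Result in mmol C m^-2 d^-1.
#'
#' @param rates named per-tissue mean rates (µmol N gDW^-1 d^-1).
#' @param biomass named per-tissue biomass per shoot (g DW).
#' @param cn named per-tissue C:N ratios (mol/mol; for mass ratios set
#'   `cn_is_molar = FALSE` and values are converted with 12/14).
#' @param shoot_density shoots per m^2.
#' @param cn_is_molar whether `cn` is molar (default) or a mass ratio.
#' @return List with `areal_n` (µmol N m^-2 d^-1), `c_production`
#'   (mmol C m^-2 d^-1) and the per-tissue breakdown.
#' @export
production_budget <- function(rates, biomass, cn, shoot_density,
                              cn_is_molar = TRUE) {
  tissues <- names(rates)
  missing_of <- function(x, what) {
    miss <- setdiff(tissues, names(x))
    if (length(miss)) stop(sprintf("missing %s for tissue(s): %s",
                                   what, paste(miss, collapse = ", ")))
    x[tissues]
  }
  biomass <- missing_of(biomass, "biomass")
  cn <- missing_of(cn, "C:N")
  if (any(c(rates, biomass, cn, shoot_density) < 0)) {
    stop("budget inputs must be non-negative")
  }
  if (!cn_is_molar) cn <- cn * 14 / 12
  n_per_shoot <- rates * biomass                    # µmol N shoot^-1 d^-1
  areal_n <- n_per_shoot * shoot_density            # µmol N m^-2 d^-1
  c_areal <- areal_n * cn / 1000                    # mmol C m^-2 d^-1
  list(areal_n = sum(areal_n), c_production = sum(c_areal),
       per_tissue = data.frame(tissue = tissues, rate = as.numeric(rates),
                               biomass = as.numeric(biomass),
                               cn = as.numeric(cn),
                               c_production = as.numeric(c_areal)))
}
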