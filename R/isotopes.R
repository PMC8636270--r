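#' Isotope-ratio conversions for 15N
#'
#' Conversions between the delta notation (per mil vs. atmospheric N2, AIR)
#' and atom percent 15N. The anchor is the isotope ratio of AIR,
#' `R_AIR = 0.0036765` (15N/14N), so natural abundance corresponds to
#' delta15N = 0 i.e. about 0.3663 at%.
#'
#' Definitions: `r = R_AIR * (1 + delta/1000)` and `at% = r/(r + 1) * 100`.
#' The pair is an exact bijection on the valid domain; `at% = 100` would
#' correspond to an infinite ratio and is rejected.
#'
#' @param delta15N delta15N values in per mil vs. AIR.
#' @param atpct atom percent 15N, in `[0, 100)`.
#' @return `delta_to_atpct` returns atom percent 15N; `atpct_to_delta`
#'   returns delta15N in per mil.
#' @examples
#' delta_to_atpct(0)            # natural abundance, ~0.3663 at%
#' atpct_to_delta(0.367194)     # ~ +2.4 per mil
#' @name isotope-conversion
NULL

#' @rdname isotope-conversion
#' @export
R_AIR <- 0.0036765

#' @rdname isotope-conversion
#' @export
delta_to_atpct <- function(delta15N) {
  stopifnot(is.numeric(delta15N))
  if (any(delta15N <= -1000, na.rm = TRUE)) {
    stop("delta15N <= -1000 per mil implies a negative isotope ratio")
  }
  r <- R_AIR * (1 + delta15N / 1000)
  r / (r + 1) * 100
}

#' @rdname isotope-conversion
#' @export
atpct_to_delta <- function(atpct) {
  stopifnot(is.numeric(atpct))
  if (any(atpct < 0 | atpct >= 100, na.rm = TRUE)) {
    stop("atom percent must lie in [0, 100); at% = 100 has an infinite ratio")
  }
  f <- atpct / 100
  r <- f / (1 - f)
  (r / R_AIR - 1) * 1000
}

#' Natural-abundance 15N atom percent (delta15N = 0)
#' @return Atom percent 15N of AIR, ~0.3663.
#' @export
atpct_natural <- function() delta_to_atpct(0)

#' Convert an isotope ratio to atom percent
#'
#' `at% = r/(r + 1) * 100`, the conversion applied to measured
#' 15N/14N ratios (e.g. 12C15N-/12C14N- secondary ion count ratios).
#'
#' @param r 15N/14N isotope ratio (non-negative; `NA` passes through).
#' @return Atom percent 15N.
#' @export
ratio_to_atpct_value <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0, na.rm = TRUE)) stop("isotope ratio must be non-negative")
  r / (r + 1) * 100
}
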