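#' Binarize root tissue from the autofluorescence channel
#'
#' Pixels above 1% (default) of the channel's maximum intensity are tissue.
#' White (TRUE) marks tissue, as in the binary matrices used for area
#' quantification.
#'
#' @param green autofluorescence (green) channel matrix.
#' @param threshold_frac threshold as a fraction of the maximum (default 0.01).
#' @return Logical tissue mask.
#' @export
binarize_tissue <- function(green, threshold_frac = 0.01) {
  stopifnot(is.matrix(green), length(green) > 0)
  mx <- max(green)
  if (mx <= 0) {
    warning("all-zero channel: empty tissue mask")
    return(matrix(FALSE, nrow(green), ncol(green)))
  }
  green > threshold_frac * mx
}

#' Detect hybridized cells from the combined red and blue channels
#'
#' Positively hybridized cells carry both the FISH (red) and DAPI (blue)
#' signal and appear pink in overlays; the cell mask is obtained by
#' thresholding the combined red + blue channel at a fraction of its
#' maximum (default 1% — the same rule as for tissue, as the threshold for
#' the combined channel is configurable).
#'
#' @param red FISH channel matrix.
#' @param blue DAPI channel matrix, co-registered with `red`.
#' @param threshold_frac threshold as a fraction of the combined maximum.
#' @return Logical cell mask.
#' @export
detect_cells <- function(red, blue, threshold_frac = 0.01) {
  stopifnot(is.matrix(red), is.matrix(blue), all(dim(red) == dim(blue)))
  combined <- red + blue
  mx <- max(combined)
  if (mx <= 0) {
    warning("all-zero combined channel: empty cell mask")
    return(matrix(FALSE, nrow(red), ncol(red)))
  }
  combined > threshold_frac * mx
}

#' Bundle tissue, cell and exclusion masks
#'
#' @param tissue_mask,cell_mask logical matrices of equal shape.
#' @param exclusion_mask optional logical matrix marking regions excluded
#'   from cell quantification (strongly autofluorescent layers such as the
#'   rhizoplane, epidermis, hypodermis and innermost stele).
#' @return List of class `mask_set`.
#' @export
mask_set <- function(tissue_mask, cell_mask, exclusion_mask = NULL) {
  stopifnot(is.logical(tissue_mask), is.logical(cell_mask),
            all(dim(tissue_mask) == dim(cell_mask)))
  if (!is.null(exclusion_mask)) {
    stopifnot(is.logical(exclusion_mask),
              all(dim(exclusion_mask) == dim(tissue_mask)))
    cell_mask <- apply_exclusion(cell_mask, exclusion_mask)
  }
  structure(list(tissue_mask = tissue_mask, cell_mask = cell_mask,
                 exclusion_mask = exclusion_mask),
            class = "mask_set")
}

#' Remove excluded regions from a cell mask
#'
#' @param cell_mask logical cell mask.
#' @param exclusion_mask logical mask of excluded regions (or `NULL`).
#' @return Cell mask with excluded pixels removed; the number of removed
#'   pixels is attached as attribute `removed_px`.
#' @export
apply_exclusion <- function(cell_mask, exclusion_mask) {
  if (is.null(exclusion_mask)) {
    attr(cell_mask, "removed_px") <- 0L
    return(cell_mask)
  }
  stopifnot(all(dim(cell_mask) == dim(exclusion_mask)))
  removed <- sum(cell_mask & exclusion_mask)
  out <- cell_mask & !exclusion_mask
  attr(out, "removed_px") <- removed
  out
}

#' Integrate a mask to an area
#'
#' All white (TRUE) pixels are integrated; with the default pixel edge of
#' 0.1 µm one pixel contributes 0.01 µm^2.
#'
#' @param mask logical matrix.
#' @param px_size pixel edge length in µm (default 0.1).
#' @return Area in µm^2.
#' @export
integrate_area <- function(mask, px_size = 0.1) {
  stopifnot(px_size > 0)
  sum(mask) * px_size^2
}

#' Stitch image tiles with cross-correlation refinement
#'
#' Tiles are placed at their nominal stage positions and each pair of
#' neighbours is refined by maximizing the cross-correlation of the overlap
#' over integer shifts within `max_shift` px (default 5). Pairs whose best
#' correlation stays below `min_cor` are flagged unresolved and keep the
#' nominal offset (to be corrected manually). Overlapping pixels in the
#' mosaic are blended by their mean.
#'
#' @param tiles list of matrices (one strip of neighbouring tiles, in order).
#' @param nominal `n x 2` matrix of 1-based nominal top-left (row, col)
#'   positions.
#' @param max_shift maximum allowed refinement shift per pair (px).
#' @param min_cor minimum acceptable overlap correlation (default 0.5).
#' @return List with `mosaic`, `positions` (refined), `shifts` (per-pair
#'   applied shift), and `flagged` (pairs left at nominal).
#' @export
stitch <- function(tiles, nominal, max_shift = 5, min_cor = 0.5) {
  n <- length(tiles)
  stopifnot(n >= 1, nrow(nominal) == n)
  nominal <- matrix(as.integer(nominal), ncol = 2)
  positions <- nominal
  shifts <- matrix(0L, n, 2)
  flagged <- logical(n)
  m <- as.integer(max_shift)
  if (n > 1) {
    for (i in 2:n) {
      rel_nom <- nominal[i, ] - nominal[i - 1, ]
      cand <- expand.grid(dy = -m:m, dx = -m:m)
      cand <- cand[order(abs(cand$dy) + abs(cand$dx)), ]
      best <- NULL; best_r <- -Inf
      any_overlap <- FALSE
      a <- tiles[[i - 1]]; b <- tiles[[i]]
      for (j in seq_len(nrow(cand))) {
        rel <- rel_nom + c(cand$dy[j], cand$dx[j])
        rr <- seq.int(max(1L, 1L + rel[1]), min(nrow(a), nrow(b) + rel[1]))
        cc <- seq.int(max(1L, 1L + rel[2]), min(ncol(a), ncol(b) + rel[2]))
        if (length(rr) < 1 || length(cc) < 1 ||
            rr[1] > rr[length(rr)] || cc[1] > cc[length(cc)]) next
        any_overlap <- TRUE
        av <- as.vector(a[rr, cc]); bv <- as.vector(b[rr - rel[1], cc - rel[2]])
        if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
        r <- stats::cor(av, bv)
        if (is.finite(r) && r > best_r + 1e-12) {
          best_r <- r
          best <- c(cand$dy[j], cand$dx[j])
        }
      }
      if (!any_overlap) stop("tiles do not overlap at the nominal offset")
      if (is.null(best) || best_r < min_cor) {
        flagged[i] <- TRUE
        best <- c(0L, 0L)
      }
      shifts[i, ] <- as.integer(best)
      positions[i, ] <- positions[i - 1, ] + rel_nom + shifts[i, ]
    }
  }
  # blend on a common canvas
  ext_r <- max(positions[, 1] + vapply(tiles, nrow, 1L) - 1L)
  ext_c <- max(positions[, 2] + vapply(tiles, ncol, 1L) - 1L)
  off_r <- 1L - min(positions[, 1]); off_c <- 1L - min(positions[, 2])
  acc <- matrix(0, ext_r + off_r, ext_c + off_c)
  cnt <- matrix(0, ext_r + off_r, ext_c + off_c)
  for (i in seq_len(n)) {
    rr <- seq.int(positions[i, 1] + off_r, length.out = nrow(tiles[[i]]))
    cc <- seq.int(positions[i, 2] + off_c, length.out = ncol(tiles[[i]]))
    acc[rr, cc] <- acc[rr, cc] + tiles[[i]]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  mosaic <- acc / pmax(cnt, 1)
  mosaic[cnt == 0] <- NA
  list(mosaic = mosaic, positions = positions, shifts = shifts,
       flagged = flagged)
}

#' Drift-correct and accumulate ion-count planes
#'
#' Per-plane drift is estimated by integer cross-correlation of a reference
#' species (default 12C14N-) against the first plane, with the same +/-
#' shift bound convention as [stitch()]; all species are shifted by the
#' estimated correction and summed. Pixels not covered by every plane are
#' marked invalid.
#'
#' @param stack an [ion_count_stack()].
#' @param max_shift drift search bound (px).
#' @param drift optional known `n_planes x 2` correction matrix (the shift
#'   to apply to each plane); when supplied, estimation is skipped.
#' @param ref_species species used for drift estimation.
#' @return List with `accumulated` (named list of count matrices), `valid`
#'   (logical matrix), and `drift` (applied per-plane corrections).
#' @export
accumulate_planes <- function(stack, max_shift = 5, drift = NULL,
                              ref_species = NULL) {
  stopifnot(inherits(stack, "ion_count_stack"))
  np <- stack$n_planes
  sp <- stack$species
  if (is.null(ref_species)) ref_species <- names(sp)[1]
  ref <- sp[[ref_species]][, , 1]
  if (is.null(drift)) {
    drift <- matrix(0L, np, 2)
    for (p in seq_len(np)[-1]) {
      drift[p, ] <- best_shift(ref, sp[[ref_species]][, , p], max_shift)$shift
    }
  } else {
    drift <- matrix(as.integer(drift), ncol = 2)
    stopifnot(nrow(drift) == np)
  }
  dims <- dim(sp[[1]])[1:2]
  cover <- matrix(0, dims[1], dims[2])
  acc <- lapply(sp, function(x) matrix(0, dims[1], dims[2]))
  ones <- matrix(1, dims[1], dims[2])
  for (p in seq_len(np)) {
    cover <- cover + shift_matrix(ones, drift[p, 1], drift[p, 2], fill = 0)
    for (s in names(sp)) {
      acc[[s]] <- acc[[s]] +
        shift_matrix(sp[[s]][, , p], drift[p, 1], drift[p, 2], fill = 0)
    }
  }
  list(accumulated = acc, valid = cover == np, drift = drift)
}

#' Convert accumulated ion counts to a 15N atom-percent image
#'
#' Per pixel, `r = 12C15N- / 12C14N-` and `at% = r/(r+1) * 100`. Pixels
#' whose accumulated 12C14N- count falls below the count-statistics floor
#' (default 100 counts; regions without plant material have low counting
#' statistics and unreliable ratios) are marked invalid rather than raising
#' an error.
#'
#' @param n15_counts,n14_counts accumulated count matrices.
#' @param min_counts validity floor on the 12C14N- counts (default 100).
#' @param valid optional additional validity mask (e.g. the plane-coverage
#'   mask from [accumulate_planes()]).
#' @return List of class `isotope_ratio_image` with `ratio`, `atpct` and
#'   `valid` matrices (invalid pixels are `NA`).
#' @export
ratio_to_atpct <- function(n15_counts, n14_counts, min_counts = 100,
                           valid = NULL) {
  stopifnot(all(dim(n15_counts) == dim(n14_counts)))
  ok <- n14_counts >= max(min_counts, 1)
  if (!is.null(valid)) ok <- ok & valid
  ratio <- matrix(NA_real_, nrow(n14_counts), ncol(n14_counts))
  ratio[ok] <- n15_counts[ok] / n14_counts[ok]
  structure(list(ratio = ratio, atpct = ratio_to_atpct_value(ratio),
                 valid = ok),
            class = "isotope_ratio_image")
}

#' Class-wise mean enrichment from masked isotope-ratio images
#'
#' The isotope-ratio matrix is multiplied pixel-wise with the cell and
#' tissue masks, the ratios within each class are averaged, and the class
#' mean is converted to at% once (averaging happens in ratio space; the
#' alternative of averaging per-pixel at% values differs at high
#' enrichment). Cell pixels are removed from the tissue class so the host
#' tissue statistic is not inflated by symbiont enrichment. Images with an
#' empty cell mask report tissue only.
#'
#' @param ri an `isotope_ratio_image` from [ratio_to_atpct()].
#' @param masks a [mask_set()] aligned to the image.
#' @return List of class `enrichment_summary` with `atpct_cells`,
#'   `atpct_tissue`, `n_cell_px`, `n_tissue_px` (valid pixels used).
#' @export
masked_mean_enrichment <- function(ri, masks) {
  stopifnot(inherits(ri, "isotope_ratio_image"), inherits(masks, "mask_set"))
  stopifnot(all(dim(masks$tissue_mask) == dim(ri$ratio)))
  cell_px <- masks$cell_mask & ri$valid
  tissue_px <- masks$tissue_mask & !masks$cell_mask & ri$valid
  if (!any(tissue_px)) warning("empty (or fully invalid) tissue mask")
  mean_at <- function(sel) {
    if (!any(sel)) return(NA_real_)
    ratio_to_atpct_value(mean(ri$ratio[sel]))
  }
  structure(list(
    atpct_cells = mean_at(cell_px),
    atpct_tissue = mean_at(tissue_px),
    n_cell_px = sum(cell_px),
    n_tissue_px = sum(tissue_px)
  ), class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("<enrichment_summary> cells %.4f at%% (n=%d px), tissue %.4f at%% (n=%d px)\n",
              x$atpct_cells, x$n_cell_px, x$atpct_tissue, x$n_tissue_px))
  invisible(x)
}

#' Relative 15N incorporation per day
#'
#' Normalizes a measured cell or tissue at% to the labelling ceiling of the
#' incubation and the incubation time:
#' `(at%_cell - at%_NA) / (at%_N2 - at%_NA) * 1/t * 100`, in percent per
#' day. Because FISH can dilute the isotopic signal, the result is a
#' minimum estimate; no correction factor is applied.
#'
#' @param atpct_cell measured at% 15N.
#' @param atpct_na natural-abundance background at% 15N.
#' @param atpct_n2 at% 15N of the dissolved N2 pool (> `atpct_na`).
#' @param t incubation time in days (> 0).
#' @return Relative incorporation in % per day.
#' @export
relative_incorporation <- function(atpct_cell, atpct_na, atpct_n2, t) {
  if (any(atpct_n2 <= atpct_na)) stop("at%_N2 must exceed at%_NA (no tracer)")
  if (any(t <= 0)) stop("incubation time must be positive")
  (atpct_cell - atpct_na) / (atpct_n2 - atpct_na) / t * 100
}

#' Area-weighted host-transfer mass balance
#'
#' Assuming the occupied area of each class is representative of its
#' biomass contribution, the fraction of fixed N residing in host tissue is
#' `area_tissue * excess_tissue / (area_tissue * excess_tissue +
#' area_cells * excess_cells) * 100`. Excess values are at% above natural
#' abundance and must be non-negative.
#'
#' @param area_tissue,area_cells class areas (same units, e.g. µm^2).
#' @param excess_tissue,excess_cells excess at% 15N of each class.
#' @return List of class `mass_balance_result` with `host_fraction` (%)
#'   and the echoed inputs.
#' @export
transfer_mass_balance <- function(area_tissue, excess_tissue,
                                  area_cells, excess_cells) {
  if (any(c(excess_tissue, excess_cells) < 0)) {
    stop("excess at% must be non-negative")
  }
  denom <- area_tissue * excess_tissue + area_cells * excess_cells
  if (denom <= 0) stop("total weighted excess is zero: fraction undefined")
  structure(list(
    host_fraction = area_tissue * excess_tissue / denom * 100,
    area_tissue = area_tissue, excess_tissue = excess_tissue,
    area_cells = area_cells, excess_cells = excess_cells
  ), class = "mass_balance_result")
}

#' @export
print.mass_balance_result <- function(x, ...) {
  cat(sprintf("<mass_balance> %.1f%% of fixed N in host tissue\n",
              x$host_fraction))
  invisible(x)
}

#' Gaussian-blurred cell overlay for visualization
#'
#' Renders the cell mask, blurred with a normalized Gaussian kernel of the
#' requested size (3-20 px; out-of-range values are clamped with a
#' warning), in red over the inverted tissue image (tissue black on white).
#' Purely presentational: quantification never uses this output.
#'
#' @param cell_mask logical cell mask.
#' @param tissue_mask logical tissue mask.
#' @param kernel_px Gaussian kernel size in px (3-20).
#' @return List with `rgb` (h x w x 3 array in `[0,1]`), `cell_layer` (the
#'   blurred, sum-preserving cell image) and `kernel_px` actually used.
#' @export
blur_overlay <- function(cell_mask, tissue_mask, kernel_px = 9) {
  stopifnot(all(dim(cell_mask) == dim(tissue_mask)))
  k <- kernel_px
  if (k < 3 || k > 20) {
    warning("kernel_px clamped to [3, 20]")
    k <- min(max(k, 3), 20)
  }
  k_odd <- as.integer(k) + (as.integer(k) %% 2L == 0L)
  brush <- EBImage::makeBrush(k_odd, shape = "Gaussian", sigma = k / 3)
  cell_layer <- EBImage::filter2(matrix(as.numeric(cell_mask),
                                        nrow(cell_mask), ncol(cell_mask)),
                                 brush)
  bg <- 1 - as.numeric(tissue_mask)
  red_scale <- if (max(cell_layer) > 0) cell_layer / max(cell_layer) else cell_layer
  rgb <- array(0, dim = c(nrow(cell_mask), ncol(cell_mask), 3))
  rgb[, , 1] <- pmin(1, bg + red_scale)
  rgb[, , 2] <- pmax(0, bg - red_scale)
  rgb[, , 3] <- pmax(0, bg - red_scale)
  list(rgb = rgb, cell_layer = cell_layer, kernel_px = k)
}
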