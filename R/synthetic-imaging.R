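#' Ground truth for a synthetic correlative FISH/nanoSIMS image set
#'
#' Defines the scene geometry and isotopic composition that
#' [gen_correlative_images()] renders: a circular root cross-section
#' (tissue), symbiont cells as small disks inside the cortex, an exclusion
#' ring standing in for the strongly autofluorescent outer tissue layers
#' (rhizoplane/epidermis/hypodermis), and the 15N atom percent of cells and
#' tissue. Cell placement keeps cells clear of the exclusion ring and of one
#' another, so `cell_mask` and `exclusion_mask` are disjoint. The minimum
#' centre separation leaves room for the 1%-threshold boundary growth of a
#' blurred cell (~2.4 px at sigma = 1), so blurred cells stay separate
#' connected components.
#'
#' @param size image edge in pixels (square images).
#' @param tissue_radius radius of the tissue disk (px).
#' @param n_cells number of symbiont cells.
#' @param cell_radius cell radius (px).
#' @param cell_atpct,tissue_atpct at% 15N of cells and of host tissue.
#' @param counts_per_px expected accumulated 12C14N- + 12C15N- counts per
#'   pixel on plant material (split evenly over planes).
#' @param n_planes number of ion-count planes per image (default 40).
#' @param exclusion_frac inner radius of the exclusion ring as a fraction of
#'   `tissue_radius`; cells are placed inside `0.85 * exclusion_frac`.
#' @param seed RNG seed.
#' @return List of class `image_truth` with the boolean `tissue_mask`,
#'   `cell_mask`, `exclusion_mask` matrices, cell centres, and the scalar
#'   parameters.
#' @export
image_truth <- function(size = 512, tissue_radius = 240, n_cells = 50,
                        cell_radius = 3, cell_atpct = 5, tissue_atpct = 1,
                        counts_per_px = 2000, n_planes = 40,
                        exclusion_frac = 0.92, seed = 1) {
  stopifnot(size > 8, tissue_radius < size / 2, n_cells >= 0, n_planes >= 1)
  if (any(c(cell_atpct, tissue_atpct) < 0 | c(cell_atpct, tissue_atpct) > 100)) {
    stop("atom percent values must lie in [0, 100]")
  }
  with_seed(seed, {
    cx <- (size + 1) / 2
    d <- sqrt(outer((seq_len(size) - cx)^2, (seq_len(size) - cx)^2, "+"))
    tissue_mask <- d <= tissue_radius
    exclusion_mask <- tissue_mask & d >= exclusion_frac * tissue_radius

    r_max <- 0.85 * exclusion_frac * tissue_radius
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_cells && tries < 20000L) {
      tries <- tries + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (r_max - cell_radius - 2)
      p <- c(cx + rad * cos(ang), cx + rad * sin(ang))
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - p)^2))) > 2 * cell_radius + 8) {
        centers <- rbind(centers, p)
      }
    }
    if (nrow(centers) < n_cells) stop("could not place all cells; reduce n_cells")
    cell_mask <- matrix(FALSE, size, size)
    for (i in seq_len(nrow(centers))) {
      dc <- sqrt(outer((seq_len(size) - centers[i, 1])^2,
                       (seq_len(size) - centers[i, 2])^2, "+"))
      cell_mask <- cell_mask | dc <= cell_radius
    }
    stopifnot(!any(cell_mask & exclusion_mask))
    structure(list(tissue_mask = tissue_mask, cell_mask = cell_mask,
                   exclusion_mask = exclusion_mask, centers = centers,
                   cell_atpct = cell_atpct, tissue_atpct = tissue_atpct,
                   counts_per_px = counts_per_px, n_planes = as.integer(n_planes),
                   seed = as.integer(seed)),
              class = "image_truth")
  })
}

#' Ion-count stack container
#'
#' Per-species stacks of raster ion-count planes recorded simultaneously by
#' the multicollector (e.g. 12C14N-, 12C15N-). Counts must be non-negative
#' and all species must share the same raster and plane count.
#'
#' @param species named list of 3-D arrays `[rows, cols, planes]`.
#' @param dwell dwell time, ms per pixel.
#' @param raster raster edge length, µm.
#' @return List of class `ion_count_stack`.
#' @export
ion_count_stack <- function(species, dwell = 1, raster = 20) {
  stopifnot(is.list(species), length(species) >= 1, !is.null(names(species)))
  dims <- lapply(species, dim)
  if (length(unique(lapply(dims, identity))) != 1L) {
    stop("all species must have identical [rows, cols, planes] dimensions")
  }
  if (any(vapply(species, function(a) any(a < 0), logical(1)))) {
    stop("ion counts must be non-negative")
  }
  structure(list(species = species, n_planes = dims[[1]][3],
                 dwell = dwell, raster = raster),
            class = "ion_count_stack")
}

#' Simulate a correlative fluorescence + nanoSIMS image set
#'
#' Renders the [image_truth()] scene as (i) a three-channel epifluorescence
#' image — DAPI (blue) and FISH (red) bright on symbiont cells,
#' autofluorescence (green) bright on root tissue, each convolved with a
#' Gaussian PSF and carrying additive sensor noise — and (ii) Poisson
#' ion-count planes for 12C14N- and 12C15N-. Per pixel and plane the total
#' N-bearing count is Poisson with mean `counts_per_px / n_planes` on plant
#' material (a small embedding-medium background elsewhere), and the 15N
#' share is binomial with probability `at%/100`, matching the counting
#' statistics of SIMS electron-multiplier detectors. Optional integer
#' per-plane drift emulates stage drift for registration tests.
#'
#' @param truth an [image_truth()].
#' @param psf_sigma fluorescence PSF sigma in px (default 1).
#' @param noise_sd fluorescence additive noise s.d. (default 2 on a
#'   max-1000 intensity scale).
#' @param signal peak fluorescence intensity (default 1000).
#' @param background_counts_per_px expected accumulated counts outside
#'   plant material (kept below any sensible count-statistics floor).
#' @param drift either `NULL` (no drift), `TRUE` (random walk, max 3 px) or
#'   an `n_planes x 2` integer matrix of (dy, dx) shifts per plane.
#' @param px_size µm per pixel edge (default 0.1).
#' @return List of class `correlative_image_set`: `fluor` (list with
#'   `dapi`, `autofluor`, `fish` matrices and `px_size`), `stack`
#'   (an [ion_count_stack()]), the applied `drift`, and the `truth`.
#' @export
gen_correlative_images <- function(truth, psf_sigma = 1, noise_sd = 2,
                                   signal = 1000,
                                   background_counts_per_px = 10,
                                   drift = NULL, px_size = 0.1) {
  stopifnot(inherits(truth, "image_truth"))
  with_seed(truth$seed + 1L, {
    sz <- nrow(truth$tissue_mask)
    np <- truth$n_planes

    render <- function(mask) {
      img <- matrix(0, sz, sz)
      img[mask] <- signal
      if (psf_sigma > 0) img <- gaussian_blur(img, psf_sigma)
      if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
      pmax(img, 0)
    }
    fluor <- list(dapi = render(truth$cell_mask),
                  autofluor = render(truth$tissue_mask),
                  fish = render(truth$cell_mask),
                  px_size = px_size)

    material <- truth$tissue_mask | truth$cell_mask
    at_map <- matrix(atpct_natural(), sz, sz)
    at_map[truth$tissue_mask] <- truth$tissue_atpct
    at_map[truth$cell_mask] <- truth$cell_atpct
    lam_map <- matrix(background_counts_per_px / np, sz, sz)
    lam_map[material] <- truth$counts_per_px / np

    if (isTRUE(drift)) {
      steps <- matrix(sample(-1:1, 2 * np, replace = TRUE), ncol = 2)
      steps[1, ] <- 0L
      drift <- apply(steps, 2, cumsum)
      drift <- pmax(pmin(drift, 3L), -3L)
    }
    if (!is.null(drift)) {
      drift <- matrix(as.integer(drift), ncol = 2)
      stopifnot(nrow(drift) == np)
    }

    n14 <- array(0, dim = c(sz, sz, np))
    n15 <- array(0, dim = c(sz, sz, np))
    for (p in seq_len(np)) {
      lam <- lam_map
      atp <- at_map
      if (!is.null(drift) && any(drift[p, ] != 0)) {
        lam <- shift_matrix(lam_map, drift[p, 1], drift[p, 2],
                            fill = background_counts_per_px / np)
        atp <- shift_matrix(at_map, drift[p, 1], drift[p, 2],
                            fill = atpct_natural())
      }
      tot <- stats::rpois(sz * sz, as.vector(lam))
      k15 <- stats::rbinom(sz * sz, tot, as.vector(atp) / 100)
      n15[, , p] <- k15
      n14[, , p] <- tot - k15
    }
    structure(list(
      fluor = fluor,
      stack = ion_count_stack(list(`12C14N` = n14, `12C15N` = n15)),
      drift = drift,
      truth = truth
    ), class = "correlative_image_set")
  })
}

#' Cut overlapping tiles with known offsets from an image
#'
#' Produces a horizontal strip of tiles that nominally overlap by
#' `overlap` px; integer jitter applied to each stage move (so each
#' tile-to-tile offset deviates from nominal by at most `jitter` px, the
#' way stage positioning error accrues per move) emulates imperfect stage
#' positions, and stitching must recover it. The true offsets are returned
#' as ground truth.
#'
#' @param img source matrix.
#' @param tile_size tile edge (px).
#' @param n_tiles number of tiles.
#' @param overlap nominal overlap between neighbours (px).
#' @param jitter maximum |jitter| (px) applied to each stage move, both
#'   axes; keep `jitter <= max_shift` of [stitch()] for exact recovery.
#' @param seed RNG seed.
#' @return List with `tiles` (list of matrices), `nominal` and `true`
#'   (n_tiles x 2 matrices of top-left positions, 1-based (row, col)).
#' @export
gen_image_tiles <- function(img, tile_size = 128, n_tiles = 2, overlap = 5,
                            jitter = 3, seed = 1) {
  stopifnot(overlap >= 1, tile_size > 2 * overlap)
  with_seed(seed, {
    base <- 1L + as.integer(jitter) * n_tiles    # keep jittered cuts in-bounds
    nominal <- cbind(rep(base, n_tiles),
                     base + (seq_len(n_tiles) - 1L) * (tile_size - overlap))
    moves <- matrix(sample(seq(-jitter, jitter), 2 * n_tiles, replace = TRUE),
                    ncol = 2)
    moves[1, ] <- 0L
    true_pos <- nominal + apply(moves, 2, cumsum)
    stopifnot(all(true_pos >= 1))
    need_r <- max(true_pos[, 1]) + tile_size
    need_c <- max(true_pos[, 2]) + tile_size
    if (nrow(img) < need_r || ncol(img) < need_c) {
      stop("source image too small for the requested tiling")
    }
    tiles <- lapply(seq_len(n_tiles), function(i) {
      img[seq.int(true_pos[i, 1], true_pos[i, 1] + tile_size - 1L),
          seq.int(true_pos[i, 2], true_pos[i, 2] + tile_size - 1L)]
    })
    list(tiles = tiles, nominal = nominal, true = true_pos)
  })
}
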