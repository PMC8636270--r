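test_that("tissue binarization applies the 1%-of-maximum rule", {
  img <- matrix(0, 10, 10)
  img[1, 1] <- 1000; img[2, 1] <- 11; img[3, 1] <- 9
  m <- binarize_tissue(img)
  expect_true(m[2, 1])     # 11 > 10
  expect_false(m[3, 1])    # 9 < 10
  expect_true(all(binarize_tissue(matrix(7, 4, 4))))
  expect_warning(m0 <- binarize_tissue(matrix(0, 4, 4)), "all-zero")
  expect_false(any(m0))
})

test_that("cell detection uses the combined red+blue channel only", {
  it <- image_truth(size = 64, tissue_radius = 28, n_cells = 3,
                    n_planes = 2, seed = 14)
  cis <- gen_correlative_images(it, psf_sigma = 0, noise_sd = 0)
  cells <- detect_cells(cis$fluor$fish, cis$fluor$dapi)
  # noiseless, unblurred input: perfect recall of the true mask
  expect_identical(cells, it$cell_mask)
  # green-only structures (tissue) never enter the cell mask
  expect_false(any(cells & it$tissue_mask & !it$cell_mask))
})

test_that("exclusion masking removes only the overlapping pixels", {
  cell <- matrix(FALSE, 8, 8); cell[3:6, 3:6] <- TRUE
  excl <- matrix(FALSE, 8, 8); excl[3:6, 3:4] <- TRUE
  out <- apply_exclusion(cell, excl)
  expect_equal(attr(out, "removed_px"), 8)
  expect_equal(sum(out), 8)
  expect_false(any(out & excl))
  # empty exclusion set: identity
  expect_equal(sum(apply_exclusion(cell, matrix(FALSE, 8, 8))), sum(cell))
  # a cell fully inside the exclusion region disappears
  expect_equal(sum(apply_exclusion(excl, excl)), 0)
  # exclusion never increases the area
  expect_lte(sum(out), sum(cell))
})

test_that("mask areas integrate with the pixel size", {
  m <- matrix(FALSE, 50, 50); m[seq_len(250)] <- TRUE
  expect_equal(integrate_area(m, 0.1), 2.5)
  expect_equal(integrate_area(matrix(FALSE, 5, 5)), 0)
  a <- matrix(FALSE, 10, 10); a[1:3, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[8:10, ] <- TRUE
  expect_equal(integrate_area(a | b), integrate_area(a) + integrate_area(b))
})

test_that("stitching recovers injected offsets within the 5 px bound", {
  img <- textured_matrix(160, 400)
  tl <- gen_image_tiles(img, tile_size = 128, n_tiles = 3, overlap = 6,
                        jitter = 3, seed = 41)
  st <- stitch(tl$tiles, tl$nominal)
  expect_equal(st$positions, tl$true)
  expect_false(any(st$flagged))
  # already aligned tiles refine to a zero shift
  tl0 <- gen_image_tiles(img, tile_size = 128, n_tiles = 2, overlap = 6,
                         jitter = 0, seed = 42)
  st0 <- stitch(tl0$tiles, tl0$nominal)
  expect_equal(st0$shifts[2, ], c(0L, 0L))
})

test_that("offsets beyond the bound are flagged and the nominal kept", {
  img <- textured_matrix(128, 300)
  a <- img[1:100, 1:100]
  b <- img[1:100, 103:202]          # true offset 102, nominal assumes 95
  nominal <- rbind(c(1L, 1L), c(1L, 96L))
  st <- stitch(list(a, b), nominal, max_shift = 5)
  expect_true(st$flagged[2])
  expect_equal(st$positions[2, ], nominal[2, ])
  # no overlap at the nominal offset at all: hard error
  expect_error(stitch(list(a, b), rbind(c(1L, 1L), c(1L, 400L))), "overlap")
})

test_that("the mosaic blends overlap by the mean and conserves content", {
  a <- matrix(1, 10, 10); b <- matrix(3, 10, 10)
  st <- stitch(list(a, b), rbind(c(1L, 1L), c(1L, 9L)), min_cor = 1.1)
  # forced nominal placement (flagged): overlap columns average to 2
  expect_equal(unique(as.vector(st$mosaic[, 9:10])), 2)
  expect_equal(unique(as.vector(st$mosaic[, 1:8])), 1)
  expect_equal(unique(as.vector(st$mosaic[, 11:18])), 3)
})

test_that("plane accumulation sums counts and respects known drift", {
  arr <- array(2, dim = c(16, 16, 40))
  st <- ion_count_stack(list(`12C14N` = arr, `12C15N` = arr))
  acc <- accumulate_planes(st)
  expect_equal(unique(as.vector(acc$accumulated$`12C14N`)), 80)
  expect_true(all(acc$valid))
  # constant image with injected drift corrections: identical on the valid region
  drift <- cbind(c(0, 1, -1, rep(0, 37)), c(0, -2, 2, rep(0, 37)))
  acc2 <- accumulate_planes(st, drift = drift)
  expect_equal(unique(as.vector(acc2$accumulated$`12C14N`[acc2$valid])), 80)
  expect_false(all(acc2$valid))
  # one plane: identity
  one <- ion_count_stack(list(`12C14N` = array(5, dim = c(4, 4, 1))))
  expect_equal(accumulate_planes(one)$accumulated$`12C14N`, matrix(5, 4, 4))
  expect_error(ion_count_stack(list(a = array(0, c(4, 4, 2)),
                                    b = array(0, c(4, 4, 3)))), "identical")
})

test_that("estimated drift corrections undo injected stage drift", {
  it <- image_truth(size = 96, tissue_radius = 40, n_cells = 5,
                    n_planes = 8, seed = 16)
  cis <- gen_correlative_images(it, drift = TRUE)
  acc <- accumulate_planes(cis$stack)
  expect_equal(acc$drift, -cis$drift, ignore_attr = TRUE)
})

test_that("count ratios convert to atom percent with a validity floor", {
  n14 <- matrix(c(1000, 1000, 1000, 50, 0, 1000), 2, 3)
  n15 <- matrix(c(1000, 10, 0, 10, 5, 500), 2, 3)
  ri <- ratio_to_atpct(n15, n14, min_counts = 100)
  expect_equal(ri$atpct[1, 1], 50)                        # r = 1
  expect_equal(ri$atpct[2, 1], 0.01 / 1.01 * 100, tolerance = 1e-9)
  expect_equal(ri$atpct[1, 2], 0)                         # r = 0
  expect_true(is.na(ri$atpct[2, 2]))                      # low counts
  expect_true(is.na(ri$atpct[1, 3]))                      # zero 14N: no error
  expect_false(ri$valid[1, 3])
})

test_that("masked means average in ratio space before conversion", {
  n14 <- matrix(1000, 2, 2)
  # two cell pixels at 1.0 and 2.0 at%
  r1 <- at_to_ratio(1.0); r2 <- at_to_ratio(2.0)
  n15 <- matrix(c(r1, r2, 0.001, 0.001) * 1000, 2, 2)
  ri <- ratio_to_atpct(n15, n14)
  cells <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  masks <- mask_set(matrix(TRUE, 2, 2), cells)
  s <- masked_mean_enrichment(ri, masks)
  oracle <- mean(c(r1, r2)); oracle <- oracle / (1 + oracle) * 100
  expect_equal(s$atpct_cells, oracle, tolerance = 1e-12)
  expect_equal(round(s$atpct_cells, 2), 1.5)
  # uniform image: mean equals the pixel value
  ri_u <- ratio_to_atpct(matrix(100, 2, 2), n14)
  expect_equal(masked_mean_enrichment(ri_u, masks)$atpct_tissue,
               ratio_to_atpct_value(0.1))
  # empty tissue mask warns
  masks0 <- mask_set(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2))
  expect_warning(masked_mean_enrichment(ri, masks0), "tissue")
})

test_that("relative incorporation normalizes to the labelling ceiling", {
  expect_equal(relative_incorporation(5.4, 0.367194, 5.4, 1), 100)
  expect_equal(relative_incorporation(0.367194, 0.367194, 5.4, 2), 0)
  # midpoint enrichment over two days: 25% per day
  mid <- (0.367194 + 5.4) / 2
  expect_equal(relative_incorporation(mid, 0.367194, 5.4, 2), 25)
  expect_error(relative_incorporation(1, 0.5, 0.4, 1), "exceed")
  expect_error(relative_incorporation(1, 0.3, 5.4, 0), "positive")
})

test_that("the mass balance weights excess by area", {
  expect_equal(transfer_mass_balance(100, 0.5, 10, 5)$host_fraction, 50)
  expect_equal(transfer_mass_balance(7, 3, 7, 3)$host_fraction, 50)
  expect_equal(transfer_mass_balance(10, 2, 10, 0)$host_fraction, 100)
  # invariant under joint rescaling of areas or excesses
  base <- transfer_mass_balance(120, 0.8, 30, 4)$host_fraction
  expect_equal(transfer_mass_balance(1200, 0.8, 300, 4)$host_fraction, base)
  expect_equal(transfer_mass_balance(120, 8, 30, 40)$host_fraction, base)
  expect_error(transfer_mass_balance(10, 0, 10, 0), "zero")
  expect_error(transfer_mass_balance(10, -1, 10, 1), "non-negative")
})

test_that("the blur overlay is sum-preserving and purely visual", {
  cell <- matrix(FALSE, 41, 41); cell[21, 21] <- TRUE
  tissue <- matrix(TRUE, 41, 41)
  b3 <- blur_overlay(cell, tissue, kernel_px = 3)
  expect_equal(sum(b3$cell_layer), 1, tolerance = 1e-6)
  # larger kernels spread further: the maximum decreases monotonically
  maxima <- sapply(c(3, 7, 11, 19), function(k)
    max(blur_overlay(cell, tissue, k)$cell_layer))
  expect_true(all(diff(maxima) < 0))
  # empty mask leaves the background untouched
  b0 <- blur_overlay(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8), 5)
  expect_equal(b0$rgb[, , 1], matrix(1, 8, 8))
  expect_warning(bc <- blur_overlay(cell, tissue, 25), "clamp")
  expect_equal(bc$kernel_px, 20)
})

test_that("small-scale end-to-end recovery stays within Poisson error", {
  it <- image_truth(size = 128, tissue_radius = 55, n_cells = 8,
                    cell_atpct = 5, tissue_atpct = 1,
                    counts_per_px = 2000, n_planes = 10, seed = 18)
  cis <- gen_correlative_images(it)
  acc <- accumulate_planes(cis$stack, drift = matrix(0L, 10, 2))
  ri <- ratio_to_atpct(acc$accumulated$`12C15N`, acc$accumulated$`12C14N`,
                       valid = acc$valid)
  masks <- mask_set(it$tissue_mask, it$cell_mask, it$exclusion_mask)
  s <- masked_mean_enrichment(ri, masks)
  expect_lt(abs(s$atpct_cells - 5),
            3 * se_atpct_ratio_mean(0.05, 2000, s$n_cell_px))
  expect_lt(abs(s$atpct_tissue - 1),
            3 * se_atpct_ratio_mean(0.01, 2000, s$n_tissue_px))
})
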