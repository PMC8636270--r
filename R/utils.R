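# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shift a matrix by integer (dy, dx) = (rows, cols); vacated pixels get `fill`.
shift_matrix <- function(m, dy, dx, fill = NA_real_) {
  dy <- as.integer(dy); dx <- as.integer(dx)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Best integer shift (dy, dx) of `img` against `ref` maximizing the
# normalized cross-correlation of the overlap, searched over
# |dy|,|dx| <= max_shift. Ties break toward the smallest |shift|.
best_shift <- function(ref, img, max_shift = 5L) {
  stopifnot(all(dim(ref) == dim(img)))
  m <- as.integer(max_shift)
  cand <- expand.grid(dy = -m:m, dx = -m:m)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), abs(cand$dy)), ]
  best <- c(0L, 0L); best_r <- -Inf
  nr <- nrow(ref); nc <- ncol(ref)
  for (i in seq_len(nrow(cand))) {
    dy <- cand$dy[i]; dx <- cand$dx[i]
    r_ref <- seq.int(max(1L, 1L + dy), min(nr, nr + dy))
    c_ref <- seq.int(max(1L, 1L + dx), min(nc, nc + dx))
    a <- ref[r_ref, c_ref]
    b <- img[r_ref - dy, c_ref - dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(as.vector(a), as.vector(b))
    if (is.finite(r) && r > best_r + 1e-12) {
      best_r <- r
      best <- c(dy, dx)
    }
  }
  list(shift = best, cor = best_r)
}

# Gaussian blur of a matrix, sum-preserving (circular FFT convolution).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
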