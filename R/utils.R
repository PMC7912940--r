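## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(code)
}

## Deterministic seed mixing; result always a valid 32-bit seed.
mix_seed <- function(a, b) {
  as.integer((as.numeric(a) * 69069 + as.numeric(b) * 3061 + 1) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Truncation (not rounding) to `digits` decimals, as used by the printed
## summary statistics this package reproduces.
truncate_decimals <- function(x, digits = 3) {
  floor(x * 10^digits + 1e-9) / 10^digits
}

## Gaussian smoothing of a matrix (EBImage's separable/FFT filter).
gaussian_smooth <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

## Bilinear sampling of `img` at fractional (row, col) positions with
## clamp-to-edge boundary handling, so every output is a convex combination
## of input pixels. Exact at integer coordinates.
bilinear_sample <- function(img, ri, ci) {
  H <- nrow(img); W <- ncol(img)
  ri <- clamp(ri, 1, H); ci <- clamp(ci, 1, W)
  r0 <- floor(ri); c0 <- floor(ci)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- ri - r0; fc <- ci - c0
  v00 <- img[cbind(r0, c0)]; v10 <- img[cbind(r1, c0)]
  v01 <- img[cbind(r0, c1)]; v11 <- img[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

## Nearest-neighbour sampling with clamp-to-edge (used for masks).
nearest_sample <- function(img, ri, ci) {
  H <- nrow(img); W <- ncol(img)
  r0 <- clamp(round(ri), 1, H)
  c0 <- clamp(round(ci), 1, W)
  img[cbind(r0, c0)]
}

#' Boundary of a binary mask
#'
#' Inner boundary: foreground pixels with at least one background
#' 4-neighbour (pixels beyond the image edge count as background). Returned
#' as an n x 2 matrix of 1-based (row, col) coordinates, ordered
#' counter-clockwise by angle about the foreground centroid.
#'
#' @param mask binary matrix (0/1 or logical).
#' @return integer matrix with columns `row`, `col`.
#' @export
mask_boundary <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  shift_bg <- function(dr, dc) {
    out <- matrix(TRUE, H, W)  # out-of-frame treated as background
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- !m[rs[ok_r], cs[ok_c]]
    out
  }
  bnd <- m & (shift_bg(-1, 0) | shift_bg(1, 0) | shift_bg(0, -1) | shift_bg(0, 1))
  idx <- which(bnd, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  ctr <- colMeans(which(m, arr.ind = TRUE))
  ang <- atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
  idx <- idx[order(ang, idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("row", "col")
  rownames(idx) <- NULL
  idx
}

## Extract zero-padded square windows centred at `centers` (n x 2, 1-based
## row/col). Returns a (win*win) x n matrix, each column one window in
## column-major order.
extract_windows <- function(image, centers, window_size) {
  r <- (window_size - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  pad <- matrix(0, H + 2L * r, W + 2L * r)
  pad[(r + 1L):(r + H), (r + 1L):(r + W)] <- image
  n <- nrow(centers)
  out <- matrix(0, window_size * window_size, n)
  for (s in seq_len(n)) {
    ri <- centers[s, 1L]; ci <- centers[s, 2L]
    out[, s] <- pad[ri:(ri + 2L * r), ci:(ci + 2L * r)]
  }
  out
}

stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "triseg_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
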