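# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# ITU-R BT.601 luminance; grayscale matrices pass through.
asGray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] >= 3L)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

frameWidth <- function(frame) dim(frame)[2]
frameHeight <- function(frame) dim(frame)[1]

# Summed-area table with a zero first row/column, so that
# sum over pixels x..x+w-1, y..y+h-1 (0-based) is
# ii[y+h+1, x+w+1] - ii[y+1, x+w+1] - ii[y+h+1, x+1] + ii[y+1, x+1].
integralImage <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(0, h + 1L, w + 1L)
  cs <- apply(m, 2, cumsum)
  if (h == 1L) cs <- matrix(cs, nrow = 1L)
  ii[-1L, -1L] <- t(apply(cs, 1, cumsum))
  ii
}

# Rectangle sums over an integral image; x, y, w, h vectors (0-based).
boxSums <- function(ii, x, y, w, h) {
  ii[cbind(y + h + 1L, x + w + 1L)] - ii[cbind(y + 1L, x + w + 1L)] -
    ii[cbind(y + h + 1L, x + 1L)] + ii[cbind(y + 1L, x + 1L)]
}

# Bilinear sampling of a grayscale matrix at 0-based coordinates (vectors).
# Coordinates are clamped to the image domain.
bilinearSample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- m[cbind(y0 + 1, x0 + 1)]
  i01 <- m[cbind(y0 + 1, x1 + 1)]
  i10 <- m[cbind(y1 + 1, x0 + 1)]
  i11 <- m[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Bilinear resampling of a matrix (or each channel of an h x w x 3 array)
# to outH x outW, aligning pixel centers at the image corners.
resampleBilinear <- function(img, outH, outW) {
  f <- function(m) {
    h <- nrow(m); w <- ncol(m)
    xs <- if (outW == 1L) (w - 1) / 2 else seq(0, w - 1, length.out = outW)
    ys <- if (outH == 1L) (h - 1) / 2 else seq(0, h - 1, length.out = outH)
    g <- expand.grid(y = ys, x = xs)
    matrix(bilinearSample(m, g$x, g$y), nrow = outH, ncol = outW)
  }
  if (is.matrix(img)) return(f(img))
  out <- array(0, c(outH, outW, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
  out
}

# 2x image pyramid by 2x2 block averaging (odd trailing row/col dropped).
downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
     m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
     m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
     m[seq(2, h, 2), seq(2, w, 2), drop = FALSE]) / 4
}

buildPyramid <- function(m, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- m
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr[[l]])) < 16L) { pyr <- pyr[seq_len(l)]; break }
    pyr[[l + 1L]] <- downsample2(pyr[[l]])
  }
  pyr[!vapply(pyr, is.null, logical(1))]
}

# Binary dilation with a 3x3 structuring element.
dilate3x3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  out <- matrix(FALSE, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    out <- out | padded[dy + seq_len(h), dx + seq_len(w)]
  }
  out
}
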