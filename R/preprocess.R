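#' Extract denoised edge points from a frame
#'
#' Converts the frame to grayscale, detects edges with a
#' gradient-magnitude operator with hysteresis linking, and removes small
#' connected components of edge pixels (speckle). Already-binarised edge
#' maps (matrices whose values are only 0 and 1) skip the gradient step and
#' are denoised directly, so synthetic edge images pass through faithfully.
#'
#' The component-size filter operates on a one-pixel dilation of the edge
#' mask, so dotted contours whose gaps are at most two pixels count as one
#' component while isolated noise pixels are removed.
#'
#' @param frame grayscale matrix or RGB array, values in [0, 1].
#' @param highThreshold strong-edge threshold on gradient magnitude;
#'   defaults to 0.25 of the maximum magnitude.
#' @param lowThreshold weak-edge threshold for hysteresis linking;
#'   defaults to 0.4 * highThreshold.
#' @param minComponentSize connected components (of the dilated mask)
#'   smaller than this many pixels are discarded.
#' @return an n x 2 matrix of edge-pixel coordinates (x, y), 0-based.
#' @export
preprocessFrame <- function(frame, highThreshold = NULL, lowThreshold = NULL,
                            minComponentSize = 20L) {
  if (length(frame) == 0L) stop("empty frame")
  gray <- asGray(frame)
  vals <- unique(as.vector(gray))
  if (length(vals) == 1L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  if (length(vals) <= 2L && all(vals %in% c(0, 1))) {
    mask <- gray > 0
  } else {
    g <- smooth3x3(gray)
    h <- nrow(g); w <- ncol(g)
    gx <- matrix(0, h, w); gy <- matrix(0, h, w)
    gx[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
    gy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
    mag <- sqrt(gx^2 + gy^2)
    if (is.null(highThreshold)) highThreshold <- 0.25 * max(mag)
    if (is.null(lowThreshold)) lowThreshold <- 0.4 * highThreshold
    if (highThreshold <= 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
    weak <- mag >= lowThreshold
    strong <- mag >= highThreshold
    lab <- EBImage::bwlabel(weak)
    keep <- unique(lab[strong])
    keep <- keep[keep > 0]
    mask <- matrix(lab %in% keep, nrow(lab), ncol(lab)) & weak
  }
  mask <- denoiseMask(mask, minComponentSize)
  idx <- which(mask, arr.ind = TRUE)
  out <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

smooth3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  # replicate borders
  p[1, ] <- p[2, ]; p[h + 2L, ] <- p[h + 1L, ]
  p[, 1] <- p[, 2]; p[, w + 2L] <- p[, w + 1L]
  k <- c(1, 2, 1) / 4
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    out <- out + k[dy + 1] * k[dx + 1] * p[dy + seq_len(h), dx + seq_len(w)]
  }
  out
}

# Remove small connected components; size is measured on the dilated mask
# so dotted chains survive while isolated speckle does not.
denoiseMask <- function(mask, minComponentSize) {
  if (!any(mask)) return(mask)
  dil <- dilate3x3(mask)
  lab <- EBImage::bwlabel(dil)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minComponentSize)
  matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
}
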