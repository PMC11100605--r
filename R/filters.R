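# Small separable image filters used by the simulator and the spot detector.

pad_reflect <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(pmin(h:1, nr), 1:nr, pmax(nr - seq_len(h) + 1L, 1L))
  ci <- c(pmin(h:1, nc), 1:nc, pmax(nc - seq_len(h) + 1L, 1L))
  m[ri, ci, drop = FALSE]
}

#' Gaussian blur of a 2D image
#'
#' Separable convolution with a truncated (4 sigma) normalized Gaussian
#' kernel; image borders are mirror-reflected.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  p <- pad_reflect(img, h)
  p <- stats::filter(p, k, sides = 2)            # down columns
  p <- t(stats::filter(t(p), k, sides = 2))      # along rows
  out <- p[(h + 1L):(h + nrow(img)), (h + 1L):(h + ncol(img)), drop = FALSE]
  matrix(as.numeric(out), nrow(img), ncol(img))
}

# 5-point discrete Laplacian with replicated borders
laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * m
}
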