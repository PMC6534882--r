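# Internal numerical helpers shared across modules.

#' @importFrom stats optim runif rnorm quantile sd
#' @importFrom utils head tail
NULL

.EPS <- 1e-12

#' Bilinear sampling of a matrix at continuous (row, col) locations.
#'
#' Locations outside the matrix sample the fill value. Vectorized over
#' `rows`/`cols` (1-based continuous coordinates of pixel centers).
#' @noRd
bilinear_sample <- function(m, rows, cols, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(fill, length(rows))
  inside <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  if (!any(inside)) return(out)
  r <- rows[inside]; c <- cols[inside]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * m[i00] +
       fr       * (1 - fc) * m[i00 + 1] +
       (1 - fr) * fc       * m[i00 + nr] +
       fr       * fc       * m[i00 + nr + 1]
  out[inside] <- v
  out
}

#' Nearest-neighbour sampling with fill outside the grid.
#' @noRd
nearest_sample <- function(m, rows, cols, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- round(rows); ci <- round(cols)
  out <- rep(fill, length(rows))
  inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out[inside] <- m[(ci[inside] - 1) * nr + ri[inside]]
  out
}

#' Clipped moving-window (box) sums via an integral image.
#'
#' Returns, for every pixel, the sum of `m` over the (2h+1)^2 window centred
#' there, with the window clipped at the borders. Used by the local
#' weighted-voting patch statistics.
#' @noRd
box_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r <- seq_len(nr); c <- seq_len(nc)
  r1 <- pmax(r - h, 1L); r2 <- pmin(r + h, nr)
  c1 <- pmax(c - h, 1L); c2 <- pmin(c + h, nc)
  # outer combination of row/col window bounds
  P[r2 + 1L, c2 + 1L, drop = FALSE] - P[r1, c2 + 1L, drop = FALSE] -
    P[r2 + 1L, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
}

#' Per-pixel count of the clipped box window (denominator for box stats).
#' @noRd
box_count <- function(nr, nc, h) {
  rcount <- pmin(seq_len(nr) + h, nr) - pmax(seq_len(nr) - h, 1L) + 1L
  ccount <- pmin(seq_len(nc) + h, nc) - pmax(seq_len(nc) - h, 1L) + 1L
  outer(rcount, ccount)
}

#' Gaussian smoothing with replicated borders.
#'
#' Separable truncated-Gaussian convolution; radius 3*sigma (at least 1).
#' @noRd
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  x <- seq(-rad, rad)
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], rad), v, rep(v[n], rad))
    as.numeric(stats::filter(vp, k, sides = 2L))[(rad + 1L):(rad + n)]
  }
  m2 <- apply(m, 2L, pad_conv)
  t(apply(m2, 1L, pad_conv))
}

#' Central-difference spatial gradient; replicate boundary handling.
#' Returns list(dr, dc) — derivative along rows and along columns.
#' @noRd
central_gradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  list(dr = (dn - up) / 2, dc = (rt - lf) / 2)
}

#' Roberts cross gradient magnitude.
#'
#' Gx = I(r,c) - I(r+1,c+1), Gy = I(r+1,c) - I(r,c+1); magnitude
#' sqrt(Gx^2 + Gy^2). The last row/column, where the 2x2 stencil leaves the
#' image, replicates the neighbouring magnitude.
#' @noRd
roberts_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- m[-nr, -nc] - m[-1L, -1L]
  gy <- m[-1L, -nc] - m[-nr, -1L]
  g <- matrix(0, nr, nc)
  g[-nr, -nc] <- sqrt(gx^2 + gy^2)
  g[nr, ] <- g[nr - 1L, ]
  g[, nc] <- g[, nc - 1L]
  g
}

#' Min-max rescale a vector to [0, 1]; constant input maps to `flat`.
#' @noRd
minmax01 <- function(x, flat = 0) {
  rng <- range(x)
  if (rng[2] - rng[1] < .EPS) return(rep(flat, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Clamp values into [lo, hi].
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
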