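#' Derive a reproducible sub-seed from a master seed
#'
#' Named, counter-based seed splitting: every stochastic stage draws its own
#' seed from the master seed, a stream name and an index, so cohorts and
#' training runs are reproducible independent of the order in which stages
#' execute. The derivation is a 31-bit polynomial hash, identical on every
#' platform.
#'
#' @param master integer master seed.
#' @param stream character stream name (e.g. \code{"phantom-case"}).
#' @param index integer counter within the stream.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(master, stream, index = 0L) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(paste0(stream, ":", index))) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Map CT intensities from an HU window to the unit interval
#'
#' Linear, invertible map from the Hounsfield window \code{[lo, hi]}
#' (default \eqn{[-1000, 400]}, covering aerated lung through soft tissue)
#' to \eqn{[-1, 1]}, clamped at the window edges. Shared by the GAN and the
#' classifier so generated and real images live on the same scale.
#'
#' @param x numeric intensities in HU.
#' @param window length-2 numeric window in HU.
#' @return values in \eqn{[-1, 1]} with the shape of \code{x}.
#' @export
huWindowToUnit <- function(x, window = c(-1000, 400)) {
  y <- (x - window[1]) / (window[2] - window[1]) * 2 - 1
  y <- pmin(pmax(y, -1), 1)
  dim(y) <- dim(x)
  y
}

#' @rdname huWindowToUnit
#' @param y numeric values in \eqn{[-1, 1]}.
#' @export
unitToHuWindow <- function(y, window = c(-1000, 400)) {
  x <- (y + 1) / 2 * (window[2] - window[1]) + window[1]
  dim(x) <- dim(y)
  x
}

# Bilinear resize with corner-aligned sampling so that resizing to the same
# size is the identity.
bilinearResize <- function(m, oh, ow = oh) {
  H <- nrow(m); W <- ncol(m)
  src <- function(n, out) {
    if (out == 1L) rep((n + 1) / 2, 1) else (seq_len(out) - 1) * (n - 1) / (out - 1) + 1
  }
  ri <- src(H, oh); ci <- src(W, ow)
  i0 <- pmin(floor(ri), H - 1L); fi <- ri - i0
  j0 <- pmin(floor(ci), W - 1L); fj <- ci - j0
  if (H == 1L) { i0 <- rep(1L, oh); fi <- rep(0, oh) }
  if (W == 1L) { j0 <- rep(1L, ow); fj <- rep(0, ow) }
  a <- m[i0, j0, drop = FALSE]; b <- m[pmin(i0 + 1, H), j0, drop = FALSE]
  c2 <- m[i0, pmin(j0 + 1, W), drop = FALSE]; d2 <- m[pmin(i0 + 1, H), pmin(j0 + 1, W), drop = FALSE]
  fi <- matrix(fi, oh, ow); fj <- matrix(fj, oh, ow, byrow = TRUE)
  a * (1 - fi) * (1 - fj) + b * fi * (1 - fj) + c2 * (1 - fi) * fj + d2 * fi * fj
}

centerCrop <- function(m, size) {
  H <- nrow(m); W <- ncol(m)
  if (H < size || W < size) stop("image smaller than crop size")
  i0 <- (H - size) %/% 2L
  j0 <- (W - size) %/% 2L
  m[i0 + seq_len(size), j0 + seq_len(size), drop = FALSE]
}

# Trilinear interpolation of a 3-d array at continuous (1-based) voxel
# coordinates. Corners that fall outside the grid contribute `pad`.
trilinearSampleIndex <- function(arr, pts, pad = -1024) {
  d <- dim(arr)
  n <- nrow(pts)
  i0 <- floor(pts[, 1]); j0 <- floor(pts[, 2]); k0 <- floor(pts[, 3])
  fi <- pts[, 1] - i0; fj <- pts[, 2] - j0; fk <- pts[, 3] - k0
  out <- numeric(n)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) * (if (dk) fk else 1 - fk)
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    v <- rep(pad, n)
    if (any(ok)) v[ok] <- arr[(kk[ok] - 1) * d[1] * d[2] + (jj[ok] - 1) * d[1] + ii[ok]]
    out <- out + w * v
  }
  out
}

# Sample a volume at physical mm positions (rows of `ptsMM`).
trilinearSampleMM <- function(arr, spacing, origin, ptsMM, pad = -1024) {
  pts <- sweep(ptsMM, 2, origin, "-")
  pts <- sweep(pts, 2, spacing, "/") + 1
  trilinearSampleIndex(arr, pts, pad)
}

stopIfNot3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop(what, " must be a finite numeric vector of length 3")
}
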