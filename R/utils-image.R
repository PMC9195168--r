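# Low-level image utilities shared by the phantom, registration and
# relaxometry code. Images are plain numeric matrices indexed (row, col),
# 1-based; fractional coordinates are sampled bilinearly with NA outside
# the support.

#' Sample an image at fractional coordinates
#'
#' Bilinear interpolation at (row, col) positions. Coordinates outside the
#' image support return `NA` (no clamping), which callers use to restrict
#' objectives to the overlap region.
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of equal length, 1-based fractional coordinates.
#' @return numeric vector of sampled values, `NA` outside the image.
#' @keywords internal
bilinearSample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # points exactly on the last row/col are still inside
  edge <- (r0 == nr & fr == 0 & c0 >= 1 & c0 + 1 <= nc) |
    (c0 == nc & fc == 0 & r0 >= 1 & r0 + 1 <= nr) |
    (r0 == nr & fr == 0 & c0 == nc & fc == 0)
  out <- rep(NA_real_, length(r))
  idx <- which(ok)
  if (length(idx)) {
    i0 <- cbind(r0[idx], c0[idx])
    v00 <- img[i0]
    v10 <- img[cbind(r0[idx] + 1L, c0[idx])]
    v01 <- img[cbind(r0[idx], c0[idx] + 1L)]
    v11 <- img[cbind(r0[idx] + 1L, c0[idx] + 1L)]
    out[idx] <- v00 * (1 - fr[idx]) * (1 - fc[idx]) +
      v10 * fr[idx] * (1 - fc[idx]) +
      v01 * (1 - fr[idx]) * fc[idx] +
      v11 * fr[idx] * fc[idx]
  }
  idx2 <- which(edge & !ok)
  if (length(idx2)) {
    rr <- pmin(r0[idx2], nr); cc <- pmin(c0[idx2], nc)
    out[idx2] <- img[cbind(rr, cc)]
  }
  out
}

#' Nearest-neighbour sampling of a binary mask
#' @keywords internal
nearestSample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- rep(0, length(r))
  if (any(ok)) out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}

#' Coordinate grid of an image
#' @return list with vectors `r`, `c` covering every pixel (column-major).
#' @keywords internal
pixelGrid <- function(dim) {
  list(
    r = rep(seq_len(dim[1]), times = dim[2]),
    c = rep(seq_len(dim[2]), each = dim[1])
  )
}

#' Translate an image by a (possibly fractional) shift
#'
#' The image content moves by `shift = c(dr, dc)`: the output at (r, c) is
#' the input sampled at (r - dr, c - dc). Out-of-support pixels get `fill`.
#'
#' @keywords internal
translateImage <- function(img, shift, fill = 0) {
  g <- pixelGrid(dim(img))
  v <- bilinearSample(img, g$r - shift[1], g$c - shift[2])
  v[is.na(v)] <- fill
  matrix(v, nrow(img), ncol(img))
}

#' Gaussian blur with renormalized edges
#'
#' Separable Gaussian convolution implemented as banded matrix products;
#' kernel rows are renormalized near the borders so the filter preserves
#' constants everywhere (no dark frame at the edges).
#'
#' @keywords internal
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  blurMat <- function(n) {
    rad <- max(1L, ceiling(3 * sigma))
    offs <- (-rad):rad
    w <- exp(-offs^2 / (2 * sigma^2))
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + offs
      ok <- j >= 1 & j <= n
      M[i, j[ok]] <- w[ok] / sum(w[ok])
    }
    M
  }
  Br <- blurMat(nrow(img))
  Bc <- blurMat(ncol(img))
  Br %*% img %*% t(Bc)
}

#' Smooth random field (for irregular lesion shapes and deformations)
#' @keywords internal
smoothNoiseField <- function(dim, sigma) {
  gaussianBlur(matrix(stats::rnorm(prod(dim)), dim[1], dim[2]), sigma)
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude MR images have Rician-distributed noise: the observed value is
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)`. For S = 0 the mean
#' magnitude is `sigma * sqrt(pi / 2)` (the noise floor).
#'
#' @param img noiseless signal matrix (>= 0).
#' @param sigma Gaussian channel noise sd, in signal units.
#' @return matrix of noisy magnitudes.
#' @export
addRicianNoise <- function(img, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  n <- length(img)
  re <- img + stats::rnorm(n, sd = sigma)
  im <- stats::rnorm(n, sd = sigma)
  matrix(sqrt(re^2 + im^2), nrow(img), ncol(img))
}

# Derive a stage-specific seed below 2^31 from a base seed.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(offset) %% 1000L)
}
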