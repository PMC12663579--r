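## Internal numerical helpers shared across modules.
##
## Convention: images are ny x nx matrices indexed [row = y, col = x],
## pixel coordinates are 0-based at pixel centers, and spatial frequencies
## are expressed in cycles per pixel on the FFT-ordered grid. Conversion to
## physical units (nm, um^-1) happens only at reporting boundaries.

#' FFT sample frequencies in cycles per pixel
#'
#' @param n number of samples.
#' @return numeric vector of length `n`, FFT-ordered (DC first).
#' @keywords internal
#' @noRd
fftFreq <- function(n) {
  k <- 0:(n - 1L)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

## ky / kx grids (cycles/px) for an ny x nx image, FFT ordering.
freqGrids <- function(ny, nx) {
  list(ky = matrix(fftFreq(ny), ny, nx),
       kx = matrix(fftFreq(nx), ny, nx, byrow = TRUE))
}

freqRadius <- function(ny, nx) {
  g <- freqGrids(ny, nx)
  sqrt(g$ky^2 + g$kx^2)
}

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Move DC to the array center (and back with inverse = TRUE).
fftShift <- function(x, inverse = FALSE) {
  d <- dim(x)
  sy <- if (inverse) ceiling(d[1] / 2) else floor(d[1] / 2)
  sx <- if (inverse) ceiling(d[2] / 2) else floor(d[2] / 2)
  iy <- ((seq_len(d[1]) - 1L + (d[1] - sy)) %% d[1]) + 1L
  ix <- ((seq_len(d[2]) - 1L + (d[2] - sx)) %% d[2]) + 1L
  x[iy, ix, drop = FALSE]
}

## Circular (periodic) convolution of an image with a kernel given by its
## transfer function on the same FFT grid.
applyTransfer <- function(img, transfer) {
  Re(ifft2(fft2(img) * transfer))
}

## Gaussian low-pass via its analytic transfer function exp(-2 pi^2 s^2 |k|^2);
## periodic boundary, exactly mass-preserving (transfer at DC is 1).
gaussianBlurFFT <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  kr2 <- freqRadius(nrow(img), ncol(img))^2
  applyTransfer(img, exp(-2 * pi^2 * sigma_px^2 * kr2))
}

## Bilinear interpolation of `img` at fractional (y, x) positions (0-based,
## pixel centers); coordinates are clamped to the image support.
bilinearAt <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- pmin(floor(y), ny - 2); x0 <- pmin(floor(x), nx - 2)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0 + 1, x0 + 1)
  i10 <- cbind(y0 + 2, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
}

## Whole-image fractional shift by (dy, dx) pixels using bilinear sampling
## with clamped borders: out[y, x] = img[y + dy, x + dx].
bilinearShift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  yy <- matrix(0:(ny - 1), ny, nx) + dy
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) + dx
  matrix(bilinearAt(img, as.vector(yy), as.vector(xx)), ny, nx)
}

## Spatial coordinate grids (0-based pixel units).
pixelGrids <- function(ny, nx, step = 1) {
  list(y = matrix(seq(0, by = step, length.out = ny), ny, nx),
       x = matrix(seq(0, by = step, length.out = nx), ny, nx, byrow = TRUE))
}

## Grayscale morphological filters with a disk structuring element and
## replicated (clamped) borders: out[p] = min/max over the disk of the
## clamped neighborhood. Opening (erosion then dilation) removes compact
## bright features narrower than the disk while preserving smooth fields.
diskOffsets <- function(r) {
  o <- expand.grid(dy = -r:r, dx = -r:r)
  o[o$dy^2 + o$dx^2 <= r^2, , drop = FALSE]
}

shiftClamped <- function(m, dy, dx) {
  iy <- pmin(pmax(seq_len(nrow(m)) + dy, 1), nrow(m))
  ix <- pmin(pmax(seq_len(ncol(m)) + dx, 1), ncol(m))
  m[iy, ix, drop = FALSE]
}

rankFilterDisk <- function(m, offsets, fun) {
  out <- m
  for (i in seq_len(nrow(offsets)))
    out <- fun(out, shiftClamped(m, offsets$dy[i], offsets$dx[i]))
  out
}

grayOpening <- function(m, radius) {
  if (radius < 1) return(m)
  off <- diskOffsets(radius)
  rankFilterDisk(rankFilterDisk(m, off, pmin), off, pmax)
}

## Run an expression with a locally-seeded RNG, restoring the caller's
## RNG state afterwards so library calls do not perturb user randomness.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
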