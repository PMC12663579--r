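## Quantitative evaluation: signal-to-background ratio (global and local),
## FWHM resolution, radial spectra, and line profiles.

## Automatic signal mask: Otsu threshold on a Gaussian-smoothed copy.
autoMask <- function(image, smoothSigma = 1) {
  sm <- gaussianBlurFFT(image, smoothSigma)
  rng <- range(sm)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  norm <- (sm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > th
}

#' Signal-to-background ratio (SBR) in dB
#'
#' \deqn{SBR = 10 \log_{10}\frac{\max(\mathrm{signal}) -
#'   \mathrm{mean}(\mathrm{background})}{\mathrm{s.d.}(\mathrm{background})}}
#' where the signal is the masked-in pixels and the background all pixels
#' without structural signal (masked-out). The default mask is an Otsu
#' threshold on a Gaussian-smoothed (sigma = 1 px) copy; a user mask or a
#' robust 99.9th-percentile "max" can be requested. The metric is invariant
#' under affine intensity maps `a I + c` (a > 0).
#'
#' @param image numeric matrix, finite.
#' @param mask optional logical matrix (TRUE = signal); `NULL` uses the
#'   automatic Otsu mask.
#' @param maxMode `"literal"` (max of signal pixels) or `"robust"`
#'   (99.9th percentile).
#' @return named list: `sbr_db`, `signal_max`, `background_mean`,
#'   `background_sd`, `mask_mode`, `max_mode`, `n_background_px`. If the
#'   numerator is non-positive `sbr_db` is `-Inf` (flagged, not an error).
#' @examples
#' img <- matrix(10, 64, 64); img[30:34, 30:34] <- 100
#' sbr(img, mask = img > 50)$sbr_db
#' @export
sbr <- function(image, mask = NULL, maxMode = c("literal", "robust")) {
  maxMode <- match.arg(maxMode)
  if (!all(is.finite(image))) stopf("image must be finite")
  maskMode <- if (is.null(mask)) "auto_otsu" else "user"
  if (is.null(mask)) mask <- autoMask(image)
  bg <- image[!mask]
  if (length(bg) < 100)
    stopf("only %d background pixels; at least 100 are required", length(bg))
  sg <- image[mask]
  if (!length(sg)) stopf("empty signal mask")
  bsd <- stats::sd(bg)
  if (bsd == 0) stopf("degenerate background: zero standard deviation")
  smax <- if (maxMode == "literal") max(sg)
          else stats::quantile(sg, 0.999, names = FALSE)
  numer <- smax - mean(bg)
  list(sbr_db = if (numer <= 0) -Inf else 10 * log10(numer / bsd),
       signal_max = smax, background_mean = mean(bg), background_sd = bsd,
       mask_mode = maskMode, max_mode = maxMode,
       n_background_px = length(bg))
}

#' Local SBR map over sliding windows
#'
#' Evaluates [sbr()] per window (automatic mask computed per window);
#' windows where the computation is undefined (too few background pixels,
#' degenerate background, non-positive numerator) are `NA`.
#'
#' @param image numeric matrix.
#' @param windowPx window side in px, >= 16.
#' @param stride step between windows (default `windowPx`, non-overlapping).
#' @return numeric matrix of SBR values (dB), one per window position.
#' @export
localSBR <- function(image, windowPx, stride = windowPx) {
  if (windowPx < 16) stopf("window must be >= 16 px")
  ny <- nrow(image); nx <- ncol(image)
  if (windowPx > ny || windowPx > nx) stopf("window larger than image")
  ys <- seq(1, ny - windowPx + 1, by = stride)
  xs <- seq(1, nx - windowPx + 1, by = stride)
  out <- matrix(NA_real_, length(ys), length(xs))
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    w <- image[ys[i]:(ys[i] + windowPx - 1), xs[j]:(xs[j] + windowPx - 1)]
    v <- tryCatch(sbr(w)$sbr_db, error = function(e) NA_real_)
    out[i, j] <- if (is.finite(v)) v else NA_real_
  }
  out
}

#' FWHM of a point-like feature
#'
#' Extracts an intensity profile through `center` along `directionDeg`
#' (bilinear sampling at 0.1 px steps), subtracts the local background
#' (median of the profile edges), and locates the two half-maximum
#' crossings by linear interpolation.
#'
#' @param image numeric matrix.
#' @param center `(y, x)` position (0-based px) of the feature; the profile
#'   peak within `searchPx` of the center is used as the maximum.
#' @param directionDeg profile direction in degrees (0 = +x).
#' @param pixelNm pixel size in nm; the FWHM is returned in nm.
#' @param halfLengthPx half-length of the extracted profile (default 15 px).
#' @param searchPx radius (px) around `center` within which the profile
#'   maximum may sit.
#' @return FWHM in nm.
#' @export
fwhm <- function(image, center, directionDeg = 0, pixelNm = 1,
                 halfLengthPx = 15, searchPx = 3) {
  th <- directionDeg * pi / 180
  step <- 0.1
  t <- seq(-halfLengthPx, halfLengthPx, by = step)
  ys <- center[1] + t * sin(th)
  xs <- center[2] + t * cos(th)
  prof <- bilinearAt(image, ys, xs)
  nedge <- max(3, round(0.1 * length(prof)))
  bg <- stats::median(c(utils::head(prof, nedge), utils::tail(prof, nedge)))
  prof <- prof - bg
  inCenter <- abs(t) <= searchPx
  ipk <- which(inCenter)[which.max(prof[inCenter])]
  pk <- prof[ipk]
  if (pk <= 0) stopf("no local maximum near the requested center")
  half <- pk / 2
  cross <- function(idx) {
    ## linear interpolation between the last sample above half and the
    ## first below, scanning outward from the peak
    for (i in idx) if (prof[i] < half) {
      j <- if (i < ipk) i + 1L else i - 1L
      frac <- (prof[j] - half) / (prof[j] - prof[i])
      return(t[j] + frac * (t[i] - t[j]))
    }
    NA_real_
  }
  left <- cross(rev(seq_len(ipk - 1L)))
  right <- cross(seq(ipk + 1L, length(prof)))
  if (is.na(left) || is.na(right))
    stopf("no two half-maximum crossings found along the profile")
  (right - left) * pixelNm
}

#' Azimuthally averaged log-amplitude spectrum
#'
#' Averages `log10 |FT(image)|` over annuli of one grid-step width and
#' reports the noise floor (median of the outer 10% of annuli) and an
#' estimated cutoff: the center of the first annulus whose amplitude drops
#' to within `marginLog10` (log10 units, default 0.3) of the noise floor.
#'
#' @param image numeric matrix.
#' @param marginLog10 cutoff margin above the noise floor, in log10 units.
#' @return list: `k` (annulus centers, cycles/px), `logAmplitude`,
#'   `noiseFloor`, `cutoff` (cycles/px, `NA` if the spectrum never reaches
#'   the floor).
#' @export
radialSpectrum <- function(image, marginLog10 = 0.3) {
  if (!all(is.finite(image))) stopf("image must be finite")
  ny <- nrow(image); nx <- ncol(image)
  amp <- Mod(fft2(image))
  kr <- freqRadius(ny, nx)
  dk <- 1 / max(ny, nx)
  bin <- floor(kr / dk)
  nb <- floor(0.5 / dk)
  keep <- bin < nb
  mean_amp <- tapply(amp[keep], bin[keep], mean)
  kcenters <- (as.numeric(names(mean_amp)) + 0.5) * dk
  logA <- log10(pmax(mean_amp, .Machine$double.xmin))
  outer10 <- logA[kcenters >= 0.9 * max(kcenters)]
  floorv <- stats::median(outer10)
  below <- which(logA <= floorv + marginLog10 & kcenters > dk)
  list(k = unname(kcenters), logAmplitude = unname(logA),
       noiseFloor = unname(floorv),
       cutoff = if (length(below)) unname(kcenters[below[1]]) else NA_real_)
}

#' Intensity profile along a segment
#'
#' Bilinear sampling at `nSamples` equally spaced positions between `p0`
#' and `p1` (0-based `(y, x)` pixel coordinates).
#'
#' @param image numeric matrix.
#' @param p0,p1 segment endpoints `(y, x)` in 0-based px, inside the image.
#' @param nSamples number of samples (default: ceiling of the segment
#'   length in px plus one).
#' @param pixelNm pixel size in nm for the distance axis.
#' @return data.frame with columns `distance_nm` and `intensity`.
#' @export
intensityProfile <- function(image, p0, p1, nSamples = NULL, pixelNm = 1) {
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stopf("zero-length segment")
  inImg <- function(p) all(p >= 0) && p[1] <= nrow(image) - 1 &&
    p[2] <= ncol(image) - 1
  if (!inImg(p0) || !inImg(p1)) stopf("endpoints must lie inside the image")
  if (is.null(nSamples)) nSamples <- ceiling(len) + 1L
  t <- seq(0, 1, length.out = nSamples)
  ys <- p0[1] + t * (p1[1] - p0[1])
  xs <- p0[2] + t * (p1[2] - p0[2])
  data.frame(distance_nm = t * len * pixelNm,
             intensity = bilinearAt(image, ys, xs))
}
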