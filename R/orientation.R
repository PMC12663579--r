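## Per-pixel fiber orientation by weighted vector summation. Within a
## (default 7x7) window, every vector from the central pixel to one of the
## window^2 - 1 = 48 surrounding pixels is scored by two weights: F1, the
## inverse of the vector length, and F2, the intensity-uniformity score
##   F2 = sqrt(1/3) - sqrt((1/2) sum_i (I_i - Ibar)^2)
## computed from three intensities sampled along the vector (at fractional
## positions 0, 1/2, 1 by bilinear interpolation, intensities normalized to
## [0, 1]). Vectors pointing along a fiber sample uniform intensity and
## score high; the weighted sum of doubled-angle unit vectors gives the
## axial mean direction, mapped to [0, 180) degrees.

#' Candidate vectors of an orientation window
#'
#' Enumerates the `windowPx^2 - 1` vectors from the central pixel of a
#' `windowPx x windowPx` window to every surrounding pixel (48 for the
#' default 7x7 window), with their lengths and first weight factor
#' `F1 = 1 / length`.
#'
#' @param windowPx odd window size >= 3.
#' @return data.frame with columns `dy`, `dx`, `length`, `F1`.
#' @export
candidateVectors <- function(windowPx = 7L) {
  windowPx <- as.integer(windowPx)
  if (windowPx < 3L || windowPx %% 2L == 0L)
    stopf("windowPx must be odd and >= 3, got %d", windowPx)
  h <- (windowPx - 1L) %/% 2L
  offs <- expand.grid(dy = -h:h, dx = -h:h)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  offs$length <- sqrt(offs$dy^2 + offs$dx^2)
  offs$F1 <- 1 / offs$length
  rownames(offs) <- NULL
  offs
}

#' Per-pixel orientation field of fibrous structures
#'
#' @param image numeric matrix; intensities are normalized to `[0, 1]`
#'   internally, so the result is invariant under positive scaling.
#' @param windowPx odd window size >= 3 (default 7: 48 candidate vectors).
#' @param intensityThreshold pixels whose normalized intensity falls below
#'   this are marked invalid (default 0.05).
#' @param combine how the two weight factors combine: `"sum"` (`F1 + F2`,
#'   clipped at 0; default) or `"product"`.
#' @return an [OrientationField-class].
#' @examples
#' img <- matrix(0, 64, 64); img[32, ] <- 1   # horizontal line
#' of <- orientationField(img)
#' median(of@thetaDeg[32, of@valid[32, ]])    # ~0 degrees
#' @export
orientationField <- function(image, windowPx = 7L, intensityThreshold = 0.05,
                             combine = c("sum", "product")) {
  combine <- match.arg(combine)
  windowPx <- as.integer(windowPx)
  if (windowPx < 3L || windowPx %% 2L == 0L)
    stopf("windowPx must be odd and >= 3, got %d", windowPx)
  mx <- max(image)
  img <- if (mx > 0) image / mx else image
  offs <- candidateVectors(windowPx)
  ny <- nrow(img); nx <- ncol(img)
  c2 <- matrix(0, ny, nx); s2 <- matrix(0, ny, nx)
  sqrt13 <- sqrt(1 / 3)
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    len <- sqrt(dy^2 + dx^2)
    F1 <- 1 / len
    I1 <- img
    I2 <- bilinearShift(img, dy / 2, dx / 2)
    I3 <- bilinearShift(img, dy, dx)
    Ibar <- (I1 + I2 + I3) / 3
    F2 <- sqrt13 -
      sqrt(0.5 * ((I1 - Ibar)^2 + (I2 - Ibar)^2 + (I3 - Ibar)^2))
    w <- if (combine == "sum") pmax(F1 + F2, 0) else pmax(F1 * F2, 0)
    alpha2 <- 2 * atan2(dy, dx)
    c2 <- c2 + w * cos(alpha2)
    s2 <- s2 + w * sin(alpha2)
  }
  theta <- (atan2(s2, c2) / 2 * 180 / pi) %% 180
  theta[theta >= 180] <- 0    # floating-point wrap of the modulo
  weight <- sqrt(c2^2 + s2^2)
  valid <- img >= intensityThreshold
  theta[!valid] <- 0
  new("OrientationField", thetaDeg = theta, weight = weight,
      valid = valid, windowPx = windowPx)
}

#' @rdname OrientationField-accessors
#' @param field an [OrientationField-class].
#' @return `thetaMap()` the angle matrix (degrees), `orientationWeights()`
#'   the resultant-length weights, `validMask()` the validity mask.
#' @name OrientationField-accessors
#' @export
thetaMap <- function(field) field@thetaDeg

#' @rdname OrientationField-accessors
#' @export
orientationWeights <- function(field) field@weight

#' @rdname OrientationField-accessors
#' @export
validMask <- function(field) field@valid

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %d x %d, window %d px, %.1f%% valid\n",
              nrow(object@thetaDeg), ncol(object@thetaDeg), object@windowPx,
              100 * mean(object@valid)))
})

#' Weighted orientation histogram and dominant peaks
#'
#' Weight-weighted histogram of the valid orientation angles over
#' `[0, 180)` degrees, frequencies normalized to sum to 1. Peaks are
#' circular local maxima (after a 3-bin circular moving average) whose
#' height exceeds `minHeightFrac` of the maximum; the angular spacing
#' between the top two peaks is reported as the circular distance
#' (`<= 90` degrees).
#'
#' @param field an [OrientationField-class] (or a list with `theta`,
#'   `weight` vectors).
#' @param bins number of histogram bins over `[0, 180)` (default 180).
#' @param minHeightFrac peak prominence as a fraction of the tallest bin.
#' @return list: `binCenters` (degrees), `frequency` (sums to 1),
#'   `peaks` (data.frame with `theta_deg`, `frequency`), `peakSpacing`
#'   (degrees between the top two peaks, `NA` if fewer than two).
#' @export
orientationHistogram <- function(field, bins = 180L, minHeightFrac = 0.3) {
  if (is(field, "OrientationField")) {
    th <- field@thetaDeg[field@valid]
    w <- field@weight[field@valid]
  } else {
    th <- field$theta; w <- field$weight
  }
  if (!length(th)) stopf("no valid pixels to histogram")
  bw <- 180 / bins
  idx <- pmin(floor(th / bw), bins - 1) + 1
  freq <- vapply(seq_len(bins), function(b) sum(w[idx == b]), numeric(1))
  tot <- sum(freq)
  if (tot > 0) freq <- freq / tot
  centers <- (seq_len(bins) - 0.5) * bw
  sm <- (freq + freq[c(bins, seq_len(bins - 1))] +
           freq[c(seq_len(bins - 1) + 1, 1)]) / 3
  left <- sm[c(bins, seq_len(bins - 1))]
  right <- sm[c(seq_len(bins - 1) + 1, 1)]
  isPeak <- sm >= left & sm > right & sm >= minHeightFrac * max(sm)
  pk <- data.frame(theta_deg = centers[isPeak], frequency = sm[isPeak])
  pk <- pk[order(-pk$frequency), , drop = FALSE]
  spacing <- if (nrow(pk) >= 2) {
    d <- abs(pk$theta_deg[1] - pk$theta_deg[2]) %% 180
    min(d, 180 - d)
  } else NA_real_
  list(binCenters = centers, frequency = freq, peaks = pk,
       peakSpacing = spacing)
}

## Dominant orientation of a set of (theta, weight): histogram peak refined
## by the weighted axial (doubled-angle) mean within +-10 degrees.
dominantTheta <- function(th, w) {
  hist <- orientationHistogram(list(theta = th, weight = w))
  peak <- hist$peaks$theta_deg[1]
  d <- abs(th - peak) %% 180
  near <- pmin(d, 180 - d) <= 10
  a2 <- 2 * th[near] * pi / 180
  (atan2(sum(w[near] * sin(a2)), sum(w[near] * cos(a2))) / 2 * 180 / pi) %% 180
}

#' Track the dominant orientation of a region over time
#'
#' For each time point the dominant orientation of the region is taken from
#' the weighted histogram (refined by a local axial mean); the series is
#' unwrapped across the 0/180-degree seam by choosing, at each step, the
#' representative `theta + 180 k` within 90 degrees of the previous value.
#'
#' @param fields list of [OrientationField-class] objects (one per frame).
#' @param region logical matrix selecting the region of interest.
#' @return data.frame with columns `t` and `theta_deg` (unwrapped; may
#'   leave `[0, 180)`).
#' @export
trackTheta <- function(fields, region) {
  if (!any(region)) stopf("empty region")
  out <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    sel <- region & f@valid
    if (!any(sel)) stopf("region has no valid pixels at frame %d", i)
    th <- dominantTheta(f@thetaDeg[sel], f@weight[sel])
    if (i > 1) {
      k <- round((out[i - 1] - th) / 180)
      th <- th + 180 * k
    }
    out[i] <- th
  }
  data.frame(t = seq_along(fields), theta_deg = out)
}
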