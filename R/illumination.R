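## Illumination-pattern parameter estimation. The sinusoidal pattern of each
## orientation is characterized by its wave vector k0 (cycles/px), the three
## pattern phases, and the modulation depth m. All three are recovered from
## the raw frames themselves so reconstructions need no prior calibration:
##  - k0: coarse peak of the separated first-order band spectrum, refined by
##    maximizing the zeroth/first-order band cross-correlation magnitude
##    under continuous frequency shifts (sub-pixel);
##  - phases: complex argument of each raw frame's spectrum at k0
##    (non-iterative correlation-argument method);
##  - m: least-squares amplitude ratio of the shifted first-order band to
##    the zeroth-order band over the OTF overlap region.

## OTF values at arbitrary (ky, kx) in cycles/px, using the model's analytic
## radial profile.
otfValues <- function(model, ky, kx) {
  kc <- cutoffFrequency(model)
  rho <- sqrt(ky^2 + kx^2) / kc
  out <- rho * 0
  inside <- rho < 1
  if (model@otfModel == "diffraction") {
    r <- rho[inside]
    out[inside] <- (2 / pi) * (acos(r) - r * sqrt(1 - r^2))
  } else {
    out[inside] <- exp(-rho[inside]^2 / (2 * 0.35^2))
  }
  out
}

## Complex band images (real space) separated with nominal equispaced
## phases: element n of the returned list holds order n-2 (-1, 0, +1).
nominalBandImages <- function(frames) {
  np <- length(frames)
  phN <- 2 * pi * (seq_len(np) - 1) / np
  S0 <- Reduce(`+`, frames) / np
  S1 <- Reduce(`+`, Map(function(f, p) f * exp(-1i * p), frames, phN)) / np
  list(S0 = S0, S1 = S1)
}

#' Estimate the pattern wave vector of one orientation
#'
#' Separates the zeroth- and first-order bands with nominal equispaced
#' phases, locates the coarse pattern peak on the integer frequency grid
#' (DC neighborhood excluded), and refines it by maximizing the magnitude
#' of the band cross-correlation
#' `C(k) = sum_r S1(r) conj(S0(r)) exp(-2 pi i k . r)` under continuous
#' shifts. The quality score is the normalized correlation
#' `|C| / (||S1|| ||S0||)`.
#'
#' @param frames list of 3 phase frames (matrices) of one orientation.
#' @param optical the [OpticalModel-class].
#' @param dcExcludeFrac radius of the excluded DC neighborhood, as a
#'   fraction of the OTF cutoff (default 0.1).
#' @param noiseFloorFactor detection threshold: the coarse peak must exceed
#'   this multiple of the median in-support spectrum magnitude (default 5).
#' @return list with `k0` (length-2 `(ky, kx)` in cycles/px) and `quality`.
#' @export
estimateK0 <- function(frames, optical, dcExcludeFrac = 0.1,
                       noiseFloorFactor = 5) {
  stopifnot(length(frames) == 3)
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  kc <- cutoffFrequency(optical)
  bands <- nominalBandImages(frames)
  F1 <- fft2(bands$S1)
  mag <- Mod(F1)
  kr <- freqRadius(ny, nx)
  mask <- kr >= dcExcludeFrac * kc & kr <= kc
  med <- stats::median(mag[mask])
  pk <- max(mag[mask])
  dc0 <- Mod(fft2(bands$S0))[1, 1]
  if (pk < noiseFloorFactor * med || pk < 1e-9 * dc0)
    stopf(paste0("pattern not detected: first-order peak %.3g does not exceed ",
                 "%g x the median in-support magnitude (%.3g)"),
          pk, noiseFloorFactor, med)
  idx <- which(mask & mag == pk, arr.ind = TRUE)[1, ]
  fy <- fftFreq(ny); fx <- fftFreq(nx)
  coarse <- c(fy[idx[1]], fx[idx[2]])
  g <- pixelGrids(ny, nx)
  P <- bands$S1 * Conj(bands$S0)
  corrAt <- function(k)
    Mod(sum(P * exp(-2i * pi * (k[1] * g$y + k[2] * g$x))))
  opt <- stats::optim(coarse, function(k) -corrAt(k), method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  k0 <- opt$par
  quality <- corrAt(k0) /
    (sqrt(sum(Mod(bands$S1)^2)) * sqrt(sum(Mod(bands$S0)^2)))
  list(k0 = k0, quality = as.numeric(quality))
}

#' Estimate pattern phases and modulation depth of one orientation
#'
#' Phases come from the complex argument of the first-order/zeroth-order
#' band correlation at the (sub-pixel) pattern frequency: with nominal
#' equispaced phase steps the separated first-order band equals the true
#' one times `exp(i delta)`, and
#' `delta = Arg(sum_r S1(r) conj(S0(r)) exp(-2 pi i k0 . r))` recovers the
#' global phase offset exactly for noiseless equispaced acquisitions
#' (non-iterative cross-correlation method). The returned phases are the
#' nominal steps plus `delta`, modulo 2 pi. The modulation depth is
#' obtained by separating bands with those phases, shifting the first
#' order back by `k0`, and fitting the complex scale between it and the
#' OTF-reweighted zeroth band over the overlap region where both OTFs are
#' significant; `m` is twice its magnitude, clipped to (0, 1].
#'
#' @inheritParams estimateK0
#' @param k0 length-2 pattern wave vector `(ky, kx)` in cycles/px.
#' @param otfThreshold minimum OTF value defining the overlap region.
#' @return list with `phases` (3 radians in `[0, 2 pi)`) and `m`.
#' @export
estimatePhasesAndModulation <- function(frames, k0, optical,
                                        otfThreshold = 0.15) {
  stopifnot(length(frames) == 3)
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  g <- pixelGrids(ny, nx)
  ramp <- exp(-2i * pi * (k0[1] * g$y + k0[2] * g$x))
  nom <- 2 * pi * (0:2) / 3
  b <- nominalBandImages(frames)
  delta <- Arg(sum(b$S1 * Conj(b$S0) * ramp))
  phases <- (nom + delta) %% (2 * pi)
  fg <- freqGrids(ny, nx)
  H <- otfValues(optical, fg$ky, fg$kx)
  Hs <- otfValues(optical, fg$ky + k0[1], fg$kx + k0[2])
  kc <- cutoffFrequency(optical)
  kr <- sqrt(fg$ky^2 + fg$kx^2)
  overlap <- H > otfThreshold & Hs > otfThreshold & kr > 0.1 * kc
  if (!any(overlap))
    stopf("OTF overlap region is empty: |k0| = %.3f cycles/px is too large for cutoff %.3f",
          sqrt(sum(k0^2)), kc)
  bands <- separateBands(frames, phases)
  B0 <- bands[[2]]
  B1s <- fft2(ifft2(bands[[3]]) * ramp)   # first order shifted back by k0
  R <- B0 * Hs / pmax(H, otfThreshold)
  a <- sum(B1s[overlap] * Conj(R[overlap])) / sum(Mod(R[overlap])^2)
  m <- min(max(2 * Mod(a), 1e-6), 1)
  list(phases = phases, m = m)
}

#' Estimate all illumination parameters of a raw stack
#'
#' Runs [estimateK0()] and [estimatePhasesAndModulation()] for every
#' orientation on one reference plane of the stack.
#'
#' @param raw a [SIMRawStack-class].
#' @param channel,time,z reference plane (default 1, 1, 1).
#' @param ... passed to [estimateK0()].
#' @return an [IlluminationParams-class] with per-orientation quality.
#' @export
estimateIllumination <- function(raw, channel = 1L, time = 1L, z = 1L, ...) {
  om <- raw@optical
  na_ <- raw@nAngles
  k0 <- matrix(0, na_, 2, dimnames = list(NULL, c("ky", "kx")))
  phases <- matrix(0, na_, raw@nPhases)
  m <- numeric(na_); quality <- numeric(na_)
  for (ai in seq_len(na_)) {
    frames <- frameGroup(raw, ai, channel, time, z)
    est <- estimateK0(frames, om, ...)
    pm <- estimatePhasesAndModulation(frames, est$k0, om)
    k0[ai, ] <- est$k0
    phases[ai, ] <- pm$phases
    m[ai] <- pm$m
    quality[ai] <- est$quality
  }
  new("IlluminationParams", k0 = k0, phases = phases, m = m, quality = quality)
}
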