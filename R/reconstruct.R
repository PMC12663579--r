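## Standard two-beam Wiener-SIM reconstruction engine: per orientation the
## three phase frames are separated into diffraction orders (-1, 0, +1) by
## inverting the phase mixing matrix, the first orders are shifted back to
## their true frequency positions with sub-pixel phase ramps on the
## upsampled grid, and all bands are merged with a generalized Wiener
## filter followed by triangular apodization to the extended cutoff.
## The same engine serves the plain Wiener baseline and, after lock-in
## background removal, the background-free reconstruction.

#' Construct reconstruction settings
#'
#' @param wienerW Wiener regularization parameter (relative to the unit-
#'   normalized OTF; default 0.15).
#' @param apodization `"triangular"` (taper to the extended cutoff
#'   `k_cutoff + max |k0|`) or `"none"`.
#' @param upsample integer output upsampling factor (default 2: 32.5 nm
#'   output pixels for 65 nm input).
#' @param notchDc zero small notches at the residual pattern-peak
#'   positions in the combined spectrum (default FALSE).
#' @param intensityCorrection `"none"` or `"mean_match"` (stack processing
#'   rescales every plane's mean to the stack median).
#' @param dcSigmaPx lock-in DC smoothing sigma in px; `NA` = one pattern
#'   period (`1/|k0|`).
#' @param dcCombine lock-in DC combination across orientations:
#'   `"per_orientation"` or `"median"`.
#' @param dcOpenRadiusPx disk radius (px) of the lock-in DC morphological
#'   opening; `NA` = 1.5 pattern periods (see [removeBackground()]).
#' @return a [ReconSettings-class].
#' @export
reconSettings <- function(wienerW = 0.15,
                          apodization = c("triangular", "none"),
                          upsample = 2L, notchDc = FALSE,
                          intensityCorrection = c("none", "mean_match"),
                          dcSigmaPx = NA_real_,
                          dcCombine = c("per_orientation", "median"),
                          dcOpenRadiusPx = NA_real_) {
  new("ReconSettings", wienerW = wienerW,
      apodization = match.arg(apodization), upsample = as.integer(upsample),
      notchDc = notchDc, intensityCorrection = match.arg(intensityCorrection),
      dcSigmaPx = dcSigmaPx, dcCombine = match.arg(dcCombine),
      dcOpenRadiusPx = dcOpenRadiusPx)
}

setMethod("show", "ReconSettings", function(object) {
  cat(sprintf("ReconSettings: w = %.3g, apodization %s, upsample %dx, notch %s, intensity correction %s\n",
              object@wienerW, object@apodization, object@upsample,
              object@notchDc, object@intensityCorrection))
})

#' Separate diffraction-order bands of one orientation
#'
#' Inverts the 3x3 phase mixing matrix `M[j, n] = exp(i n phi_j)`
#' (n = -1, 0, +1) applied to the Fourier transforms of the three phase
#' frames. For real inputs the -1 band is the conjugate mirror of +1.
#'
#' @param frames list of 3 matrices (one per phase).
#' @param phases numeric vector of the 3 pattern phases (radians).
#' @return list of 3 complex FFT-ordered spectra, orders (-1, 0, +1).
#' @export
separateBands <- function(frames, phases) {
  stopifnot(length(frames) == 3, length(phases) == 3)
  M <- outer(phases, c(-1, 0, 1), function(p, n) exp(1i * n * p))
  detM <- M[1,1]*(M[2,2]*M[3,3]-M[2,3]*M[3,2]) -
    M[1,2]*(M[2,1]*M[3,3]-M[2,3]*M[3,1]) +
    M[1,3]*(M[2,1]*M[3,2]-M[2,2]*M[3,1])
  if (Mod(detM) < 1e-10)
    stopf("phase mixing matrix is singular for phases %s",
          paste(sprintf("%.3f", phases), collapse = ", "))
  Mi <- solve(M)
  fts <- lapply(frames, fft2)
  lapply(1:3, function(n)
    Mi[n, 1] * fts[[1]] + Mi[n, 2] * fts[[2]] + Mi[n, 3] * fts[[3]])
}

## Embed an FFT-ordered spectrum into an `up`-times larger FFT grid,
## preserving real-space amplitudes (zero-padding in frequency space).
embedSpectrum <- function(spec, up) {
  if (up == 1L) return(spec)
  ny <- nrow(spec); nx <- ncol(spec)
  uy <- up * ny; ux <- up * nx
  big <- matrix(0i, uy, ux)
  mapIdx <- function(n, un) {
    i <- 0:(n - 1L)
    ifelse(i < ceiling(n / 2), i, un - (n - i)) + 1L
  }
  big[mapIdx(ny, uy), mapIdx(nx, ux)] <- spec
  big * up^2
}

#' Shift a band spectrum with sub-pixel accuracy
#'
#' Translates the spectrum by `shiftK` (content at frequency `k` moves to
#' `k + shiftK`) by multiplying the real-space band with a continuous phase
#' ramp, after embedding it in the `upsample`-times larger padded grid.
#' Frequencies are in cycles per original pixel throughout.
#'
#' @param band complex FFT-ordered spectrum on the original grid.
#' @param shiftK length-2 `(ky, kx)` translation in cycles/px.
#' @param upsample integer padding factor for the output grid.
#' @param maxContentK support radius of the band content (cycles/px), used
#'   to verify the shifted band fits inside the padded Nyquist limit.
#' @return complex FFT-ordered spectrum on the padded grid.
#' @export
shiftBand <- function(band, shiftK, upsample = 2L, maxContentK = NULL) {
  up <- as.integer(upsample)
  if (!is.null(maxContentK) &&
      sqrt(sum(shiftK^2)) + maxContentK > 0.5 * up + 1e-12)
    stopf("shift |%.3f| + content radius %.3f exceeds the padded Nyquist %.3f",
          sqrt(sum(shiftK^2)), maxContentK, 0.5 * up)
  emb <- embedSpectrum(band, up)
  if (all(shiftK == 0)) return(emb)
  b <- ifft2(emb)
  g <- pixelGrids(nrow(emb), ncol(emb), step = 1 / up)
  fft2(b * exp(2i * pi * (shiftK[1] * g$y + shiftK[2] * g$x)))
}

#' Generalized Wiener combination of shifted bands
#'
#' Merges all orientations and orders into one super-resolution spectrum:
#' \deqn{SR(k) = Apo(k) \frac{\sum_{d,n} w_{d,n} OTF(k + n k_{0,d})
#'   B_{d,n}(k)}{\sum_{d,n} w_{d,n}^2 OTF(k + n k_{0,d})^2 + w^2}}
#' with band weights `w_{d,0} = 1` and `w_{d,+-1} = m_d / 2`, and
#' triangular apodization `max(0, 1 - |k|/(k_cutoff + max_d |k0_d|))`.
#'
#' @param bandsShifted list over orientations of lists over orders
#'   (-1, 0, +1) of padded, shifted complex spectra from [shiftBand()].
#' @param params an [IlluminationParams-class].
#' @param optical the [OpticalModel-class].
#' @param settings a [ReconSettings-class].
#' @return complex FFT-ordered SR spectrum on the padded grid.
#' @export
wienerCombine <- function(bandsShifted, params, optical, settings) {
  up <- settings@upsample
  uy <- nrow(bandsShifted[[1]][[2]]); ux <- ncol(bandsShifted[[1]][[2]])
  fy <- fftFreq(uy) * up; fx <- fftFreq(ux) * up   # cycles per original px
  KY <- matrix(fy, uy, ux); KX <- matrix(fx, uy, ux, byrow = TRUE)
  kc <- cutoffFrequency(optical)
  num <- matrix(0i, uy, ux)
  den <- matrix(settings@wienerW^2, uy, ux)
  for (d in seq_along(bandsShifted)) {
    k0 <- params@k0[d, ]
    for (ni in 1:3) {
      n <- ni - 2L
      w <- if (n == 0L) 1 else params@m[d] / 2
      H <- otfValues(optical, KY + n * k0[1], KX + n * k0[2])
      num <- num + w * H * bandsShifted[[d]][[ni]]
      den <- den + (w * H)^2
    }
  }
  sr <- num / den
  kr <- sqrt(KY^2 + KX^2)
  kmax <- kc + max(sqrt(rowSums(params@k0^2)))
  if (settings@apodization == "triangular")
    sr <- sr * pmax(0, 1 - kr / kmax)
  if (settings@notchDc) {
    notchR <- 1.5 / nrow(bandsShifted[[1]][[2]]) * up
    for (d in seq_along(bandsShifted)) for (s in c(-1, 1)) {
      dd <- sqrt((KY - s * params@k0[d, 1])^2 + (KX - s * params@k0[d, 2])^2)
      sr[dd < notchR] <- 0
    }
  }
  sr
}

## Engine shared by the Wiener and lock-in reconstructions: frames is a
## list over orientations of lists over phases of matrices.
reconstructEngine <- function(framesByAngle, params, optical, settings,
                              clip = TRUE) {
  kc <- cutoffFrequency(optical)
  bandsShifted <- lapply(seq_along(framesByAngle), function(d) {
    bands <- separateBands(framesByAngle[[d]], params@phases[d, ])
    lapply(1:3, function(ni) {
      n <- ni - 2L
      shiftBand(bands[[ni]], -n * params@k0[d, ], settings@upsample,
                maxContentK = kc)
    })
  })
  spec <- wienerCombine(bandsShifted, params, optical, settings)
  sr <- Re(ifft2(spec))
  if (clip) sr[sr < 0] <- 0
  sr
}

checkTwoBeamStack <- function(raw) {
  need <- framesPerPlane(acquisitionGeometry("two_beam_2d"))
  if (raw@nAngles * raw@nPhases != need)
    stopf("two-beam reconstruction needs %d frames per plane (3 angles x 3 phases), got %d x %d",
          need, raw@nAngles, raw@nPhases)
}

provenanceOf <- function(raw, params, settings, algorithm) {
  list(algorithm = algorithm,
       wavelength_nm = raw@optical@wavelengthNm, na = raw@optical@na,
       pixel_nm = raw@optical@pixelNm, otf_model = raw@optical@otfModel,
       dims = as.integer(raw@optical@dims),
       k0 = unname(params@k0), phases = unname(params@phases),
       m = params@m, quality = params@quality,
       wiener_w = settings@wienerW, apodization = settings@apodization,
       upsample = settings@upsample, notch_dc = settings@notchDc,
       intensity_correction = settings@intensityCorrection,
       dc_sigma_px = settings@dcSigmaPx, dc_combine = settings@dcCombine,
       dc_open_radius_px = settings@dcOpenRadiusPx,
       software = paste0("LockinSIM ",
                         as.character(utils::packageVersion("LockinSIM"))),
       metadata = raw@metadata)
}

#' Standard Wiener-SIM reconstruction of one plane
#'
#' Band separation, sub-pixel frequency shifting, generalized Wiener
#' combination and apodization on the nine raw frames of one plane. If
#' `params` is `NULL` the illumination parameters are estimated from the
#' raw frames first (an unmodulated stack therefore raises a pattern-not-
#' detected error rather than silently returning a widefield image).
#'
#' @param raw a [SIMRawStack-class]; the plane `(channel, time, z)` is
#'   reconstructed.
#' @param params optional [IlluminationParams-class]; `NULL` estimates them.
#' @param settings a [ReconSettings-class].
#' @param channel,time,z plane to reconstruct (default 1, 1, 1).
#' @return a [ReconstructionResult-class] tagged `"wiener"`.
#' @export
reconstructWiener <- function(raw, params = NULL, settings = reconSettings(),
                              channel = 1L, time = 1L, z = 1L) {
  checkTwoBeamStack(raw)
  if (is.null(params))
    params <- estimateIllumination(raw, channel, time, z)
  frames <- lapply(seq_len(raw@nAngles), function(a)
    frameGroup(raw, a, channel, time, z))
  sr <- reconstructEngine(frames, params, raw@optical, settings)
  new("ReconstructionResult", srImage = sr,
      pixelNm = raw@optical@pixelNm / settings@upsample,
      algorithm = "wiener",
      provenance = provenanceOf(raw, params, settings, "wiener"))
}

#' Lock-in (background-free) SIM reconstruction of one plane
#'
#' Removes the out-of-focus DC background with [removeBackground()] and
#' feeds the AC frames through the same Wiener-SIM engine. Illumination
#' parameters are estimated on the raw frames before background removal
#' (the pattern correlation peaks are stronger there).
#'
#' @inheritParams reconstructWiener
#' @return a [ReconstructionResult-class] tagged `"lockin"`.
#' @export
reconstructLockin <- function(raw, params = NULL, settings = reconSettings(),
                              channel = 1L, time = 1L, z = 1L) {
  checkTwoBeamStack(raw)
  if (is.null(params))
    params <- estimateIllumination(raw, channel, time, z)
  sig <- if (is.na(settings@dcSigmaPx)) NULL else settings@dcSigmaPx
  openR <- if (is.na(settings@dcOpenRadiusPx)) NULL else settings@dcOpenRadiusPx
  dem <- removeBackground(raw, params, sigmaPx = sig,
                          combine = settings@dcCombine,
                          openRadiusPx = openR)
  frames <- lapply(seq_len(raw@nAngles), function(a)
    lapply(seq_len(raw@nPhases), function(j)
      dem@acFrames[channel, time, z, a, j, , ]))
  sr <- reconstructEngine(frames, params, raw@optical, settings)
  new("ReconstructionResult", srImage = sr,
      pixelNm = raw@optical@pixelNm / settings@upsample,
      algorithm = "lockin",
      provenance = provenanceOf(raw, params, settings, "lockin"))
}

#' @rdname ReconstructionResult-accessors
#' @param result a [ReconstructionResult-class].
#' @return `srImage()` the reconstructed matrix; `resultPixelNm()` the
#'   effective pixel size; `provenance()` the parameter record.
#' @name ReconstructionResult-accessors
#' @export
srImage <- function(result) result@srImage

#' @rdname ReconstructionResult-accessors
#' @export
resultPixelNm <- function(result) result@pixelNm

#' @rdname ReconstructionResult-accessors
#' @export
provenance <- function(result) result@provenance

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult (%s): %d x %d at %.2f nm/px, max %.4g\n",
              object@algorithm, nrow(object@srImage), ncol(object@srImage),
              object@pixelNm, max(object@srImage)))
})

#' Reconstruct a z- and/or t-stack plane by plane
#'
#' Runs the chosen reconstruction on every (channel, time, z) plane.
#' Illumination parameters are shared (estimated once on the first plane)
#' or re-estimated per plane. With `intensityCorrection = "mean_match"`
#' every output plane's mean is rescaled to the median of the plane means,
#' compensating bleaching or illumination drift across the stack.
#'
#' @param raw a [SIMRawStack-class] with z and/or t extents.
#' @param mode `"wiener"` or `"lockin"`.
#' @param settings a [ReconSettings-class].
#' @param params optional shared [IlluminationParams-class].
#' @param perPlaneParams re-estimate illumination per plane (default FALSE).
#' @return list with `sr` (array `(c, t, z, Y, X)`), `pixelNm`, and
#'   `provenance` of the first plane.
#' @export
processStack <- function(raw, mode = c("wiener", "lockin"),
                         settings = reconSettings(), params = NULL,
                         perPlaneParams = FALSE) {
  mode <- match.arg(mode)
  fn <- if (mode == "wiener") reconstructWiener else reconstructLockin
  d <- dim(raw@data)
  up <- settings@upsample
  out <- array(0, c(d[1], d[2], d[3], d[6] * up, d[7] * up))
  if (is.null(params) && !perPlaneParams)
    params <- estimateIllumination(raw, 1L, 1L, 1L)
  prov <- NULL
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3])) {
    p <- if (perPlaneParams) NULL else params
    res <- fn(raw, params = p, settings = settings,
              channel = ci, time = ti, z = zi)
    if (is.null(prov)) prov <- res@provenance
    out[ci, ti, zi, , ] <- res@srImage
  }
  if (settings@intensityCorrection == "mean_match") {
    means <- apply(out, 1:3, mean)
    target <- stats::median(means[means > 0])
    for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3]))
      if (means[ci, ti, zi] > 0)
        out[ci, ti, zi, , ] <- out[ci, ti, zi, , ] * target / means[ci, ti, zi]
  }
  list(sr = out, pixelNm = raw@optical@pixelNm / up, provenance = prov)
}
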