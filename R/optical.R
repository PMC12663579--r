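#' Build an optical model with analytic OTF and PSF
#'
#' Constructs the scalar incoherent imaging model for a widefield/SIM
#' microscope. The default OTF is the diffraction-limited incoherent OTF of
#' a circular pupil (normalized pupil autocorrelation)
#' \deqn{OTF(\rho) = \frac{2}{\pi}\left(\arccos\rho - \rho\sqrt{1-\rho^2}\right),
#'   \quad \rho = |k| / k_c,\qquad k_c = 2\,\mathrm{NA}/\lambda,}
#' sampled on the FFT frequency grid of `dims`; a Gaussian approximation
#' (truncated at the same cutoff) is available via `otfModel = "gaussian"`.
#' The PSF is the inverse transform of the OTF, shifted to the array center,
#' clipped at tiny negatives and renormalized to unit sum.
#'
#' The pixel size must satisfy Nyquist sampling of the OTF support:
#' `pixelNm <= wavelengthNm / (4 NA)`, otherwise an error names the largest
#' admissible pixel.
#'
#' @param wavelengthNm emission wavelength in nm (e.g. 488).
#' @param na numerical aperture (e.g. 1.49).
#' @param pixelNm pixel size in nm (e.g. 65).
#' @param dims image dimensions `c(ny, nx)`.
#' @param otfModel `"diffraction"` (default) or `"gaussian"`.
#' @return an [OpticalModel-class].
#' @examples
#' om <- opticalModel(488, 1.49, 65, c(128, 128))
#' cutoffFrequency(om)            # cycles/px
#' cutoffFrequency(om, "um^-1")   # ~6.11 um^-1
#' @export
opticalModel <- function(wavelengthNm, na, pixelNm, dims,
                         otfModel = c("diffraction", "gaussian")) {
  otfModel <- match.arg(otfModel)
  stopifnot(wavelengthNm > 0, na > 0, pixelNm > 0)
  dims <- as.integer(dims)
  kc <- 2 * na / wavelengthNm * pixelNm    # cycles per pixel
  if (kc > 0.5)
    stopf(paste0("Nyquist violation: pixel %.1f nm is too large for ",
                 "NA %.2f at %.0f nm; the maximum admissible pixel is ",
                 "%.1f nm (= lambda / (4 NA))"),
          pixelNm, na, wavelengthNm, wavelengthNm / (4 * na))
  kr <- freqRadius(dims[1], dims[2])
  rho <- kr / kc
  otf <- matrix(0, dims[1], dims[2])
  inside <- rho < 1
  if (otfModel == "diffraction") {
    r <- rho[inside]
    otf[inside] <- (2 / pi) * (acos(r) - r * sqrt(1 - r^2))
  } else {
    ## Gaussian fall-off matched to the diffraction OTF's initial slope
    ## (exp(-(4/pi) rho / ...) heuristics avoided; plain sigma_rho = 0.35),
    ## truncated at the physical cutoff so support invariants hold.
    otf[inside] <- exp(-rho[inside]^2 / (2 * 0.35^2))
  }
  psf <- Re(ifft2(otf))
  psf <- fftShift(psf)
  psf[psf < 0] <- 0
  psf <- psf / sum(psf)
  new("OpticalModel", wavelengthNm = wavelengthNm, na = na, pixelNm = pixelNm,
      dims = dims, otf = otf, psf = psf, otfModel = otfModel)
}

#' OTF cutoff frequency
#'
#' `k_cutoff = 2 NA / lambda`, the support radius of the incoherent OTF.
#'
#' @param model an [OpticalModel-class].
#' @param units `"cycles/px"` (internal convention) or `"um^-1"`.
#' @return cutoff frequency in the requested units.
#' @export
cutoffFrequency <- function(model, units = c("cycles/px", "um^-1")) {
  units <- match.arg(units)
  kc_nm <- 2 * model@na / model@wavelengthNm   # nm^-1
  switch(units,
         "cycles/px" = kc_nm * model@pixelNm,
         "um^-1" = kc_nm * 1000)
}

#' @rdname OpticalModel-accessors
#' @param model an [OpticalModel-class].
#' @return `otf()` and `psf()` return the FFT-ordered OTF and the centered
#'   PSF matrix; `pixelSize()` the pixel size in nm; `modelDims()` `c(ny, nx)`.
#' @name OpticalModel-accessors
#' @aliases otf psf pixelSize modelDims
#' @export
otf <- function(model) model@otf

#' @rdname OpticalModel-accessors
#' @export
psf <- function(model) model@psf

#' @rdname OpticalModel-accessors
#' @export
pixelSize <- function(model) model@pixelNm

#' @rdname OpticalModel-accessors
#' @export
modelDims <- function(model) model@dims

setMethod("show", "OpticalModel", function(object) {
  cat(sprintf("OpticalModel (%s): lambda %.0f nm, NA %.2f, pixel %.1f nm, %d x %d\n",
              object@otfModel, object@wavelengthNm, object@na, object@pixelNm,
              object@dims[1], object@dims[2]))
  cat(sprintf("  k_cutoff: %.4f cycles/px (%.3f um^-1)\n",
              cutoffFrequency(object), cutoffFrequency(object, "um^-1")))
})

#' Acquisition geometry for a SIM modality
#'
#' Defaults encode the two standard linear-SIM acquisition schemes:
#' two-beam 2D-SIM with 3 angles x 3 phases (9 frames per plane, single
#' axial sampling) and three-beam 3D-SIM with 3 angles x 5 phases (15
#' frames per plane, twice the axial sampling density).
#'
#' @param modality `"two_beam_2d"` or `"three_beam_3d"`.
#' @param angles,phases,zSamplingRelative override the modality defaults.
#' @return an [AcquisitionGeometry-class].
#' @examples
#' framesPerPlane(acquisitionGeometry("two_beam_2d"))    # 9
#' framesPerPlane(acquisitionGeometry("three_beam_3d"))  # 15
#' @export
acquisitionGeometry <- function(modality = c("two_beam_2d", "three_beam_3d"),
                                angles = NULL, phases = NULL,
                                zSamplingRelative = NULL) {
  modality <- match.arg(modality)
  def <- switch(modality,
                two_beam_2d = list(angles = 3L, phases = 3L, z = 1),
                three_beam_3d = list(angles = 3L, phases = 5L, z = 2))
  new("AcquisitionGeometry", modality = modality,
      angles = as.integer(angles %||% def$angles),
      phases = as.integer(phases %||% def$phases),
      zSamplingRelative = as.numeric(zSamplingRelative %||% def$z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raw frames required per focal plane
#'
#' @param geom an [AcquisitionGeometry-class].
#' @return `angles * phases`.
#' @export
framesPerPlane <- function(geom) {
  stopifnot(is(geom, "AcquisitionGeometry"))
  as.integer(geom@angles * geom@phases)
}

#' Acquisition speed-up of one geometry over another
#'
#' Fold reduction in the number of exposures needed to cover the same
#' volume, accounting for both frames per plane and relative axial sampling
#' density. For the default three-beam 3D-SIM reference (15 frames, double
#' z-sampling) versus two-beam 2D-SIM (9 frames, single z-sampling) this is
#' (15 x 2) / (9 x 1) = 10/3, i.e. beyond 3-fold.
#'
#' @param reference the slower [AcquisitionGeometry-class] (numerator).
#' @param candidate the faster [AcquisitionGeometry-class] (denominator).
#' @return the exposure ratio as a numeric scalar.
#' @examples
#' speedupRatio(acquisitionGeometry("three_beam_3d"),
#'              acquisitionGeometry("two_beam_2d"))   # 3.333...
#' @export
speedupRatio <- function(reference, candidate) {
  (framesPerPlane(reference) * reference@zSamplingRelative) /
    (framesPerPlane(candidate) * candidate@zSamplingRelative)
}

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf("AcquisitionGeometry '%s': %d angles x %d phases = %d frames/plane, z-sampling x%g\n",
              object@modality, object@angles, object@phases,
              framesPerPlane(object), object@zSamplingRelative))
})
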