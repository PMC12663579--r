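#' @import methods
NULL

#' Optical model of the SIM microscope
#'
#' Scalar diffraction-limited imaging model: wavelength, numerical aperture
#' and pixel geometry together with the incoherent optical transfer function
#' (OTF) sampled on the FFT frequency grid and the matching point spread
#' function (PSF). The OTF is normalized to 1 at zero frequency and has
#' compact support of radius `k_cutoff = 2 NA / lambda`; the PSF is
#' non-negative and sums to 1.
#'
#' @slot wavelengthNm emission wavelength in nm.
#' @slot na numerical aperture of the objective.
#' @slot pixelNm pixel size in nm (sample space).
#' @slot dims image dimensions `c(ny, nx)`.
#' @slot otf real matrix, FFT-ordered OTF (DC at `[1, 1]`).
#' @slot psf real matrix, centered PSF, unit sum.
#' @slot otfModel `"diffraction"` (pupil autocorrelation) or `"gaussian"`.
#'
#' @seealso [opticalModel()], [cutoffFrequency()]
#' @export
setClass("OpticalModel",
  representation(wavelengthNm = "numeric", na = "numeric", pixelNm = "numeric",
                 dims = "integer", otf = "matrix", psf = "matrix",
                 otfModel = "character"),
  validity = function(object) {
    msg <- character()
    if (object@wavelengthNm <= 0) msg <- c(msg, "wavelengthNm must be positive")
    if (object@na <= 0) msg <- c(msg, "na must be positive")
    if (object@pixelNm <= 0) msg <- c(msg, "pixelNm must be positive")
    if (length(object@dims) != 2 || any(object@dims < 8))
      msg <- c(msg, "dims must be two integers >= 8")
    if (!isTRUE(all.equal(object@otf[1, 1], 1, tolerance = 1e-9)))
      msg <- c(msg, "otf must be 1 at zero frequency")
    if (any(object@psf < 0)) msg <- c(msg, "psf must be non-negative")
    if (abs(sum(object@psf) - 1) > 1e-6) msg <- c(msg, "psf must sum to 1")
    kc <- 2 * object@na / object@wavelengthNm * object@pixelNm
    kr <- freqRadius(object@dims[1], object@dims[2])
    if (any(object@otf[kr > kc + 1e-12] != 0))
      msg <- c(msg, "otf must vanish beyond the cutoff frequency")
    if (length(msg)) msg else TRUE
  })

#' SIM acquisition geometry
#'
#' Number of pattern orientations and phase steps per plane and the relative
#' axial sampling density for a SIM modality. Two-beam 2D-SIM uses 3 angles
#' x 3 phases (9 frames) at single axial sampling; three-beam 3D-SIM uses
#' 3 angles x 5 phases (15 frames) at twice the axial sampling density.
#'
#' @slot modality `"two_beam_2d"` or `"three_beam_3d"`.
#' @slot angles number of pattern orientations.
#' @slot phases number of phase steps per orientation.
#' @slot zSamplingRelative relative axial sampling density (planes per unit
#'   depth, relative to single-z-step 2D-SIM).
#'
#' @seealso [acquisitionGeometry()], [framesPerPlane()], [speedupRatio()]
#' @export
setClass("AcquisitionGeometry",
  representation(modality = "character", angles = "integer",
                 phases = "integer", zSamplingRelative = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@modality %in% c("two_beam_2d", "three_beam_3d"))
      msg <- c(msg, "modality must be 'two_beam_2d' or 'three_beam_3d'")
    if (object@angles < 1L) msg <- c(msg, "angles must be >= 1")
    if (object@phases < 1L) msg <- c(msg, "phases must be >= 1")
    if (object@zSamplingRelative <= 0)
      msg <- c(msg, "zSamplingRelative must be positive")
    if (length(msg)) msg else TRUE
  })

#' Raw SIM acquisition stack
#'
#' Raw frames in canonical axis order (channel, time, z, angle, phase, y, x)
#' together with the optical model and free-form acquisition tags. All
#' intensities are finite and non-negative; every (channel, time, z) holds a
#' complete `nAngles x nPhases` frame group.
#'
#' @slot data 7-d numeric array, dims `(c, t, z, angle, phase, ny, nx)`.
#' @slot nAngles number of pattern orientations.
#' @slot nPhases number of phase steps per orientation.
#' @slot optical an [OpticalModel-class] for the acquisition.
#' @slot metadata named list of free-form acquisition tags.
#'
#' @seealso [simRawStack()], [readStack()], [renderSimRaw()]
#' @export
setClass("SIMRawStack",
  representation(data = "array", nAngles = "integer", nPhases = "integer",
                 optical = "OpticalModel", metadata = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 7)
      msg <- c(msg, "data must have 7 axes (c, t, z, angle, phase, y, x)")
    else {
      if (d[4] != object@nAngles || d[5] != object@nPhases)
        msg <- c(msg, "angle/phase axis extents must match nAngles/nPhases")
      if (!all(d[6:7] == object@optical@dims))
        msg <- c(msg, "frame size must match the optical model dims")
    }
    if (!all(is.finite(object@data))) msg <- c(msg, "intensities must be finite")
    if (any(object@data < 0)) msg <- c(msg, "intensities must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Illumination pattern parameters
#'
#' Per-orientation sinusoidal illumination parameters: pattern wave vector
#' `k0` (cycles/pixel, `(ky, kx)`), phase list, modulation depth `m` in
#' (0, 1], and a correlation-quality score. The deviation of the phase steps
#' from an equispaced design is reported, not silently assumed.
#'
#' @slot k0 numeric matrix `nAngles x 2`, columns `(ky, kx)` in cycles/px.
#' @slot phases numeric matrix `nAngles x nPhases`, radians modulo 2 pi.
#' @slot m numeric vector of modulation depths in (0, 1].
#' @slot quality numeric vector of normalized correlation peak strengths.
#'
#' @seealso [illuminationParams()], [estimateIllumination()]
#' @export
setClass("IlluminationParams",
  representation(k0 = "matrix", phases = "matrix", m = "numeric",
                 quality = "numeric"),
  validity = function(object) {
    msg <- character()
    na <- nrow(object@k0)
    if (ncol(object@k0) != 2) msg <- c(msg, "k0 must have columns (ky, kx)")
    if (nrow(object@phases) != na || length(object@m) != na)
      msg <- c(msg, "per-orientation fields must agree in length")
    if (any(sqrt(rowSums(object@k0^2)) >= 0.5))
      msg <- c(msg, "|k0| must be below the grid Nyquist (0.5 cycles/px)")
    if (any(object@m <= 0 | object@m > 1))
      msg <- c(msg, "modulation depths must lie in (0, 1]")
    if (any(object@quality < 0, na.rm = TRUE)) msg <- c(msg, "quality must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Synthetic ground-truth scene
#'
#' Deterministic ground-truth structure for simulations: fluorescent beads,
#' crossed filaments, radial line (Siemens-star-like) targets, or a 3-d
#' volumetric filament scene. The truth map is non-negative with maximum
#' normalized to 1 (all-zero scenes stay zero), and is bit-reproducible for
#' identical (kind, parameters, seed).
#'
#' @slot kind one of `"beads"`, `"crossed_filaments"`, `"radial_lines"`,
#'   `"volume_filaments"`.
#' @slot truth 2-d matrix, or 3-d array `(z, y, x)` for volumes.
#' @slot params named list of geometry parameters used.
#' @slot seed integer seed the scene was generated from.
#'
#' @seealso [makeScene()]
#' @export
setClass("SyntheticScene",
  representation(kind = "character", truth = "array", params = "list",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("beads", "crossed_filaments", "radial_lines",
                            "volume_filaments"))
      msg <- c(msg, "unknown scene kind")
    if (any(object@truth < 0)) msg <- c(msg, "truth must be non-negative")
    mx <- max(object@truth)
    if (mx > 0 && abs(mx - 1) > 1e-9)
      msg <- c(msg, "truth maximum must be normalized to 1")
    if (length(msg)) msg else TRUE
  })

#' Simulation recipe
#'
#' Everything needed to turn a [SyntheticScene-class] into a raw SIM stack:
#' the optical model, illumination parameters, additive Gaussian noise sd,
#' a contrast level multiplying the modulation depth, an unmodulated
#' widefield-background level, and the seed controlling the noise.
#'
#' @slot optical an [OpticalModel-class].
#' @slot illum an [IlluminationParams-class] (3 orientations by default).
#' @slot noiseSd additive Gaussian noise standard deviation (intensity units).
#' @slot contrastLevel multiplier on modulation depth, in (0, 1].
#' @slot backgroundLevel unmodulated widefield background level, >= 0.
#' @slot seed integer RNG seed for the noise.
#'
#' @seealso [simulationRecipe()], [renderSimRaw()]
#' @export
setClass("SimulationRecipe",
  representation(optical = "OpticalModel", illum = "IlluminationParams",
                 noiseSd = "numeric", contrastLevel = "numeric",
                 backgroundLevel = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@contrastLevel <= 0 || object@contrastLevel > 1)
      msg <- c(msg, "contrastLevel must be in (0, 1]")
    if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Lock-in demodulation result
#'
#' Output of [removeBackground()]: per-orientation DC background maps, the
#' modulation amplitude map, and the background-subtracted AC frames, plus a
#' snapshot of the settings used (smoothing sigma, combine mode, clipped
#' negative mass).
#'
#' @slot dcMaps numeric array `(c, t, z, angle, ny, nx)`, >= 0.
#' @slot amplitudeMaps numeric array, same dims as `dcMaps`, >= 0.
#' @slot acFrames numeric array shaped like the input stack data, >= 0.
#' @slot settings named list: `sigma_px`, `combine`, `clipped_mass`.
#'
#' @seealso [removeBackground()], [demodulateThreePhase()]
#' @export
setClass("DemodulationResult",
  representation(dcMaps = "array", amplitudeMaps = "array",
                 acFrames = "array", settings = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@acFrames < 0)) msg <- c(msg, "acFrames must be >= 0")
    if (any(object@dcMaps < 0)) msg <- c(msg, "dcMaps must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Wiener-SIM reconstruction settings
#'
#' @slot wienerW Wiener regularization parameter (relative to the
#'   normalized OTF), > 0.
#' @slot apodization `"triangular"` or `"none"`.
#' @slot upsample integer output upsampling factor (>= 1, default 2).
#' @slot notchDc notch residual pattern peaks near the shifted DC positions.
#' @slot intensityCorrection `"none"` or `"mean_match"` for stack processing.
#' @slot dcSigmaPx Gaussian smoothing sigma (px) for the lock-in DC map;
#'   `NA` means the default of one pattern period (1/|k0|).
#' @slot dcCombine `"per_orientation"` or `"median"` DC combination mode.
#' @slot dcOpenRadiusPx disk radius (px) of the morphological opening of
#'   the lock-in DC map; `NA` means the default of 1.5 pattern periods.
#'
#' @seealso [reconSettings()], [reconstructWiener()], [reconstructLockin()]
#' @export
setClass("ReconSettings",
  representation(wienerW = "numeric", apodization = "character",
                 upsample = "integer", notchDc = "logical",
                 intensityCorrection = "character", dcSigmaPx = "numeric",
                 dcCombine = "character", dcOpenRadiusPx = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@wienerW <= 0) msg <- c(msg, "wienerW must be > 0")
    if (!object@apodization %in% c("triangular", "none"))
      msg <- c(msg, "apodization must be 'triangular' or 'none'")
    if (object@upsample < 1L) msg <- c(msg, "upsample must be >= 1")
    if (!object@intensityCorrection %in% c("none", "mean_match"))
      msg <- c(msg, "intensityCorrection must be 'none' or 'mean_match'")
    if (!object@dcCombine %in% c("per_orientation", "median"))
      msg <- c(msg, "dcCombine must be 'per_orientation' or 'median'")
    if (length(msg)) msg else TRUE
  })

#' Super-resolution reconstruction result
#'
#' @slot srImage non-negative matrix, `upsample` times the input grid.
#' @slot pixelNm effective output pixel size (input pixel / upsample).
#' @slot algorithm `"wiener"` or `"lockin"`.
#' @slot provenance named list capturing parameters and settings.
#'
#' @seealso [reconstructWiener()], [reconstructLockin()], [writeOutputs()]
#' @export
setClass("ReconstructionResult",
  representation(srImage = "matrix", pixelNm = "numeric",
                 algorithm = "character", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@srImage < 0)) msg <- c(msg, "srImage must be >= 0")
    if (!object@algorithm %in% c("wiener", "lockin"))
      msg <- c(msg, "algorithm must be 'wiener' or 'lockin'")
    if (length(msg)) msg else TRUE
  })

#' Per-pixel fiber orientation field
#'
#' Orientation angles theta in [0, 180) degrees with a resultant-length
#' weight map and a validity mask (pixels above the intensity threshold).
#'
#' @slot thetaDeg matrix of angles in degrees, `[0, 180)` where valid.
#' @slot weight non-negative matrix of resultant lengths.
#' @slot valid logical matrix.
#' @slot windowPx odd window size used (default 7).
#'
#' @seealso [orientationField()], [orientationHistogram()]
#' @export
setClass("OrientationField",
  representation(thetaDeg = "matrix", weight = "matrix", valid = "matrix",
                 windowPx = "integer"),
  validity = function(object) {
    msg <- character()
    th <- object@thetaDeg[object@valid]
    if (length(th) && (any(th < 0) || any(th >= 180)))
      msg <- c(msg, "thetaDeg must lie in [0, 180) on valid pixels")
    if (any(object@weight < 0)) msg <- c(msg, "weight must be >= 0")
    if (object@windowPx < 3L || object@windowPx %% 2L == 0L)
      msg <- c(msg, "windowPx must be odd and >= 3")
    if (length(msg)) msg else TRUE
  })
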