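#' Construct illumination parameters
#'
#' Builds per-orientation sinusoidal pattern parameters. Defaults follow
#' common two-beam 2D-SIM practice: three orientations at 0, 60 and 120
#' degrees, pattern frequency at 80% of the OTF cutoff, three equispaced
#' phases (0, 120, 240 degrees) and modulation depth 0.9.
#'
#' @param optical an [OpticalModel-class] fixing the cutoff frequency.
#' @param anglesDeg pattern orientations in degrees.
#' @param k0Frac pattern frequency as a fraction of the OTF cutoff.
#' @param nPhases number of phase steps per orientation.
#' @param phases optional matrix `nAngles x nPhases` of phases (radians);
#'   default equispaced `2 pi (j-1) / nPhases`.
#' @param m modulation depth(s) in (0, 1], recycled across orientations.
#' @return an [IlluminationParams-class].
#' @export
illuminationParams <- function(optical, anglesDeg = c(0, 60, 120),
                               k0Frac = 0.8, nPhases = 3L, phases = NULL,
                               m = 0.9) {
  kc <- cutoffFrequency(optical)
  a <- anglesDeg * pi / 180
  k0 <- cbind(ky = k0Frac * kc * sin(a), kx = k0Frac * kc * cos(a))
  if (is.null(phases))
    phases <- matrix(2 * pi * (seq_len(nPhases) - 1) / nPhases,
                     nrow = length(anglesDeg), ncol = nPhases, byrow = TRUE)
  new("IlluminationParams", k0 = k0, phases = phases,
      m = rep_len(m, length(anglesDeg)),
      quality = rep_len(NA_real_, length(anglesDeg)))
}

#' @rdname IlluminationParams-accessors
#' @param params an [IlluminationParams-class].
#' @return `patternWaveVectors()` returns the `nAngles x 2` matrix of
#'   `(ky, kx)` in cycles/px; `patternPhases()` the phase matrix in radians;
#'   `modulationDepths()` the per-orientation depths.
#' @name IlluminationParams-accessors
#' @export
patternWaveVectors <- function(params) params@k0

#' @rdname IlluminationParams-accessors
#' @export
patternPhases <- function(params) params@phases

#' @rdname IlluminationParams-accessors
#' @export
modulationDepths <- function(params) params@m

setMethod("show", "IlluminationParams", function(object) {
  n <- nrow(object@k0)
  cat(sprintf("IlluminationParams: %d orientations, %d phases\n",
              n, ncol(object@phases)))
  for (d in seq_len(n)) {
    dphi <- diff(object@phases[d, ])
    equi <- 2 * pi / ncol(object@phases)
    dev <- max(abs(((dphi - equi + pi) %% (2 * pi)) - pi)) * 180 / pi
    cat(sprintf("  [%d] |k0| = %.4f c/px at %.1f deg, m = %.3f, equispaced-phase dev %.2f deg%s\n",
                d, sqrt(sum(object@k0[d, ]^2)),
                atan2(object@k0[d, 1], object@k0[d, 2]) * 180 / pi,
                object@m[d], dev,
                if (is.na(object@quality[d])) "" else
                  sprintf(", quality %.3f", object@quality[d])))
  }
})

#' Construct a raw SIM stack from an array
#'
#' @param data numeric array; either 7-d canonical
#'   `(c, t, z, angle, phase, y, x)` or 4-d `(angle, phase, y, x)` which is
#'   promoted to singleton channel/time/z axes.
#' @param optical an [OpticalModel-class] matching the frame size.
#' @param metadata named list of acquisition tags.
#' @return a [SIMRawStack-class].
#' @export
simRawStack <- function(data, optical, metadata = list()) {
  d <- dim(data)
  if (length(d) == 4) {
    data <- array(data, c(1L, 1L, 1L, d))
    d <- dim(data)
  }
  if (length(d) != 7)
    stopf("data must have 4 (angle, phase, y, x) or 7 canonical axes")
  new("SIMRawStack", data = data, nAngles = as.integer(d[4]),
      nPhases = as.integer(d[5]), optical = optical, metadata = metadata)
}

#' Extract one 3-phase frame group
#'
#' @param raw a [SIMRawStack-class].
#' @param angle orientation index.
#' @param channel,time,z plane indices (default 1).
#' @return list of `nPhases` matrices.
#' @export
frameGroup <- function(raw, angle, channel = 1L, time = 1L, z = 1L) {
  lapply(seq_len(raw@nPhases), function(j)
    raw@data[channel, time, z, angle, j, , ])
}

#' @rdname SIMRawStack-accessors
#' @param raw a [SIMRawStack-class].
#' @return `stackData()` the 7-d array; `stackOptical()` the optical model;
#'   `stackDims()` the named dimension vector.
#' @name SIMRawStack-accessors
#' @export
stackData <- function(raw) raw@data

#' @rdname SIMRawStack-accessors
#' @export
stackOptical <- function(raw) raw@optical

#' @rdname SIMRawStack-accessors
#' @export
stackDims <- function(raw) {
  d <- dim(raw@data)
  names(d) <- c("channel", "time", "z", "angle", "phase", "y", "x")
  d
}

setMethod("show", "SIMRawStack", function(object) {
  d <- stackDims(object)
  cat(sprintf("SIMRawStack: %s (c,t,z,angle,phase,y,x), range [%.3g, %.3g]\n",
              paste(d, collapse = " x "), min(object@data), max(object@data)))
})

## ---------------------------------------------------------------------------
## Ground-truth scenes

sceneKinds <- c("beads", "crossed_filaments", "radial_lines", "volume_filaments")

#' Generate a deterministic synthetic ground-truth scene
#'
#' Scenes are rendered at pixel scale with area-weighted antialiasing and
#' are bit-reproducible for identical `(kind, params, seed)`.
#'
#' Supported kinds and their parameters (defaults in parentheses):
#' \describe{
#'   \item{`beads`}{`n` (50) fluorescent microspheres of `diameter_nm` (100)
#'     rendered as antialiased disks; needs `pixel_nm` (65).}
#'   \item{`crossed_filaments`}{`n` (12) straight filaments of `width_px`
#'     (1.5) crossing the field at random positions and angles.}
#'   \item{`radial_lines`}{`n_spokes` (36, or from `delta_deg`) radial lines
#'     of `width_px` (1) between `r_inner` (5) and the field edge.}
#'   \item{`volume_filaments`}{3-d scene: `nz` (2) planes each holding `n`
#'     (6) filaments of `width_px` (1.5); truth has dims `(z, y, x)`.}
#' }
#'
#' @param kind scene kind, one of
#'   `"beads"`, `"crossed_filaments"`, `"radial_lines"`, `"volume_filaments"`.
#' @param dims image dims `c(ny, nx)`.
#' @param params named list of geometry parameters (see Details).
#' @param seed integer seed.
#' @return a [SyntheticScene-class] with truth normalized to max 1.
#' @examples
#' sc <- makeScene("crossed_filaments", c(128, 128), list(n = 8), seed = 1)
#' range(sceneTruth(sc))
#' @export
makeScene <- function(kind, dims = c(256L, 256L), params = list(), seed = 1L) {
  if (!kind %in% sceneKinds)
    stopf("unknown scene kind '%s'; valid kinds: %s", kind,
          paste(sceneKinds, collapse = ", "))
  ny <- as.integer(dims[1]); nx <- as.integer(dims[2])
  truth <- withSeed(as.integer(seed), switch(kind,
    beads = renderBeads(ny, nx, params),
    crossed_filaments = renderFilaments(ny, nx, params),
    radial_lines = renderRadialLines(ny, nx, params),
    volume_filaments = renderVolumeFilaments(ny, nx, params)))
  mx <- max(truth)
  if (mx > 0) truth <- truth / mx
  new("SyntheticScene", kind = kind, truth = as.array(truth),
      params = params, seed = as.integer(seed))
}

#' @rdname SyntheticScene-accessors
#' @param scene a [SyntheticScene-class].
#' @return `sceneTruth()` the ground-truth array; `sceneKind()` the kind.
#' @name SyntheticScene-accessors
#' @export
sceneTruth <- function(scene) scene@truth

#' @rdname SyntheticScene-accessors
#' @export
sceneKind <- function(scene) scene@kind

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene '%s': %s, seed %d\n", object@kind,
              paste(dim(object@truth), collapse = " x "), object@seed))
})

renderBeads <- function(ny, nx, p) {
  n <- p$n %||% 50L
  diameter_nm <- p$diameter_nm %||% 100
  pixel_nm <- p$pixel_nm %||% 65
  r_px <- diameter_nm / 2 / pixel_nm
  img <- matrix(0, ny, nx)
  if (n < 1) return(img)
  cy <- stats::runif(n, 2, ny - 3)
  cx <- stats::runif(n, 2, nx - 3)
  g <- pixelGrids(ny, nx)
  for (i in seq_len(n)) {
    ## area-weighted antialiasing: coverage ~ clamp(r + 1/2 - dist, 0, 1)
    d <- sqrt((g$y - cy[i])^2 + (g$x - cx[i])^2)
    img <- img + pmin(pmax(r_px + 0.5 - d, 0), 1)
  }
  img
}

lineDistanceProfile <- function(ny, nx, py, px, theta, width_px) {
  g <- pixelGrids(ny, nx)
  ## perpendicular distance from each pixel to the infinite line through
  ## (py, px) with direction (dy, dx) = (sin theta, cos theta)
  d <- abs(cos(theta) * (g$y - py) - sin(theta) * (g$x - px))
  pmin(pmax(width_px / 2 + 0.5 - d, 0), 1)
}

renderFilaments <- function(ny, nx, p) {
  n <- p$n %||% 12L
  width_px <- p$width_px %||% 1.5
  img <- matrix(0, ny, nx)
  if (n < 1) return(img)
  for (i in seq_len(n)) {
    py <- stats::runif(1, 0.1 * ny, 0.9 * ny)
    px <- stats::runif(1, 0.1 * nx, 0.9 * nx)
    theta <- stats::runif(1, 0, pi)
    img <- img + lineDistanceProfile(ny, nx, py, px, theta, width_px)
  }
  img
}

renderRadialLines <- function(ny, nx, p) {
  n_spokes <- p$n_spokes %||% (if (!is.null(p$delta_deg)) round(180 / p$delta_deg)
                               else 36L)
  width_px <- p$width_px %||% 1
  r_inner <- p$r_inner %||% 5
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  g <- pixelGrids(ny, nx)
  dy <- g$y - cy; dx <- g$x - cx
  r <- sqrt(dy^2 + dx^2)
  img <- matrix(0, ny, nx)
  for (i in seq_len(n_spokes)) {
    theta <- pi * (i - 1) / n_spokes     # spokes cover [0, 180): full lines
    d <- abs(cos(theta) * dy - sin(theta) * dx)
    img <- img + pmin(pmax(width_px / 2 + 0.5 - d, 0), 1) * (r >= r_inner)
  }
  pmin(img, 1) * (r <= min(ny, nx) / 2 - 2)
}

renderVolumeFilaments <- function(ny, nx, p) {
  nz <- p$nz %||% 2L
  n <- p$n %||% 6L
  width_px <- p$width_px %||% 1.5
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz))
    arr[z, , ] <- renderFilaments(ny, nx, list(n = n, width_px = width_px))
  arr
}

## ---------------------------------------------------------------------------
## Raw SIM rendering

#' Construct a simulation recipe
#'
#' @param optical an [OpticalModel-class].
#' @param illum an [IlluminationParams-class]; default
#'   `illuminationParams(optical)`.
#' @param noiseSd additive Gaussian noise sd (intensity units; truth peaks
#'   at 1 before PSF blur).
#' @param contrastLevel multiplier on modulation depth in (0, 1].
#' @param backgroundLevel unmodulated widefield-background level, >= 0.
#' @param seed integer RNG seed for noise.
#' @return a [SimulationRecipe-class].
#' @export
simulationRecipe <- function(optical, illum = illuminationParams(optical),
                             noiseSd = 0, contrastLevel = 1,
                             backgroundLevel = 0, seed = 1L) {
  new("SimulationRecipe", optical = optical, illum = illum,
      noiseSd = noiseSd, contrastLevel = contrastLevel,
      backgroundLevel = backgroundLevel, seed = as.integer(seed))
}

#' Render a raw two-beam SIM acquisition from a scene
#'
#' For each orientation `d` and phase `j` the raw frame is
#' \deqn{I_{d,j} = \{[1 + m_d \cos(2\pi k_{0,d} \cdot r + \varphi_{d,j})]
#'   \cdot O\} * PSF + \mathcal{N}(0, \sigma^2),}
#' clipped at zero after noise. The modulation depth is
#' `m_d * contrastLevel`. If `backgroundLevel > 0` the unmodulated
#' widefield background is superimposed on every frame (see
#' [injectBackground()]). The widefield image `O * PSF` is returned
#' alongside the stack.
#'
#' @param scene a 2-d [SyntheticScene-class].
#' @param recipe a [SimulationRecipe-class]; its optical model fixes the
#'   frame size, which must match the scene.
#' @return list with elements `stack` (a [SIMRawStack-class]) and
#'   `widefield` (matrix).
#' @export
renderSimRaw <- function(scene, recipe) {
  truth <- scene@truth
  if (length(dim(truth)) != 2) stopf("renderSimRaw needs a 2-d scene")
  om <- recipe@optical
  if (!all(dim(truth) == om@dims)) stopf("scene dims must match optical model")
  k0 <- recipe@illum@k0
  if (any(sqrt(rowSums(k0^2)) >= 0.5))
    stopf("|k0| exceeds the grid Nyquist frequency (0.5 cycles/px)")
  phases <- recipe@illum@phases
  m <- recipe@illum@m * recipe@contrastLevel
  na_ <- nrow(k0); np <- ncol(phases)
  ny <- om@dims[1]; nx <- om@dims[2]
  g <- pixelGrids(ny, nx)
  widefield <- applyTransfer(truth, om@otf)
  frames <- array(0, c(1L, 1L, 1L, na_, np, ny, nx))
  withSeed(recipe@seed, {
    for (d in seq_len(na_)) {
      ramp <- 2 * pi * (k0[d, 1] * g$y + k0[d, 2] * g$x)
      for (j in seq_len(np)) {
        pat <- 1 + m[d] * cos(ramp + phases[d, j])
        fr <- applyTransfer(pat * truth, om@otf)
        if (recipe@noiseSd > 0)
          fr <- fr + matrix(stats::rnorm(ny * nx, 0, recipe@noiseSd), ny, nx)
        frames[1, 1, 1, d, j, , ] <- pmax(fr, 0)
      }
    }
  })
  stack <- simRawStack(frames, om,
                       metadata = list(scene_kind = scene@kind,
                                       scene_seed = scene@seed,
                                       noise_sd = recipe@noiseSd,
                                       contrast_level = recipe@contrastLevel,
                                       seed = recipe@seed))
  if (recipe@backgroundLevel > 0)
    stack <- injectBackground(stack, widefield, recipe@backgroundLevel)
  list(stack = stack, widefield = widefield)
}

#' Superimpose an unmodulated widefield background on a raw stack
#'
#' Adds `level * blur(widefield)` to every frame, emulating out-of-focus
#' background: the added term is smooth and carries no pattern modulation.
#' By default the blur re-applies the model PSF once; a Gaussian blur of
#' `blurSigmaPx` can be requested instead.
#'
#' @param raw a [SIMRawStack-class].
#' @param widefield matrix matching the frame size.
#' @param level background level, >= 0.
#' @param blurSigmaPx optional Gaussian sigma (px) replacing the PSF blur.
#' @return a [SIMRawStack-class] with the background added to every frame.
#' @export
injectBackground <- function(raw, widefield, level, blurSigmaPx = NULL) {
  if (level < 0) stopf("background level must be >= 0")
  if (!all(dim(widefield) == raw@optical@dims))
    stopf("widefield dims must match the stack frames")
  bg <- if (is.null(blurSigmaPx)) applyTransfer(widefield, raw@optical@otf)
        else gaussianBlurFFT(widefield, blurSigmaPx)
  if (level == 0) return(raw)
  d <- dim(raw@data)
  add <- aperm(array(bg * level, c(d[6], d[7], d[1:5])),
               c(3, 4, 5, 6, 7, 1, 2))
  out <- raw
  out@data <- raw@data + add
  out@metadata$background_level <- level
  validObject(out)
  out
}

## Gaussian-equivalent sigma (px) of the in-focus PSF from its FWHM.
psfSigmaPx <- function(optical) {
  p <- optical@psf
  cy <- floor(nrow(p) / 2) + 1L
  prof <- p[cy, ]
  cx <- which.max(prof)
  half <- prof[cx] / 2
  right <- which(prof[cx:length(prof)] < half)[1]
  if (is.na(right)) return(1.0)
  i <- cx + right - 2L
  frac <- (prof[i] - half) / (prof[i] - prof[i + 1L])
  hwhm <- (i - cx) + frac
  2 * hwhm / 2.354820045
}

#' Render an optical-sectioning series from a 3-d scene
#'
#' Simulates two-beam SIM acquisitions focused at each requested depth of a
#' volumetric scene. A scene plane at defocus `dz` contributes with reduced
#' pattern modulation `m(dz) = m exp(-(dz/zmUm)^2)` and a widened PSF whose
#' Gaussian-equivalent width grows as
#' `sigma(dz) = sigma0 sqrt(1 + (dz/zrUm)^2)` (sigma0 is the in-focus PSF
#' width), capturing the rapid loss of stripe contrast and sharpness with
#' depth. At `dz = 0` this reduces exactly to [renderSimRaw()].
#'
#' @param scene3d a `volume_filaments` [SyntheticScene-class] (truth dims
#'   `(z, y, x)`).
#' @param recipe a [SimulationRecipe-class].
#' @param zPlanesUm focal-plane depths (um) to acquire; must be non-empty.
#' @param sceneZStepUm axial spacing (um) of the scene planes; plane `i`
#'   sits at depth `(i - 1) * sceneZStepUm`.
#' @param zmUm axial 1/e half-width of the pattern-modulation envelope (um).
#' @param zrUm defocus scale of PSF widening (um).
#' @return list with `stack` (a [SIMRawStack-class] whose z axis runs over
#'   `zPlanesUm`) and `zPlanesUm`.
#' @export
renderVolumeStack <- function(scene3d, recipe, zPlanesUm,
                              sceneZStepUm = 0.6, zmUm = 0.6, zrUm = 0.4) {
  if (length(zPlanesUm) < 1) stopf("zPlanesUm must be non-empty")
  truth <- scene3d@truth
  if (length(dim(truth)) != 3) stopf("renderVolumeStack needs a 3-d scene")
  om <- recipe@optical
  nz_scene <- dim(truth)[1]
  sceneZ <- (seq_len(nz_scene) - 1) * sceneZStepUm
  k0 <- recipe@illum@k0
  phases <- recipe@illum@phases
  m <- recipe@illum@m * recipe@contrastLevel
  na_ <- nrow(k0); np <- ncol(phases)
  ny <- om@dims[1]; nx <- om@dims[2]
  g <- pixelGrids(ny, nx)
  s0 <- psfSigmaPx(om)
  kr2 <- freqRadius(ny, nx)^2
  frames <- array(0, c(1L, 1L, length(zPlanesUm), na_, np, ny, nx))
  withSeed(recipe@seed, {
    for (zi in seq_along(zPlanesUm)) {
      z0 <- zPlanesUm[zi]
      for (d in seq_len(na_)) {
        ramp <- 2 * pi * (k0[d, 1] * g$y + k0[d, 2] * g$x)
        for (j in seq_len(np)) {
          acc <- matrix(0, ny, nx)
          for (i in seq_len(nz_scene)) {
            dz <- sceneZ[i] - z0
            mdz <- m[d] * exp(-(dz / zmUm)^2)
            sigma_add <- s0 * abs(dz) / zrUm
            transfer <- om@otf * exp(-2 * pi^2 * sigma_add^2 * kr2)
            pat <- 1 + mdz * cos(ramp + phases[d, j])
            acc <- acc + applyTransfer(pat * truth[i, , ], transfer)
          }
          if (recipe@noiseSd > 0)
            acc <- acc + matrix(stats::rnorm(ny * nx, 0, recipe@noiseSd), ny, nx)
          frames[1, 1, zi, d, j, , ] <- pmax(acc, 0)
        }
      }
    }
  })
  stack <- simRawStack(frames, om,
                       metadata = list(scene_kind = scene3d@kind,
                                       z_planes_um = zPlanesUm,
                                       zm_um = zmUm, zr_um = zrUm,
                                       seed = recipe@seed))
  list(stack = stack, zPlanesUm = zPlanesUm)
}
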