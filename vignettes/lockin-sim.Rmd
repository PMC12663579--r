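---
title: "Lock-in demodulation for background-free 2D-SIM: models and methods"
author: "LockinSIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lock-in demodulation for background-free 2D-SIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LockinSIM)
```

# The imaging model

A two-beam 2D-SIM acquisition illuminates the sample with a sinusoidal
stripe pattern at three orientations and three phase steps per orientation
(nine raw frames per plane). Each raw frame at a given orientation is

$$I_j(\mathbf r) = \Big\{\big[1 + m\cos(2\pi\,\mathbf k_0\!\cdot\!\mathbf r
 + \varphi_j)\big]\, O(\mathbf r)\Big\} * H(\mathbf r),$$

with pattern wave vector $\mathbf k_0$ (cycles/pixel), phases $\varphi_j$,
modulation depth $m \in (0, 1]$, sample $O$ and point spread function $H$.
Real samples are three-dimensional: only structure near the focal plane is
effectively modulated by the stripes, while out-of-focus light, scattering
and autofluorescence contribute an essentially unmodulated background that
varies slowly across the field. Splitting the sample into an in-focus part
$O_\mathrm{in}$ and an out-of-focus part $O_\mathrm{out}$, every raw frame
decomposes into a modulation-independent (DC) term and a
modulation-dependent (AC) term:

$$I_j = \underbrace{\big[O_\mathrm{out} + (1-m)\,O_\mathrm{in}\big] * H}_{I_\mathrm{dc}}
 \;+\; \underbrace{\big[m + m\cos(2\pi\,\mathbf k_0\!\cdot\!\mathbf r + \varphi_j)\big]
 O_\mathrm{in} * H}_{I_{j,\mathrm{ac}}}.$$

The package's core operation estimates $I_\mathrm{dc}$ from the three
phase frames of each orientation (lock-in / three-phase homodyne
demodulation), filters it, and subtracts it before the standard Wiener-SIM
reconstruction. Everything else — band separation, sub-pixel band
shifting, generalized Wiener combination, apodization — is the classical
linear-SIM engine and is shared between the plain Wiener baseline
(`reconstructWiener()`) and the background-free path
(`reconstructLockin()`).

# Three-phase demodulation and the DC estimate

Per pixel, the three frames satisfy
$I_j = C + a\cos\varphi_j + b\sin\varphi_j$, an exactly determined linear
system for $(C, a, b)$ whenever the phases are distinct modulo $2\pi$.
`demodulateThreePhase()` solves it for arbitrary phase designs; for
equispaced phases it reduces to the classical root-mean-square
optical-sectioning formulas
$C = (I_1+I_2+I_3)/3$ and
$A = \tfrac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2}$,
which the test suite verifies against a brute-force per-pixel least-squares
oracle.

The phase mean $C$ equals $I_\mathrm{dc} + m\,(O_\mathrm{in}*H)$ and the
modulation amplitude $A$ estimates the in-focus term, so
`estimateDC()` returns $\max(C - A,\, 0)$.

## Refining the DC map

$A$ is the amplitude of the *shifted* first-order band and therefore
carries that band's OTF attenuation: on fine structures $A$ underestimates
$m\,(O_\mathrm{in}*H)$ and $C - A$ retains a compact, structure-shaped
bias. Subtracting it would misclassify up to a third of the in-focus
signal as background. `removeBackground()` therefore refines the raw map
before subtraction:

* where modulation is present, the raw DC map is replaced by its
  **grayscale morphological opening** (disk radius `openRadiusPx`,
  default $\lceil 1.5/|\mathbf k_0|\rceil$ pixels, i.e. 1.5 pattern
  periods — wider than any structure the OTF can transmit), which removes
  the compact bias while keeping the local background floor, followed by
  Gaussian smoothing (`filterDC()`, default $\sigma = 1/|\mathbf k_0|$
  px), because background varies slowly and residual in-focus texture must
  not be subtracted;
* where no modulation is present the raw estimate is already exact
  (unmodulated light produces identical frames, so $A = 0$ and
  $C - A$ *is* the background) and is used unfiltered.

The two paths are blended per pixel by a modulation-confidence weight
$W = S^2/(S^2 + (0.02\,\bar C)^2)$, where $S$ and $\bar C$ are the
amplitude and mean maps smoothed with a 2-px Gaussian. The quadratic form
makes the switch sharp: structure pixels (amplitude a substantial fraction
of the mean) get $W \approx 1$ even at interference nulls of the
amplitude map, and unmodulated pixels get $W \approx 0$. Setting
`openRadiusPx = 0` disables the refinement and uses the plain
`filterDC(estimateDC(...))` everywhere.

Two alternatives were considered. Compensating $A$ for the shifted-band
OTF in the frequency domain is formally exact on the band overlap, but the
regularized inverse filter has broad kernel tails that leak amplitude from
bright structures into weak background regions and punch holes into the DC
map there. A plain morphological floor without the confidence weight
handles thin modulated structures but destroys background fields whose own
spatial scale approaches the opening radius. The blended estimator
satisfies all four properties the package tests: residual injected
background below 5%, in-focus signal preservation above 90%,
near-idempotence on background-free stacks, and a near-empty
reconstruction of background-only stacks.

Negative values after subtraction are clipped (fluorescence is
non-negative) and the clipped mass is recorded in the result's settings
snapshot. A `combine = "median"` mode replaces the per-orientation DC maps
by their pixel-wise median across orientations, which is more robust when
one orientation's pattern is degraded.

# Illumination parameter estimation

Reconstruction needs $\mathbf k_0$, $\varphi_j$ and $m$ per orientation;
all three are estimated from the raw frames (`estimateIllumination()`),
and for the lock-in path they are estimated *before* background removal,
where the pattern correlation peaks are strongest.

* **Wave vector.** Bands are separated with nominal equispaced phases; the
  coarse pattern peak is the maximum of the first-order band spectrum
  inside the OTF support, excluding a DC neighborhood of radius
  $0.1\,k_c$. Sub-pixel refinement maximizes the magnitude of the
  band cross-correlation
  $C(\mathbf k) = \sum_\mathbf{r} S_1 \overline{S_0}\,
  e^{-2\pi i\,\mathbf k\cdot\mathbf r}$ under continuous shifts
  (Nelder–Mead, relative tolerance $10^{-12}$), which resolves the peak far
  below the grid spacing — noiseless recovery is a few $10^{-4}$
  cycles/px. Detection requires the coarse peak to exceed 5 times the
  median in-support magnitude (and a $10^{-9}$ floor relative to the
  zeroth-band DC); an unmodulated stack raises a "pattern not detected"
  error rather than silently reconstructing a widefield image.
* **Phases.** With nominal equispaced steps the separated first-order band
  equals the true band times $e^{i\delta}$, and
  $\delta = \arg C(\mathbf k_0)$ recovers the global offset exactly for
  noiseless equispaced acquisitions (the estimator is covariant under
  global phase shifts). Hardware phase steps are equispaced by design;
  arbitrary per-frame phases can still be supplied manually to
  `demodulateThreePhase()` and `separateBands()`. Absolute phase accuracy
  is limited by the $\mathbf k_0$ error times the field radius; at the
  estimator's $\mathbf k_0$ accuracy this is irrelevant for
  reconstruction, which uses the same $\hat{\mathbf k}_0$.
* **Modulation depth.** Bands are separated with the estimated phases, the
  first order is shifted back by $\mathbf k_0$, and a complex scale is
  fitted between it and the OTF-reweighted zeroth band over the region
  where both OTFs exceed 0.15; $m$ is twice its magnitude, clipped to
  $(0, 1]$.

# The Wiener-SIM engine

`separateBands()` inverts the $3\times 3$ mixing matrix
$M_{jn} = e^{in\varphi_j}$; `shiftBand()` embeds each band in an
`upsample`-times padded grid (default 2: 32.5 nm output pixels for 65 nm
input) and translates it with a continuous real-space phase ramp;
`wienerCombine()` merges all orientations and orders,

$$SR(\mathbf k) = \mathrm{Apo}(\mathbf k)\,
 \frac{\sum_{d,n} w_{d,n}\, H(\mathbf k + n\mathbf k_{0,d})\,
       \tilde B_{d,n}(\mathbf k)}
      {\sum_{d,n} w_{d,n}^2\, H(\mathbf k + n\mathbf k_{0,d})^2 + w^2},$$

with band weights $w_{d,0}=1$, $w_{d,\pm 1}=m_d/2$ in numerator *and*
denominator (the modulation-weighted generalized Wiener form), Wiener
parameter `wienerW` (default 0.15 relative to the unit-normalized OTF) and
triangular apodization
$\mathrm{Apo} = \max(0,\, 1 - |\mathbf k|/(k_c + \max_d |\mathbf k_{0,d}|))$.
An optional notch zeroes residual pattern peaks. The final image is the
real part of the inverse transform, clipped at zero.

Numerical conventions: FFT-ordered grids in cycles per (original) pixel
throughout, conversion to nm or µm$^{-1}$ only at reporting boundaries;
0-based pixel-center coordinates `(row, col)`. The whole pipeline is
verified at $64\times 64$ against an independent direct-DFT
reimplementation (explicit DFT matrices, explicit inversions and loops) to
better than $10^{-6}$ relative RMS, in both plain Wiener and lock-in
modes.

Apodization trades resolution for ringing suppression: the triangular
taper roughly halves the contrast near the extended cutoff. FWHM-based
resolution assessments in the test suite therefore use
`apodization = "none"`; with the default pattern frequency
$|\mathbf k_0| = 0.8\,k_c$ the reconstructed bead width is about
$0.56\times$ the widefield width, matching the band-limit prediction
$1/(1+0.8)$.

# The optical model

`opticalModel()` uses the scalar diffraction-limited incoherent OTF of a
circular pupil (normalized pupil autocorrelation),
$\mathrm{OTF}(\rho) = \tfrac{2}{\pi}(\arccos\rho - \rho\sqrt{1-\rho^2})$
for $\rho = |\mathbf k|/k_c$, $k_c = 2\,\mathrm{NA}/\lambda$, verified
against a numerical pupil-overlap integral. A truncated Gaussian
approximation is available (`otfModel = "gaussian"`). Refractive-index
effects, pupil apodization and vectorial high-NA corrections are outside
the model — a documented limitation; at NA 1.49 the true PSF is slightly
wider and anisotropic compared to the scalar prediction. The pixel size
must satisfy $p \le \lambda/(4\,\mathrm{NA})$ so the OTF support fits on
the grid; the error message names the bound.

# The synthetic-data generator

`makeScene()` renders deterministic ground truth (beads with antialiased
disks, crossed filaments, radial line targets, and a volumetric filament
variant), and `renderSimRaw()` applies the image model: pattern
multiplication, OTF-mediated convolution, additive Gaussian noise, zero
clipping. Defaults are the reference experimental conditions: wavelength
488 nm, NA 1.49, 65 nm pixels, three orientations at 0°/60°/120°, three
equispaced phases, modulation depth 0.9, pattern frequency
$0.8\,k_c$ (a typical high-frequency setting; the experimental period is
hardware-specific), `contrastLevel` multiplying $m$. Background is
emulated by `injectBackground()`: the widefield image, blurred once more
with the PSF, added to every frame at a chosen level — unmodulated and
smooth, as out-of-focus light is.

`renderVolumeStack()` extends this to depth: a scene plane at defocus
$\Delta z$ contributes with modulation
$m(\Delta z) = m\,e^{-(\Delta z/z_m)^2}$ and a PSF widened to
$\sigma(\Delta z) = \sigma_0\sqrt{1+(\Delta z/z_R)^2}$. The axial
envelope of real stripe patterns is system-specific, so $z_m$ (default
0.6 µm) and $z_R$ (default 0.4 µm) are exposed parameters, not claims
about any particular instrument; the defaults give stripe contrast that is
essentially gone beyond ±1.5 µm, consistent with high-NA two-beam
interference. Optical-sectioning tests use two planes separated by
$3 z_m$, where the out-of-plane modulation is $e^{-9} \approx 10^{-4}$.

What the simulator does *not* emulate: Poisson shot noise (a flag exists
for the noise model but camera gain/offset/read-noise maps do not),
refractive aberrations, field-dependent pattern distortion,
photobleaching, and sample motion. Passing tests on these simulations
therefore demonstrates algorithmic correctness under the stated model, not
robustness to every artifact of real acquisitions.

# Quantification

* `sbr()` implements
  $\mathrm{SBR} = 10\log_{10}\frac{\max(\mathrm{signal}) -
  \mathrm{mean}(\mathrm{bg})}{\mathrm{sd}(\mathrm{bg})}$ in dB, with the
  background taken from all pixels without structural signal. The default
  mask is an Otsu threshold on a 1-px-smoothed copy (the segmentation is a
  package choice; a user mask can be passed), the literal maximum is used
  by default with a robust 99.9th-percentile alternative flagged in the
  report. The metric is invariant under affine intensity maps, and a
  non-positive numerator yields $-\infty$ flagged rather than an error.
* `localSBR()` evaluates the same metric over sliding windows, `NA` where
  undefined.
* `fwhm()` measures full width at half maximum along a bilinear profile
  with edge-median background subtraction and linear interpolation of the
  half-maximum crossings.
* `radialSpectrum()` reports the azimuthally averaged $\log_{10}$
  amplitude, a noise floor (median of the outer 10% of annuli) and an
  estimated cutoff: the first annulus within 0.3 log10 units of the floor.
  This cutoff rule is a package definition for comparing images on equal
  footing, not a resolution criterion.

# Orientation analysis

`orientationField()` computes per-pixel fiber orientation by weighted
vector summation in a window (default 7×7, hence 48 candidate vectors from
the center to every surrounding pixel): $F_1 = 1/|\mathbf v|$ favors short
vectors; $F_2 = \sqrt{1/3} - \sqrt{\tfrac12\sum_{i=1}^3 (I_i - \bar I)^2}$
scores intensity uniformity along the vector, from three samples at
fractional positions $0, \tfrac12, 1$ by bilinear interpolation
(intensities normalized to $[0,1]$, $\bar I$ the three-sample mean, so
$F_2$ peaks at $\sqrt{1/3} \approx 0.577$ for uniform intensity). The
combined weight is $F_1 + F_2$ clipped at zero (a product variant exists
behind a flag), and weights multiply doubled-angle unit vectors
$(\cos 2\alpha, \sin 2\alpha)$ — the standard axial-statistics device that
resolves the 180° ambiguity — whose resultant gives
$\theta = \tfrac12\operatorname{atan2}(\cdot) \in [0°, 180°)$ and a
confidence weight. Pixels below `intensityThreshold` (default 0.05 of the
maximum) are invalid; for quantitative angle recovery on rendered lines
the tests evaluate core pixels (threshold 0.5), since the orientation of
antialiased half-covered edge pixels is genuinely less defined.
`orientationHistogram()` and `trackTheta()` provide weighted histograms
with peak spacing and seam-unwrapped time series of the dominant angle.

# Stack processing and I/O

`processStack()` reconstructs each (channel, time, z) plane with shared or
per-plane illumination parameters; `intensityCorrection = "mean_match"`
rescales every plane's mean to the stack median, compensating bleaching.
`depthCodeProjection()` encodes the z index of the per-pixel maximum as
hue.

Multi-page TIFF I/O accepts any page order via a layout string over the
axes (channel, time, z, angle, phase) with per-axis counts, replacing
vendor-specific converters; the canonical order is phase-fastest.
Because the TIFF backend stores 32-bit pages as scaled integers, images
are normalized by a power-of-two scale (so the scaling itself is exact in
floating point) recorded in a JSON sidecar together with the full
parameter provenance at 17 significant digits; re-ingesting a sidecar
reproduces a reconstruction bit-exactly.

# Problem sizes and limitations

The bundled tests run entirely on synthetic data: demodulation identities
at 16²–64², parameter recovery and engine-oracle equivalence at 64²–128²,
background-suppression and resolution studies at 256², and two-plane
volumes at 128². These sizes were chosen so the full suite documents the
method's behavior in minutes on a single CPU; the algorithms are
$O(N \log N)$ per plane (plus the rank filters' $O(N r^2)$) and scale to
camera-sized fields.

Known limitations: scalar OTF at high NA; equispaced-phase assumption in
the automatic phase estimator; the DC refinement assumes background
features wider than ~1.5 pattern periods (dirt or debris at the structure
scale in an *unmodulated* layer is handled by the confidence weight, but
background that is both sharp and partially modulated will leak); axial
resolution remains at the 2D-SIM level — optical sectioning removes
out-of-focus light but does not sharpen the axial PSF.
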