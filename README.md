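# LockinSIM

Background-free super-resolution reconstruction for two-beam 2D structured
illumination microscopy (SIM), in R.

2D-SIM doubles lateral resolution from nine raw frames per plane (3
pattern orientations × 3 phases), but every raw frame is an axial
projection: out-of-focus light, scattering and autofluorescence add a
background that degrades modulation contrast, buries fine structure and
produces reconstruction artifacts. Widefield-compatible fixes exist —
TIRF/GI illumination is depth-limited, three-beam 3D-SIM needs 15 frames
per plane at doubled z-sampling. This package instead removes the
background computationally, exploiting that in-focus structure is
modulated by the illumination stripes while out-of-focus background is
not.

Each raw frame obeys

    I_j = {[1 + m cos(2π k0·r + φ_j)] · O} * H

and splits into a modulation-independent (DC) part
`I_dc = [O_out + (1−m) O_in] * H` and a modulation-dependent (AC) part.
Per pixel, the three phase frames `I_j = C + a cos φ_j + b sin φ_j` are an
exactly solvable linear system: the phase mean `C` carries
`I_dc + m (O_in*H)` and the modulation amplitude `A = √(a²+b²)` estimates
`m (O_in*H)`, so `max(C − A, 0)` isolates the background (lock-in /
three-phase homodyne demodulation). The refined DC map (see the methods
vignette) is subtracted from every frame before a standard Wiener-SIM
engine — band separation, sub-pixel frequency shifting, generalized
Wiener combination `Σ w·H·B / (Σ w²H² + w²_reg)`, triangular apodization —
reconstructs the super-resolved image. Against three-beam 3D-SIM the
acquisition is (15 × 2)/(9 × 1) = 3.3-fold faster for the same volume.

The package also provides: a synthetic SIM data generator (beads,
filaments, radial targets, 3-d volumes; pattern modulation, PSF blur,
Gaussian noise, controllable unmodulated background), illumination
parameter estimation (k0, phases, modulation depth) from the raw data,
quantitative metrics (signal-to-background ratio in dB, FWHM, radial
spectra, line profiles), per-pixel fiber orientation by weighted vector
summation, optical-sectioning z-stack and time-lapse processing with
depth-coded projections, and multi-page TIFF I/O with JSON provenance
sidecars that reproduce reconstructions bit-exactly.

## Worked example

Simulate a filament scene under the reference conditions (488 nm, NA 1.49,
65 nm pixels), superimpose an unmodulated widefield background, and
compare the plain Wiener reconstruction with the lock-in path:

```r
library(LockinSIM)

om    <- opticalModel(488, 1.49, 65, c(256, 256))
scene <- makeScene("crossed_filaments", c(256, 256), list(n = 12), seed = 1)
sim   <- renderSimRaw(scene, simulationRecipe(om, noiseSd = 0, seed = 2))
raw   <- injectBackground(sim$stack, sim$widefield, level = 1)

params <- estimateIllumination(raw)
params
#> IlluminationParams: 3 orientations, 3 phases
#>   [1] |k0| = 0.3175 c/px at 0.0 deg, m = 0.614, equispaced-phase dev 0.00 deg, quality 0.415
#>   [2] |k0| = 0.3175 c/px at 60.0 deg, m = 0.611, equispaced-phase dev 0.00 deg, quality 0.413
#>   [3] |k0| = 0.3175 c/px at 120.0 deg, m = 0.615, equispaced-phase dev 0.00 deg, quality 0.413

wiener <- reconstructWiener(raw, params = params)
lockin <- reconstructLockin(raw, params = params)
lockin
#> ReconstructionResult (lockin): 512 x 512 at 32.50 nm/px, max 1.05

mask <- sceneTruth(scene)[rep(1:256, each = 2), rep(1:256, each = 2)] > 0.2
for (r in list(wiener, lockin)) {
  s <- sbr(srImage(r), mask = mask)
  cat(sprintf("%-7s SBR %6.2f dB | background mean %.4f | signal max %.3f\n",
              r@algorithm, s$sbr_db, s$background_mean, s$signal_max))
}
#> wiener  SBR  12.29 dB | background mean 0.0299 | signal max 1.160
#> lockin  SBR  12.53 dB | background mean 0.0187 | signal max 1.033
```

The estimated pattern frequency is 0.8× the OTF cutoff (0.3969 cycles/px),
the phases come out equispaced, and the lock-in reconstruction reaches a
higher signal-to-background ratio with a lower background floor. At the
level of the raw frames the removal is much more dramatic than the SBR of
the final images suggests — the mean residual of the injected background
after `removeBackground()` is below 0.2% here — because Wiener
reconstruction itself spreads and attenuates the smooth background.

Pattern parameters on estimation-friendly data recover the ground truth to
a few 10⁻⁴ cycles/px (k0) and a fraction of a degree (phases); a
reconstructed 100 nm bead shrinks to ≈0.56× its widefield FWHM at this
pattern frequency. See `vignette("lockin-sim")` for the model, parameter
meanings, defaults, and design decisions, and `inst/scripts/lockinsim.R`
for a command-line wrapper
(`simulate | demodulate | reconstruct | metrics | orientation | project`).

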