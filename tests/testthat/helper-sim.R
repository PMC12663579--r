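# Shared fixtures: all built in code at test time.

# Experimental-condition optical model at a reduced grid (wavelength 488 nm,
# NA 1.49, 65 nm pixels).
testOptical <- function(n = 128L) opticalModel(488, 1.49, 65, c(n, n))

# Antialiased straight line through the image center at a given angle
# (degrees, measured from +x toward +y).
lineImage <- function(deg, n = 96L, width = 1.5) {
  th <- deg * pi / 180
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  d <- abs(cos(th) * (g$y - (n - 1) / 2) - sin(th) * (g$x - (n - 1) / 2))
  matrix(pmin(pmax(width / 2 + 0.5 - d, 0), 1), n, n)
}

# Noiseless filament acquisition used by several modules.
filamentSim <- function(n = 128L, seed = 3L, noiseSd = 0, illum = NULL,
                        backgroundLevel = 0) {
  om <- testOptical(n)
  sc <- makeScene("crossed_filaments", c(n, n), list(n = 10), seed = seed)
  ill <- if (is.null(illum)) illuminationParams(om) else illum
  rec <- simulationRecipe(om, illum = ill, noiseSd = noiseSd,
                          backgroundLevel = backgroundLevel, seed = seed + 1L)
  c(renderSimRaw(sc, rec), list(optical = om, scene = sc, recipe = rec))
}

# Circular angular distance in degrees on the 180-degree axial circle.
axialDist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Wrapped phase difference in degrees.
phaseDistDeg <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi) * 180 / pi
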