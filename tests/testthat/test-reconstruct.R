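test_that("band separation inverts the phase mixing exactly", {
  set.seed(21)
  ny <- 32
  ph <- c(0.2, 2.3, 4.4)
  # build frames from known complex bands
  B0r <- matrix(rnorm(ny^2), ny)            # real-space components
  Bpr <- matrix(complex(real = rnorm(ny^2), imaginary = rnorm(ny^2)), ny)
  frames <- lapply(ph, function(p)
    B0r + 2 * Re(exp(1i * p) * Bpr))
  bands <- separateBands(frames, ph)
  expect_lt(max(Mod(bands[[2]] - stats::fft(B0r))), 1e-8)
  expect_lt(max(Mod(bands[[3]] - stats::fft(Bpr))), 1e-8)
  # order -1 is the conjugate mirror of +1 for real frames
  conjMirror <- function(X) {
    n <- nrow(X)
    Conj(X)[c(1, n:2), c(1, n:2)]
  }
  expect_lt(max(Mod(bands[[1]] - conjMirror(bands[[3]]))), 1e-8)
  expect_error(separateBands(frames, c(0, 0, 1)), "singular")
})

test_that("unmodulated input has empty first-order bands", {
  om <- testOptical(64)
  sc <- makeScene("crossed_filaments", c(64, 64), list(n = 6), seed = 2)
  wf <- LockinSIM:::applyTransfer(sceneTruth(sc), otf(om))
  bands <- separateBands(rep(list(wf), 3), c(0, 2, 4) * pi / 3)
  e0 <- sum(Mod(bands[[2]])^2)
  expect_lt(sum(Mod(bands[[3]])^2) / e0, 1e-20)
  # equispaced phases: zeroth band equals the FT of the phase-mean image
  sim <- filamentSim(64)
  fr <- frameGroup(sim$stack, 1)
  b <- separateBands(fr, c(0, 2, 4) * pi / 3)
  pm <- (fr[[1]] + fr[[2]] + fr[[3]]) / 3
  expect_lt(max(Mod(b[[2]] - stats::fft(pm))), 1e-8)
})

test_that("band shifting is exact, invertible and sub-pixel accurate", {
  set.seed(3)
  img <- matrix(rnorm(32^2), 32)
  spec <- stats::fft(img)
  # zero shift at upsample 1 is the identity
  expect_lt(max(Mod(shiftBand(spec, c(0, 0), 1L) - spec)), 1e-10)
  # shift then inverse shift on the same grid returns the original
  fwd <- shiftBand(spec, c(0.13, -0.07), 1L)
  back <- shiftBand(fwd, c(-0.13, 0.07), 1L)
  expect_lt(sqrt(mean(Mod(back - spec)^2)) / max(Mod(spec)), 1e-10)
  # a pure spatial harmonic moves to the shifted frequency
  g <- LockinSIM:::pixelGrids(32, 32)
  kp <- c(3 / 32, 5 / 32)
  harm <- cos(2 * pi * (kp[1] * g$y + kp[2] * g$x))
  sh <- shiftBand(stats::fft(harm), c(2 / 32, 1 / 32), 2L)
  amp <- Mod(sh)
  idx <- which(amp == max(amp), arr.ind = TRUE)[1, ]
  fy <- LockinSIM:::fftFreq(64) * 2
  expect_equal(c(fy[idx[1]], fy[idx[2]]), kp + c(2 / 32, 1 / 32),
               tolerance = 1e-9)
  # shifts beyond the padded Nyquist are rejected
  expect_error(shiftBand(spec, c(0.9, 0), 1L, maxContentK = 0.4), "Nyquist")
})

test_that("a single zeroth-order band reduces to Wiener deconvolution", {
  om <- testOptical(64)
  sc <- makeScene("crossed_filaments", c(64, 64), list(n = 6), seed = 2)
  wf <- LockinSIM:::applyTransfer(sceneTruth(sc), otf(om))
  params <- new("IlluminationParams",
                k0 = matrix(c(0.1, 0.1), 1, 2,
                            dimnames = list(NULL, c("ky", "kx"))),
                phases = matrix(c(0, 2, 4) * pi / 3, 1),
                m = 1e-6, quality = 0)
  st <- reconSettings(apodization = "none", upsample = 1L)
  # zero out the +-1 bands: only order 0 contributes (m ~ 0 weights)
  bands <- list(list(matrix(0i, 64, 64), stats::fft(wf), matrix(0i, 64, 64)))
  spec <- wienerCombine(bands, params, om, st)
  H <- otf(om)
  expected <- stats::fft(wf) * H / (H^2 + st@wienerW^2)
  expect_lt(max(Mod(spec - expected)), 1e-8)
})

test_that("the SR spectrum support is bounded by the extended cutoff", {
  sim <- filamentSim(64)
  params <- estimateIllumination(sim$stack)
  st <- reconSettings()
  kc <- cutoffFrequency(sim$optical)
  bandsShifted <- lapply(1:3, function(d) {
    bands <- separateBands(frameGroup(sim$stack, d),
                           patternPhases(params)[d, ])
    lapply(1:3, function(ni)
      shiftBand(bands[[ni]], -(ni - 2) * patternWaveVectors(params)[d, ],
                st@upsample, maxContentK = kc))
  })
  spec <- wienerCombine(bandsShifted, params, sim$optical, st)
  kr <- LockinSIM:::freqRadius(128, 128) * 2   # cycles per original px
  kmax <- kc + max(sqrt(rowSums(patternWaveVectors(params)^2)))
  expect_true(all(Mod(spec)[kr > kmax + 1e-9] == 0))
})

test_that("reconstruction contracts: frame count, determinism, linearity", {
  sim <- filamentSim(64)
  bad <- simRawStack(stackData(sim$stack)[, , , , 1:2, , , drop = FALSE],
                     sim$optical)
  expect_error(reconstructWiener(bad), "9 frames")
  params <- estimateIllumination(sim$stack)
  r1 <- reconstructWiener(sim$stack, params = params)
  r2 <- reconstructWiener(sim$stack, params = params)
  expect_identical(srImage(r1), srImage(r2))
  # unmodulated stack: the error from illumination estimation propagates
  wf <- LockinSIM:::applyTransfer(sceneTruth(sim$scene), otf(sim$optical))
  flat <- simRawStack(array(rep(wf, 9), c(1, 1, 1, 3, 3, 64, 64)),
                      sim$optical)
  flat@data <- aperm(array(wf, c(64, 64, 1, 1, 1, 3, 3)), c(3, 4, 5, 6, 7, 1, 2))
  expect_error(reconstructWiener(flat), "pattern not detected")
  # linearity: scaling the input scales the output
  scaled <- simRawStack(stackData(sim$stack) * 2.5, sim$optical)
  r3 <- reconstructWiener(scaled, params = params)
  expect_equal(srImage(r3), srImage(r1) * 2.5, tolerance = 1e-9)
})

test_that("lock-in and Wiener agree on background-free scenes and
           lock-in wins once background is injected", {
  sim <- filamentSim(128)
  params <- estimateIllumination(sim$stack)
  rw <- reconstructWiener(sim$stack, params = params)
  rl <- reconstructLockin(sim$stack, params = params)
  big <- sceneTruth(sim$scene)[rep(1:128, each = 2), rep(1:128, each = 2)]
  mask <- big > 0.2
  expect_gt(cor(srImage(rw)[mask], srImage(rl)[mask]), 0.95)
  # background-only stack reconstructs to (almost) nothing under lock-in
  empty <- makeScene("crossed_filaments", c(128, 128), list(n = 0), seed = 1)
  zero <- simRawStack(array(0, dim(stackData(sim$stack))), sim$optical)
  bgOnly <- injectBackground(zero, sim$widefield, 1)
  rwB <- reconstructWiener(bgOnly, params = params)
  rlB <- reconstructLockin(bgOnly, params = params)
  expect_lt(quantile(srImage(rlB), 0.99),
            0.05 * quantile(srImage(rwB), 0.99))
})

test_that("stack processing is plane-consistent and mean-matching works", {
  sim <- filamentSim(64)
  params <- estimateIllumination(sim$stack)
  single <- processStack(sim$stack, mode = "wiener", params = params)
  direct <- reconstructWiener(sim$stack, params = params)
  expect_equal(single$sr[1, 1, 1, , ], srImage(direct), tolerance = 1e-12)
  # three planes with means 10, 20, 40 -> equal output means
  d <- stackData(sim$stack)
  multi <- array(0, c(1, 1, 3, 3, 3, 64, 64))
  for (z in 1:3) multi[1, 1, z, , , , ] <- d[1, 1, 1, , , , ] * c(1, 2, 4)[z]
  stk <- simRawStack(multi, sim$optical)
  out <- processStack(stk, mode = "wiener", params = params,
                      settings = reconSettings(intensityCorrection = "mean_match"))
  means <- apply(out$sr, 3, mean)
  expect_lt(diff(range(means)) / mean(means), 1e-6)
})

test_that("resolution is extended beyond the widefield cutoff", {
  om <- testOptical(128)
  sc <- makeScene("beads", c(128, 128), list(n = 20, diameter_nm = 100,
                                             pixel_nm = 65), seed = 11)
  ill <- illuminationParams(om)
  sim <- renderSimRaw(sc, simulationRecipe(om, illum = ill, seed = 3))
  res <- reconstructLockin(sim$stack, params = ill)
  kc <- cutoffFrequency(om)
  kmax <- kc + sqrt(sum(patternWaveVectors(ill)[1, ]^2))
  spec <- Mod(stats::fft(srImage(res)))
  kr <- LockinSIM:::freqRadius(256, 256) * 2
  inExt <- spec[kr > kc * 1.05 & kr < kmax * 0.95]
  floorLevel <- stats::median(spec[kr > kmax * 1.1])
  expect_gt(stats::quantile(inExt, 0.9), 10 * max(floorLevel, 1e-300))
  # the widefield image has no such energy
  wspec <- Mod(stats::fft(sim$widefield))
  wkr <- LockinSIM:::freqRadius(128, 128)
  expect_lt(max(wspec[wkr > kc * 1.05 & wkr < 0.5]) / max(wspec), 1e-10)
})

test_that("the pipeline matches a literal direct-DFT reimplementation", {
  om <- testOptical(64)
  sc <- makeScene("crossed_filaments", c(64, 64), list(n = 6), seed = 2)
  ill <- illuminationParams(om)
  sim <- renderSimRaw(sc, simulationRecipe(om, illum = ill, seed = 7))
  frames <- lapply(1:3, function(a) frameGroup(sim$stack, a))
  k0 <- patternWaveVectors(ill)
  ph <- patternPhases(ill)
  m <- modulationDepths(ill)
  kc <- cutoffFrequency(om)
  for (mode in c(FALSE, TRUE)) {
    got <- if (mode)
      srImage(reconstructLockin(sim$stack, params = ill))
    else
      srImage(reconstructWiener(sim$stack, params = ill))
    want <- oracleReconstruct(frames, k0, ph, m, kc, lockin = mode)
    rms <- sqrt(mean((got - want)^2)) / max(want)
    expect_lt(rms, 1e-6)
  }
})
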