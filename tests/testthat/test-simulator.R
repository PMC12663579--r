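test_that("scenes are deterministic, normalized and correctly parameterized", {
  s1 <- makeScene("radial_lines", c(96, 96), list(n_spokes = 36), seed = 7)
  s2 <- makeScene("radial_lines", c(96, 96), list(n_spokes = 36), seed = 7)
  expect_identical(sceneTruth(s1), sceneTruth(s2))
  expect_equal(max(sceneTruth(s1)), 1)
  expect_true(all(sceneTruth(s1) >= 0))
  # empty filament scene is all zero
  s0 <- makeScene("crossed_filaments", c(64, 64), list(n = 0), seed = 1)
  expect_true(all(sceneTruth(s0) == 0))
  expect_error(makeScene("nonsense", c(64, 64)), "beads")
  # 100 nm beads at 65 nm pixels: an antialiased disk of radius ~0.77 px.
  # The support must stay within radius r + 1/2 px of the centroid and the
  # mass must straddle the continuous ramp-profile integral (pixel-grid
  # sampling and max-normalization move it by a bounded factor).
  sb <- makeScene("beads", c(128, 128), list(n = 1, diameter_nm = 100,
                                             pixel_nm = 65), seed = 2)
  tr <- sceneTruth(sb)
  idx <- which(tr > 0, arr.ind = TRUE)
  ctr <- colSums(idx * tr[idx]) / sum(tr[idx])
  r <- 100 / 2 / 65
  expect_true(all(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= r + 0.5 + 0.75))
  s <- seq(0, r + 0.5, by = 1e-4)
  oracleMass <- sum(2 * pi * s * pmin(pmax(r + 0.5 - s, 0), 1)) * 1e-4
  expect_gt(sum(tr), 0.6 * oracleMass)
  expect_lt(sum(tr), 1.8 * oracleMass)
})

test_that("raw rendering follows the modulated-illumination image model", {
  om <- testOptical(64)
  ill <- illuminationParams(om)
  # uniform scene: equispaced phase mean cancels the modulation exactly
  tr <- array(1, c(64, 64))
  sc <- new("SyntheticScene", kind = "beads", truth = tr, params = list(),
            seed = 1L)
  rec <- simulationRecipe(om, illum = ill, noiseSd = 0, seed = 1)
  sim <- renderSimRaw(sc, rec)
  fr <- frameGroup(sim$stack, 1)
  pm <- (fr[[1]] + fr[[2]] + fr[[3]]) / 3
  expect_lt(max(abs(pm - sim$widefield)), 1e-10)
  expect_lt(max(abs(pm - 1)), 1e-10)
  # m = 0 (contrast -> 0 limit via m): all frames equal the widefield
  ill0 <- illuminationParams(om, m = 1e-6)
  sim0 <- renderSimRaw(sc, simulationRecipe(om, illum = ill0, seed = 1))
  for (j in 1:3)
    expect_lt(max(abs(frameGroup(sim0$stack, 2)[[j]] - sim0$widefield)), 1e-5)
})

test_that("the simulated spectrum carries symmetric pattern peaks at +-k0", {
  om <- testOptical(128)
  ill <- illuminationParams(om, m = 0.9)
  sc <- makeScene("crossed_filaments", c(128, 128), list(n = 8), seed = 5)
  sim <- renderSimRaw(sc, simulationRecipe(om, illum = ill,
                                           noiseSd = 0.002, seed = 9))
  # remove the widefield (zeroth) content, then locate the peak
  fr <- frameGroup(sim$stack, 1)
  resid <- fr[[1]] - (fr[[1]] + fr[[2]] + fr[[3]]) / 3
  amp <- Mod(stats::fft(resid))
  kr <- LockinSIM:::freqRadius(128, 128)
  amp[kr < 0.05] <- 0
  idx <- which(amp == max(amp), arr.ind = TRUE)[1, ]
  fy <- LockinSIM:::fftFreq(128)
  kpk <- c(fy[idx[1]], fy[idx[2]])
  k0 <- patternWaveVectors(ill)[1, ]
  expect_lt(min(sqrt(sum((kpk - k0)^2)), sqrt(sum((kpk + k0)^2))), 0.02)
  # and the mirrored peak is present with comparable strength
  iy2 <- which.min(abs(fy + kpk[1])); ix2 <- which.min(abs(fy + kpk[2]))
  expect_gt(amp[iy2, ix2], 0.5 * max(amp))
})

test_that("background injection is linear and energy-monotone", {
  sim <- filamentSim(64)
  b0 <- injectBackground(sim$stack, sim$widefield, 0)
  expect_identical(stackData(b0), stackData(sim$stack))
  zero <- simRawStack(array(0, dim(stackData(sim$stack))), sim$optical)
  b1 <- injectBackground(zero, sim$widefield, 1)
  blurred <- LockinSIM:::applyTransfer(sim$widefield, otf(sim$optical))
  expect_equal(stackData(b1)[1, 1, 1, 2, 3, , ], blurred, tolerance = 1e-12)
  b2 <- injectBackground(zero, sim$widefield, 2)
  expect_equal(mean(stackData(b2)), 2 * mean(stackData(b1)), tolerance = 1e-12)
  expect_error(injectBackground(sim$stack, sim$widefield, -1), ">= 0")
  # frame mean non-decreasing in level
  means <- vapply(c(0, 0.5, 1, 2), function(L)
    mean(stackData(injectBackground(sim$stack, sim$widefield, L))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("volume rendering reduces to the planar model in focus and
           loses modulation at depth", {
  om <- testOptical(64)
  ill <- illuminationParams(om)
  rec <- simulationRecipe(om, illum = ill, noiseSd = 0, seed = 4)
  sc2 <- makeScene("crossed_filaments", c(64, 64), list(n = 5), seed = 8)
  sc3 <- new("SyntheticScene", kind = "volume_filaments",
             truth = array(sceneTruth(sc2), c(1, 64, 64)),
             params = list(), seed = 8L)
  vol <- renderVolumeStack(sc3, rec, zPlanesUm = 0, sceneZStepUm = 0.6)
  flat <- renderSimRaw(sc2, rec)
  expect_equal(stackData(vol$stack)[1, 1, 1, , , , ],
               stackData(flat$stack)[1, 1, 1, , , , ], tolerance = 1e-10)
  # a plane far beyond the modulation envelope contributes unmodulated light
  volFar <- renderVolumeStack(sc3, rec, zPlanesUm = 5 * 0.6,
                              sceneZStepUm = 0.6, zmUm = 0.6)
  fr <- lapply(1:3, function(j) stackData(volFar$stack)[1, 1, 1, 1, j, , ])
  expect_lt(max(abs(fr[[1]] - fr[[2]])), 1e-6 * max(fr[[1]]))
  expect_error(renderVolumeStack(sc3, rec, zPlanesUm = numeric(0)),
               "non-empty")
})
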