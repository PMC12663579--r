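test_that("SBR reproduces the closed-form definition and its invariances", {
  set.seed(41)
  img <- matrix(rnorm(64^2, 10, 2), 64, 64)
  mask <- matrix(FALSE, 64, 64)
  mask[30:34, 30:34] <- TRUE
  img[32, 32] <- 100
  rep1 <- sbr(img, mask = mask)
  # 10 log10((max - mean(bg)) / sd(bg)) recomputable from the report
  expect_equal(rep1$sbr_db,
               10 * log10((rep1$signal_max - rep1$background_mean) /
                            rep1$background_sd), tolerance = 1e-12)
  expect_equal(rep1$sbr_db,
               10 * log10((100 - mean(img[!mask])) / sd(img[!mask])),
               tolerance = 1e-12)
  # constructed example: max 100, bg mean ~10 sd ~2 -> ~16.5 dB
  expect_equal(rep1$sbr_db, 10 * log10(90 / 2), tolerance = 0.05 * 16.5)
  # affine invariance a*I + c
  rep2 <- sbr(3 * img + 7, mask = mask)
  expect_equal(rep2$sbr_db, rep1$sbr_db, tolerance = 1e-10)
  # degenerate background and negative numerator handling
  expect_error(sbr(matrix(c(rep(1, 200), 5), 201, 1), mask = matrix(c(rep(FALSE, 200), TRUE), 201, 1)),
               "degenerate")
  dark <- img; dark[mask] <- 0
  expect_identical(sbr(dark, mask = mask)$sbr_db, -Inf)
  tiny <- matrix(1, 5, 5)
  expect_error(sbr(tiny, mask = tiny > 0.5), "100")
})

test_that("local SBR maps track spatial background structure", {
  set.seed(42)
  base <- matrix(rnorm(96^2, 5, 1), 96, 96)
  spots <- matrix(0, 96, 96)
  ys <- seq(8, 88, by = 16)
  for (y in ys) for (x in ys) spots[y, x] <- 60
  # uniform field: map constant within sampling error
  m1 <- localSBR(base + spots, 32, stride = 32)
  expect_identical(dim(m1), c(3L, 3L))
  expect_lt(diff(range(m1, na.rm = TRUE)), 6)
  # gradient confined to the left half lowers left-half SBR
  grad <- base + spots
  grad[, 1:48] <- grad[, 1:48] + matrix(seq(20, 0, length.out = 48),
                                        96, 48, byrow = TRUE)
  m2 <- localSBR(grad, 32, stride = 32)
  expect_lt(median(m2[, 1], na.rm = TRUE), median(m2[, 3], na.rm = TRUE))
  # non-overlapping tiling count
  expect_identical(dim(localSBR(base + spots, 24, stride = 24)), c(4L, 4L))
  expect_error(localSBR(base, 128), "larger")
  expect_error(localSBR(base, 8), ">= 16")
})

test_that("FWHM measurements match closed forms and the model PSF", {
  # Gaussian spot sigma = 2 px at 65 nm: FWHM = 2.3548 * 2 * 65
  g <- LockinSIM:::pixelGrids(64, 64)
  spot <- exp(-((g$y - 32)^2 + (g$x - 32)^2) / (2 * 2^2))
  expect_equal(fwhm(spot, c(32, 32), 0, 65), 2.354820045 * 2 * 65,
               tolerance = 0.02)
  expect_equal(fwhm(spot, c(32, 32), 0, 65), fwhm(spot, c(32, 32), 90, 65),
               tolerance = 0.02)
  # diagonal profiles cross bilinear cells obliquely: slightly looser
  expect_equal(fwhm(spot, c(32, 32), 37, 65), fwhm(spot, c(32, 32), 0, 65),
               tolerance = 0.03)
  # widefield-rendered 100 nm bead vs the PSF grid measured directly
  om <- testOptical(128)
  sc <- makeScene("beads", c(128, 128), list(n = 1, diameter_nm = 100,
                                             pixel_nm = 65), seed = 6)
  wf <- LockinSIM:::applyTransfer(sceneTruth(sc), otf(om))
  ctr <- which(wf == max(wf), arr.ind = TRUE)[1, ] - 1
  beadF <- mean(c(fwhm(wf, ctr, 0, 65), fwhm(wf, ctr, 90, 65)))
  p <- psf(om)
  pctr <- which(p == max(p), arr.ind = TRUE)[1, ] - 1
  psfF <- mean(c(fwhm(p, pctr, 0, 65), fwhm(p, pctr, 90, 65)))
  expect_lt(abs(beadF - psfF) / psfF, 0.15)
  expect_error(fwhm(matrix(0, 32, 32), c(16, 16)), "maximum")
})

test_that("radial spectra resolve the OTF support", {
  set.seed(7)
  noise <- matrix(rnorm(128^2), 128, 128)
  rs <- radialSpectrum(noise)
  # white noise: flat profile within sampling error
  expect_lt(diff(range(rs$logAmplitude[-1])), 0.5)
  # widefield image: estimated cutoff at (or just past) the OTF support
  om <- testOptical(128)
  sc <- makeScene("crossed_filaments", c(128, 128), list(n = 10), seed = 3)
  wf <- LockinSIM:::applyTransfer(sceneTruth(sc), otf(om))
  rsw <- radialSpectrum(wf)
  kc <- cutoffFrequency(om)
  expect_lt(rsw$cutoff, kc + 2 / 128)
  expect_gt(rsw$cutoff, 0.5 * kc)
  # lock-in SR of a noiseless simulation cuts off beyond the widefield
  ill <- illuminationParams(om)
  sim <- renderSimRaw(sc, simulationRecipe(om, illum = ill, seed = 2))
  sr <- srImage(reconstructLockin(sim$stack, params = ill))
  rss <- radialSpectrum(sr)
  expect_gt(rss$cutoff * 2, rsw$cutoff)   # SR k in cycles per fine px
})

test_that("intensity profiles sample the image as documented", {
  img <- matrix(7, 32, 32)
  pr <- intensityProfile(img, c(5, 2), c(5, 29), nSamples = 28)
  expect_true(all(pr$intensity == 7))
  # axis-aligned integer sampling returns the pixel row
  img2 <- matrix(seq_len(32 * 32), 32, 32)
  pr2 <- intensityProfile(img2, c(10, 4), c(10, 14), nSamples = 11)
  expect_equal(pr2$intensity, img2[11, 5:15], tolerance = 1e-12)
  # two Gaussian spots 4 sigma apart: two maxima, one interior minimum
  g <- LockinSIM:::pixelGrids(64, 64)
  two <- exp(-((g$y - 32)^2 + (g$x - 28)^2) / 8) +
    exp(-((g$y - 32)^2 + (g$x - 36)^2) / 8)
  pr3 <- intensityProfile(two, c(32, 20), c(32, 44), nSamples = 200)
  v <- pr3$intensity
  locmax <- which(diff(sign(diff(v))) < 0) + 1
  expect_identical(length(locmax), 2L)
  mid <- v[seq(locmax[1], locmax[2])]
  expect_lt(min(mid), min(v[locmax]) - 1e-6)
  expect_error(intensityProfile(img, c(3, 3), c(3, 3)), "zero-length")
  expect_error(intensityProfile(img, c(-2, 3), c(3, 3)), "inside")
})
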