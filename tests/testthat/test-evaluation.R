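test_that("CSF segmentation thresholds the HF map", {
  s <- ScalarVolume(array(c(2.19, 0.37, NA, 2.0), c(4, 1, 1)))
  m <- csfMaskFromSigma(s)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, TRUE))
  # monotone in the threshold: higher threshold gives a subset
  s2 <- ScalarVolume(array(runif(125, 0, 3), c(5, 5, 5)))
  m1 <- csfMaskFromSigma(s2, 1.5)
  m2 <- csfMaskFromSigma(s2, 2.5)
  expect_true(all(m1[m2]))
  # phantom CSF is recovered exactly with noise off
  run <- noiseFreePhantomRun()
  expect_identical(run$csf, run$labels == 3L)
})

test_that("tissue statistics: mean, population std, CV", {
  x <- ScalarVolume(array(c(0.3, 0.5, 1, 1), c(4, 1, 1)))
  masks <- list(A = array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1)),
                B = array(c(FALSE, FALSE, TRUE, TRUE), c(4, 1, 1)))
  td <- tissueDistributions(x, masks)
  a <- td$stats[td$stats$tissue == "A", ]
  expect_equal(a$mean, 0.4)
  expect_equal(a$std, 0.1)          # population, not sample
  expect_equal(a$cv, 25)
  b <- td$stats[td$stats$tissue == "B", ]
  expect_equal(b$std, 0)
  expect_equal(b$cv, 0)
  # overlapping masks and empty masks are rejected
  expect_error(tissueDistributions(x, list(A = masks$A, B = masks$A)),
               "disjoint")
  expect_error(tissueDistributions(x, list(A = array(FALSE, c(4, 1, 1)))),
               "empty")
})

test_that("CJV is the signed GM-WM overlap measure", {
  gm <- list(mean = 0.55, std = 0.17)
  wm <- list(mean = 0.30, std = 0.05)
  expect_equal(cjv(gm, wm), 88, tolerance = 1e-12)
  expect_equal(cjv(wm, gm), -88, tolerance = 1e-12)
  expect_equal(cjv(list(mean = 1, std = 0), list(mean = 0.2, std = 0)), 0)
  expect_error(cjv(gm, gm), "equal")
})

test_that("CV and CJV are scale invariant", {
  run <- noiseFreePhantomRun()
  x <- voxelData(run$sigmaLfIso)
  masks <- list(GM = run$labels == 1L, WM = run$labels == 2L)
  t1 <- tissueDistributions(run$sigmaLfIso, masks)$stats
  t2 <- tissueDistributions(
    ScalarVolume(x * 3.7, spacing = voxelSpacing(run$sigmaLfIso)),
    masks)$stats
  expect_equal(t1$cv, t2$cv, tolerance = 1e-9)
  c1 <- cjv(t1[t1$tissue == "GM", ], t1[t1$tissue == "WM", ])
  c2 <- cjv(t2[t2$tissue == "GM", ], t2[t2$tissue == "WM", ])
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("PSD profile resolves a planted sinusoid and floors constants", {
  d <- c(8, 64, 8)
  sp <- c(1, 1, 1)
  f0 <- 0.25          # cycles/mm
  line <- sin(2 * pi * f0 * (0:(d[2] - 1)))
  a <- array(rep(line, each = d[1]), d)
  p <- psdProfile(ScalarVolume(a, spacing = sp), axis = 2)
  expect_equal(p$freq[which.max(p$powerDb)], f0, tolerance = 1e-9)
  # constant volume: all non-DC power at the floor
  pc <- psdProfile(ScalarVolume(array(1, d), spacing = sp), axis = 2)
  expect_true(all(pc$powerDb == -120))
  # DC bin removed: frequencies start above zero
  expect_gt(min(p$freq), 0)
  expect_error(psdProfile(ScalarVolume(array(1, c(4, 4, 4)))), "usable")
})

test_that("white-noise periodogram is flat within Monte-Carlo tolerance", {
  set.seed(99)
  a <- array(rnorm(32 * 64 * 32), c(32, 64, 32))
  p <- psdProfile(ScalarVolume(a), axis = 2)
  # average over 1024 lines: spread of the log-spectrum is small
  expect_lt(diff(range(p$powerDb)), 1.5)
})

test_that("down/up-sampling attenuates supra-Nyquist content only", {
  d <- c(48, 48, 4)
  x <- array(0, d)
  # 0.45 cycles/mm sits above the 2 mm Nyquist (0.25) and aliases to
  # 0.05 under 2 mm sampling, well away from the 0.1 reference tone
  hi <- sin(2 * pi * 0.45 * (0:(d[1] - 1)))
  lo <- sin(2 * pi * 0.1 * (0:(d[1] - 1)))
  for (j in 1:d[2]) for (k in 1:d[3]) x[, j, k] <- hi + lo
  v <- ScalarVolume(x, spacing = c(1, 1, 1))
  r <- resampleResolutionReference(v, 2)
  p0 <- psdProfile(v, axis = 1)
  p2 <- psdProfile(r, axis = 1)
  iHi <- which.min(abs(p0$freq - 0.45))
  iLo <- which.min(abs(p0$freq - 0.1))
  expect_lt(p2$powerDb[iHi], p0$powerDb[iHi] - 10)   # strong attenuation
  expect_lt(abs(p2$powerDb[iLo] - p0$powerDb[iLo]), 3)
  # identity at native spacing and on constants
  rId <- resampleResolutionReference(v, 1)
  expect_equal(voxelData(rId), x, tolerance = 1e-12)
  cst <- ScalarVolume(array(2, d))
  expect_equal(voxelData(resampleResolutionReference(cst, 2)),
               array(2, d), tolerance = 1e-12)
  expect_error(resampleResolutionReference(v, 0.5), "finer")
})
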