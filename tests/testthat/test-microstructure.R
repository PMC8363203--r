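test_that("direction average is the arithmetic mean over a shell", {
  # three directions holding 1, 2, 3 -> mean 2
  d <- array(0, c(2, 2, 2, 4))
  d[, , , 1] <- 10                     # b = 0
  d[, , , 2] <- 1; d[, , , 3] <- 2; d[, , , 4] <- 3
  g <- fibonacciDirections(3)
  dwi <- DwiSeries(d, GradientTable(c(0, 1000, 1000, 1000),
                                    cbind(c(0, 0, 0), g)))
  expect_true(all(voxelData(directionAverage(dwi, 1000)) == 2))
  expect_true(all(voxelData(directionAverage(dwi, 1000, subset = 2:3)) == 2.5))
  expect_error(directionAverage(dwi, 1000, subset = integer(0)), "subset")
  expect_error(directionAverage(dwi, 500), "shell")
})

test_that("predicted signal matches the printed compartment model", {
  # direct evaluation of the three-term sum
  expect_equal(predictSignal(1000, 0.5, 0.2, 1e-3),
               0.8 * (0.5 * exp(-0.85) + 0.5 * exp(-0.5)) + 0.2 * exp(-3),
               tolerance = 1e-15)
  expect_equal(predictSignal(1000, 0.5, 0.2, 1e-3), 0.4235357,
               tolerance = 1e-6)
  expect_equal(predictSignal(1000, 0, 1, 0), exp(-3), tolerance = 1e-15)
})

test_that("signal model is normalised at b = 0 and decays with b", {
  set.seed(101)
  for (i in 1:200) {
    p <- c(runif(1), runif(1), runif(1, 0, 4e-3))
    expect_equal(predictSignal(0, p[1], p[2], p[3]), 1, tolerance = 1e-14)
  }
  # strictly decreasing in b for valid parameters with d_e* > 0
  b <- seq(0, 5000, by = 100)
  for (i in 1:20) {
    p <- c(runif(1, 0.01, 0.99), runif(1, 0.01, 0.99), runif(1, 1e-4, 3e-3))
    s <- predictSignal(b, p[1], p[2], p[3])
    expect_true(all(diff(s) < 0))
  }
})

test_that("voxel fit recovers noise-free parameters", {
  b <- c(50, 150, 1000, 1800, 4500)
  for (p in list(c(0.4, 0.2, 1.2e-3), c(0.6, 0.2, 0.8e-3),
                 c(0.9, 0.05, 2.5e-3))) {
    s <- predictSignal(b, p[1], p[2], p[3])
    f <- fitVoxel(s, b, 1)
    expect_true(f$converged)
    expect_equal(f$vIc, p[1], tolerance = 1e-3)
    expect_equal(f$vIso, p[2], tolerance = 1e-3)
    expect_equal(f$dEStar, p[3], tolerance = 0.05 * p[3])
  }
})

test_that("pure free-water signals collapse to the CSF limit", {
  b <- c(50, 150, 1000, 1800, 4500)
  f <- fitVoxel(exp(-b * 3e-3), b, 1)
  # the fit must reproduce the signals and the derived parameters of the
  # free-water limit (the model has an exact ridge at v_ic = 0,
  # d_e* = d_iso where v_iso is unidentifiable, so only derived
  # quantities are contractual)
  expect_lt(f$objective, 1e-18)
  chi <- (1 - f$vIso) * (1 - f$vIc) + f$vIso
  de <- ((1 - f$vIso) * (1 - f$vIc)^2 * f$dEStar + f$vIso * 3e-3) / chi
  expect_equal(chi, 1, tolerance = 1e-6)
  expect_equal(de, 3e-3, tolerance = 1e-8)
})

test_that("voxel fit validates its inputs", {
  b <- c(50, 150, 1000, 1800, 4500)
  s <- predictSignal(b, 0.5, 0.2, 1e-3)
  expect_error(fitVoxel(c(s[-1], NaN), b, 1), "non-finite")
  expect_error(fitVoxel(s, b, 0), "s0")
  expect_error(fitVoxel(s[1:2], b[1:2], 1), "shells")
})

test_that("leave-one-out MIP enumerates all subsets and dominates runs", {
  spec <- phantomSpec()
  dwi <- simulateDwi(spec, mode = "spherical")
  lab <- voxelData(makeDefaultPhantom(spec))
  # restrict to a handful of voxels to keep the enumeration check light
  mask <- array(FALSE, dim(lab))
  mask[which(lab == 2L)[1:3]] <- TRUE
  mask[which(lab == 1L)[1:3]] <- TRUE
  fit <- fitLooMip(dwi, mask = mask, keepRuns = TRUE)
  expect_identical(fit$report$nRuns, 16L)
  expect_length(fit$runs, 16L)
  # noise-free: all runs identical, MIP equals any single run
  for (nm in c("vIc", "vIso", "dEStar")) {
    final <- voxelData(fit[[nm]])[mask]
    for (r in fit$runs)
      expect_equal(r[[nm]][mask], final, tolerance = 1e-12)
  }
})

test_that("MIP is the voxelwise maximum over the runs", {
  # noisy case: runs differ, the final map must dominate each of them
  spec <- phantomSpec(noiseModel = "rician", noiseSigma = 2.5, seed = 5L)
  dwi <- simulateDwi(spec, mode = "spherical")
  lab <- voxelData(makeDefaultPhantom(spec))
  mask <- array(FALSE, dim(lab))
  mask[which(lab > 0)[seq(1, 1000, by = 97)]] <- TRUE
  fit <- fitLooMip(dwi, mask = mask, keepRuns = TRUE)
  runsDiffer <- FALSE
  for (nm in c("vIc", "vIso", "dEStar")) {
    final <- voxelData(fit[[nm]])[mask]
    for (r in fit$runs) {
      expect_true(all(final - r[[nm]][mask] >= -1e-12))
      if (any(abs(final - r[[nm]][mask]) > 1e-9)) runsDiffer <- TRUE
    }
  }
  expect_true(runsDiffer)
})

test_that("derived LF parameters follow their closed forms", {
  mkv <- function(x) ScalarVolume(array(x, c(1, 1, 1)))
  # CSF limit: v_iso = 1
  lf <- deriveLfParams(mkv(0.3), mkv(1), mkv(1e-3))
  expect_equal(voxelData(lf$chiE)[1], 1)
  expect_equal(voxelData(lf$dE)[1], 3e-3)
  expect_equal(voxelData(lf$dI)[1], 0.3 * 1.7e-3)
  # pure extracellular: v_iso = v_ic = 0
  lf2 <- deriveLfParams(mkv(0), mkv(0), mkv(1.1e-3))
  expect_equal(voxelData(lf2$chiE)[1], 1)
  expect_equal(voxelData(lf2$dE)[1], 1.1e-3)
  # generic point
  lf3 <- deriveLfParams(mkv(0.5), mkv(0.2), mkv(1e-3))
  expect_equal(voxelData(lf3$chiE)[1], 0.6, tolerance = 1e-12)
  expect_equal(voxelData(lf3$dE)[1], (0.8 * 0.25 * 1e-3 + 0.2 * 3e-3) / 0.6,
               tolerance = 1e-12)
  expect_equal(voxelData(lf3$dE)[1], 1.333333e-3, tolerance = 1e-6)
  expect_equal(voxelData(lf3$dI)[1], 8.5e-4, tolerance = 1e-12)
  # degenerate chi_e = 0
  lf4 <- deriveLfParams(mkv(1), mkv(0), mkv(1e-3))
  expect_true(is.na(voxelData(lf4$dE)[1]))
  expect_identical(lf4$dE@metadata$nUndefined, 1L)
})
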