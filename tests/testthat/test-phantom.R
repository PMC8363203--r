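test_that("default phantom geometry is deterministic and complete", {
  spec <- phantomSpec()
  lab1 <- voxelData(makeDefaultPhantom(spec))
  lab2 <- voxelData(makeDefaultPhantom(spec))
  expect_identical(lab1, lab2)
  expect_setequal(unique(as.vector(lab1)), c(0L, 1L, 2L, 3L))
  # counts are fixed for the default 32^3 spec
  expect_identical(dim(lab1), c(32L, 32L, 32L))
  expect_gt(sum(lab1 == 1L), 0)
  expect_gt(sum(lab1 == 2L), 0)
  expect_gt(sum(lab1 == 3L), 0)
})

test_that("too-small grids are rejected", {
  expect_error(phantomSpec(gridShape = c(8L, 8L, 8L)), ">= 16")
})

test_that("spin-echo simulator follows saturation recovery", {
  # near-zero T1 saturates both images: ratio -> 1
  tis <- defaultTissueParams()
  tis$T1 <- rep(1e-6, 3)
  spec <- phantomSpec(tissues = tis)
  se <- simulateSePair(spec, mode = "relaxation")
  lab <- voxelData(makeDefaultPhantom(spec))
  expect_equal(voxelData(se$se1)[lab > 0], voxelData(se$se2)[lab > 0],
               tolerance = 1e-12)

  # WM-like T1 = 0.83 s at TR 0.7/3.0 s gives the known ratio
  spec2 <- phantomSpec()
  se2 <- simulateSePair(spec2, mode = "relaxation")
  lab2 <- voxelData(makeDefaultPhantom(spec2))
  wm1 <- voxelData(se2$se1)[lab2 == 2L][1]
  wm2 <- voxelData(se2$se2)[lab2 == 2L][1]
  expected <- (1 - exp(-0.7 / 0.83)) / (1 - exp(-3.0 / 0.83))
  expect_equal(wm1 / wm2, expected, tolerance = 1e-12)
  expect_equal(expected, 0.5855121, tolerance = 1e-6)
})

test_that("calibrated spin-echo mode round-trips the water target", {
  spec <- phantomSpec()
  se <- simulateSePair(spec, mode = "calibrated")
  lab <- voxelData(makeDefaultPhantom(spec))
  W <- waterFromRatio(imageRatio(se$se1, se$se2, lab > 0))
  for (k in 1:3)
    expect_equal(unique(voxelData(W)[lab == k]), spec@tissues$W[k],
                 tolerance = 1e-12)
  # out-of-range target is rejected
  tis <- defaultTissueParams()
  tis$W[3] <- 0.999  # still fine
  bad <- phantomSpec(tissues = tis)
  expect_silent(simulateSePair(bad, mode = "calibrated"))
})

test_that("spherical DWI equals the compartment model exactly", {
  spec <- phantomSpec()
  dwi <- simulateDwi(spec, mode = "spherical")
  lab <- voxelData(makeDefaultPhantom(spec))
  # b = 0 volume carries S0 everywhere in tissue
  expect_equal(voxelData(dwi)[, , , 1][lab > 0],
               dwi@metadata$truth$s0[lab > 0])
  # CSF (v_iso = 1) at b = 1000: S/S0 = exp(-3)
  i1000 <- which(bValues(dwi) == 1000)[1]
  csfSig <- voxelData(dwi)[, , , i1000][lab == 3L][1]
  s0 <- dwi@metadata$truth$s0[lab == 3L][1]
  expect_equal(csfSig / s0, exp(-3), tolerance = 1e-12)
  # direction average equals the forward model at every shell
  for (b in c(50, 150, 1000, 1800, 4500)) {
    sb <- voxelData(directionAverage(dwi, b))
    for (k in 1:3) {
      t <- spec@tissues[k, ]
      pred <- t$pd * predictSignal(b, t$v_ic, t$v_iso, t$d_e_star)
      expect_equal(unique(sb[lab == k]), pred, tolerance = 1e-12)
    }
  }
})

test_that("tensor-mode DWI is rotationally consistent", {
  spec <- phantomSpec()
  dwi <- simulateDwi(spec, mode = "tensor")
  lab <- voxelData(makeDefaultPhantom(spec))
  # isotropic tissues: identical signal on every direction of a shell
  idx <- which(bValues(dwi) == 1000)
  sig <- sapply(idx, function(j) voxelData(dwi)[, , , j][lab == 3L][1])
  expect_equal(max(sig) - min(sig), 0, tolerance = 1e-12)
  # WM is anisotropic: signals vary across directions
  sigWm <- sapply(idx, function(j) voxelData(dwi)[, , , j][lab == 2L][1])
  expect_gt(max(sigWm) - min(sigWm), 1e-3)
  expect_error(simulateDwi(spec, mode = "nonsense"))
})

test_that("noise models are seeded, reproducible and correctly scaled", {
  x <- array(0, c(12, 12, 12))
  expect_identical(addNoise(x, "gaussian", 0, seed = 1L), x)
  expect_error(addNoise(x, "gaussian", -1, seed = 1L), "sigma")
  n1 <- addNoise(x, "rician", 1, seed = 42L)
  n2 <- addNoise(x, "rician", 1, seed = 42L)
  expect_identical(n1, n2)
  # Rician magnitude of pure noise is Rayleigh: mean sigma sqrt(pi/2)
  big <- array(0, c(40, 40, 40))
  r <- addNoise(big, "rician", 2, seed = 3L)
  expect_equal(mean(r), 2 * sqrt(pi / 2), tolerance = 0.02)
  # gaussian keeps the mean
  g <- addNoise(big, "gaussian", 2, seed = 4L)
  expect_equal(mean(g), 0, tolerance = 0.02)
})

test_that("gradient tables validate direction norms and lengths", {
  gtab <- defaultGradientTable()
  expect_length(bValues(gtab), 1 + 5 * 16)
  nrm <- sqrt(colSums(bVectors(gtab)^2))
  expect_true(all(abs(nrm[bValues(gtab) > 0] - 1) < 1e-6))
  expect_error(GradientTable(c(0, 1000), matrix(c(0, 0, 0, 2, 0, 0), 3)),
               "unit norm")
  sh <- identifyShells(gtab)
  expect_equal(sh$b, c(0, 50, 150, 1000, 1800, 4500))
  expect_equal(sh$n, c(1L, rep(16L, 5)))
})

test_that("simulators are bit-reproducible under a fixed seed", {
  spec <- phantomSpec(noiseModel = "rician", noiseSigma = 2, seed = 11L)
  d1 <- simulateDwi(spec)
  d2 <- simulateDwi(spec)
  expect_identical(voxelData(d1), voxelData(d2))
  s1 <- simulateSePair(spec, noiseModel = "gaussian")
  s2 <- simulateSePair(spec, noiseModel = "gaussian")
  expect_identical(voxelData(s1$se1), voxelData(s2$se1))
})
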