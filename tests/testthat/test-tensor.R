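mkDwiFromTensor <- function(D, ndir = 12, s0 = 100) {
  g <- fibonacciDirections(ndir)
  b <- c(0, rep(1000, ndir))
  q <- colSums(g * (D %*% g))
  sig <- c(s0, s0 * exp(-1000 * q))
  d <- array(0, c(3, 3, 3, ndir + 1))
  for (j in seq_along(sig)) d[, , , j] <- sig[j]
  DwiSeries(d, GradientTable(b, cbind(c(0, 0, 0), g)))
}

test_that("WLS recovers isotropic and anisotropic tensors", {
  D <- diag(rep(1e-3, 3))
  tv <- fitDiffusionTensor(mkDwiFromTensor(D))
  six <- voxelData(tv)[2, 2, 2, ]
  expect_equal(six, c(1e-3, 1e-3, 1e-3, 0, 0, 0), tolerance = 1e-10)

  R <- qr.Q(qr(matrix(c(1, 2, 0, 0, 1, 3, 1, 0, 1), 3)))
  Da <- R %*% diag(c(1.8e-3, 0.6e-3, 0.4e-3)) %*% t(R)
  tva <- fitDiffusionTensor(mkDwiFromTensor(Da))
  got <- voxelData(tva)[2, 2, 2, ]
  expect_equal(got, c(Da[1, 1], Da[2, 2], Da[3, 3],
                      Da[1, 2], Da[1, 3], Da[2, 3]), tolerance = 1e-9)
})

test_that("tensor-mode phantom round-trips through the tensor fit", {
  run <- noiseFreePhantomRun()
  spec <- run$spec
  dwi <- simulateDwi(spec, mode = "tensor")
  lab <- voxelData(makeDefaultPhantom(spec))
  tv <- fitDiffusionTensor(dwi, mask = lab > 0)
  truth <- dwi@metadata$truth$tensor6
  for (k in 1:3) {
    sel <- which(lab == k)[1]
    for (c6 in 1:6) {
      est <- voxelData(tv)[, , , c6][sel]
      expect_equal(est, truth[, , , c6][sel], tolerance = 1e-9)
    }
  }
  # WM principal eigenvector aligns with the seeded fibre direction
  e <- tensorEigen(tv)
  sel <- which(lab == 2L)[1]
  d3 <- dim(lab)
  v1 <- sapply(1:3, function(r) e$vectors[, , , r, 1][sel])
  expect_equal(abs(sum(v1 * spec@wmOrientation)), 1, tolerance = 1e-6)
})

test_that("insufficient directions invalidate the tensor fit", {
  dwi <- mkDwiFromTensor(diag(rep(1e-3, 3)), ndir = 5)
  expect_error(fitDiffusionTensor(dwi), "6 directions")
})

test_that("eigendecomposition sorts, rotates and clamps correctly", {
  six <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  arr <- array(0, c(1, 1, 1, 6))
  arr[1, 1, 1, ] <- six(diag(c(3e-3, 1e-3, 2e-3)))
  e <- tensorEigen(TensorVolume(arr))
  expect_equal(e$values[1, 1, 1, ], c(3e-3, 2e-3, 1e-3), tolerance = 1e-15)

  R <- qr.Q(qr(matrix(c(2, 1, 1, 0, 1, 1, 0, 0, 1), 3)))
  M <- R %*% diag(c(3e-3, 2e-3, 1e-3)) %*% t(R)
  arr[1, 1, 1, ] <- six(M)
  e2 <- tensorEigen(TensorVolume(arr))
  expect_equal(e2$values[1, 1, 1, ], c(3e-3, 2e-3, 1e-3), tolerance = 1e-12)

  arr[1, 1, 1, ] <- six(diag(c(1e-3, 2e-3, -1e-6)))
  e3 <- tensorEigen(TensorVolume(arr))
  expect_equal(min(e3$values[1, 1, 1, ]), 0)
  expect_identical(e3$nClamped, 1L)
})

test_that("extracellular rescaling preserves eigenvectors and fixes the trace", {
  six <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  # eta = 1 when d_e equals the mean diffusivity
  arr <- array(0, c(1, 1, 1, 6)); arr[1, 1, 1, ] <- six(diag(rep(1e-3, 3)))
  De <- extracellularTensor(TensorVolume(arr),
                            ScalarVolume(array(1e-3, c(1, 1, 1))))
  expect_equal(voxelData(De)[1, 1, 1, ], arr[1, 1, 1, ], tolerance = 1e-15)
  # eta = 1.2 example
  De2 <- extracellularTensor(TensorVolume(arr),
                             ScalarVolume(array(1.2e-3, c(1, 1, 1))))
  expect_equal(voxelData(De2)[1, 1, 1, 1], 1.2e-3, tolerance = 1e-15)
  # trace identity on a random tensor field
  set.seed(22)
  n <- 6L
  arrR <- array(rnorm(n^3 * 6, sd = 1e-3), c(n, n, n, 6))
  arrR[, , , 1:3] <- abs(arrR[, , , 1:3]) + 1e-3
  deMap <- array(runif(n^3, 0.5e-3, 3e-3), c(n, n, n))
  DeR <- extracellularTensor(TensorVolume(arrR), ScalarVolume(deMap))
  tr <- voxelData(DeR)[, , , 1] + voxelData(DeR)[, , , 2] +
    voxelData(DeR)[, , , 3]
  expect_equal(tr, 3 * deMap, tolerance = 1e-12)
})

test_that("conductivity tensor follows the linear relation", {
  six <- diag(c(1, 1, 1))
  mkT <- function(d) {
    a <- array(0, c(1, 1, 1, 6)); a[1, 1, 1, ] <- c(d, d, d, 0, 0, 0)
    TensorVolume(a)
  }
  mkS <- function(x) ScalarVolume(array(x, c(1, 1, 1)))
  # pure-CSF limit: chi_e = 1, isotropic D_e -> C = sigma_HF I
  lf <- list(chiE = mkS(1), dE = mkS(3e-3), dI = mkS(0))
  C <- conductivityTensor(mkS(2.19), lf, mkT(3e-3))
  expect_equal(voxelData(C)[1, 1, 1, 1], 2.19, tolerance = 1e-12)
  # generic GM-like point
  lf2 <- list(chiE = mkS(0.6), dE = mkS(1.333333e-3), dI = mkS(8.5e-4))
  C2 <- conductivityTensor(mkS(0.37), lf2, mkT(1.333333e-3))
  expect_equal(voxelData(C2)[1, 1, 1, 1], 0.3150947, tolerance = 1e-4)
  # linearity in sigma_HF
  C3 <- conductivityTensor(mkS(0), lf2, mkT(1.333333e-3))
  expect_equal(voxelData(C3)[1, 1, 1, 1], 0)
})

test_that("isotropic equivalent is the eigenvalue geometric mean", {
  mk <- function(v, rotate = FALSE) {
    M <- diag(v)
    if (rotate) {
      R <- qr.Q(qr(matrix(rnorm(9), 3)))
      M <- R %*% M %*% t(R)
    }
    a <- array(0, c(1, 1, 1, 6))
    a[1, 1, 1, ] <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    TensorVolume(a)
  }
  expect_equal(voxelData(isotropicEquivalent(mk(c(0.7, 0.7, 0.7))))[1], 0.7,
               tolerance = 1e-12)
  expect_equal(voxelData(isotropicEquivalent(mk(c(0.1, 0.2, 0.4))))[1], 0.2,
               tolerance = 1e-12)
  expect_equal(voxelData(isotropicEquivalent(mk(c(0.5, 0.3, 0))))[1], 0,
               tolerance = 1e-12)
  # rotation invariance
  set.seed(31)
  for (i in 1:10) {
    v <- runif(3, 0.1, 2)
    expect_equal(voxelData(isotropicEquivalent(mk(v, rotate = TRUE)))[1],
                 prod(v)^(1 / 3), tolerance = 1e-10)
  }
})
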