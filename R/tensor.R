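## Diffusion tensor estimation at b = 1000, extracellular rescaling and
## conductivity tensor assembly.

#' Ratio of intra- to extracellular ion concentrations
#'
#' The fixed scalar beta = 0.41 entering the conductivity tensor
#' relation; measured with microelectrodes in the literature, not
#' estimable from MRI.
#'
#' @param beta dimensionless ratio in (0, 1]
#' @return classed list
#' @export
ctiConstants <- function(beta = 0.41) {
  stopifnot(beta > 0, beta <= 1)
  structure(list(beta = beta), class = "ctiConstants")
}

#' Fit the diffusion tensor on one shell
#'
#' Per-voxel weighted log-linear least squares of
#' ln(S/S0) = -b g' D g on the requested shell (default b = 1000 s/mm^2,
#' the only shell used for the tensor), with one reweighting pass using
#' the squared predicted signals as weights. Non-positive signals are
#' floored at a small epsilon and counted.
#'
#' @param dwi a [DwiSeries-class] with a b = 0 volume and >= 6 directions
#'   on the requested shell
#' @param shell nominal b-value (s/mm^2), default 1000
#' @param mask optional logical array / ScalarVolume
#' @return [TensorVolume-class] D; metadata counts `nFloored` signal
#'   floors
#' @export
fitDiffusionTensor <- function(dwi, shell = 1000, mask = NULL) {
  idx <- shellIndices(gradients(dwi), shell)
  if (length(idx) < 6L)
    stop("need at least 6 directions on the tensor shell")
  b <- bValues(dwi)[idx]
  g <- bVectors(dwi)[, idx, drop = FALSE]
  # design: ln(S/S0) = -X d, columns (xx, yy, zz, xy, xz, yz)
  X <- cbind(b * g[1, ]^2, b * g[2, ]^2, b * g[3, ]^2,
             2 * b * g[1, ] * g[2, ], 2 * b * g[1, ] * g[3, ],
             2 * b * g[2, ] * g[3, ])
  d3 <- dim(dwi)[1:3]
  m <- resolveMask(mask, d3)
  s0 <- s0Volume(dwi)
  m <- m & is.finite(s0) & s0 > 0
  vox <- which(m)
  nv <- length(vox)
  dat <- voxelData(dwi)
  S <- matrix(0, length(idx), nv)
  for (jj in seq_along(idx)) S[jj, ] <- dat[, , , idx[jj]][vox]
  eps <- 1e-10
  nFloored <- sum(S <= 0)
  S[S <= 0] <- eps
  Y <- log(S / rep(s0[vox], each = length(idx)))   # nshell-dirs x nvox
  # OLS pass (shared design)
  XtX <- crossprod(X)
  D0 <- -solve(XtX, crossprod(X, Y))               # 6 x nvox
  # one reweighting pass: weights = squared predicted signals
  Yhat <- -X %*% D0
  W2 <- exp(2 * Yhat)
  D1 <- matrix(NA_real_, 6, nv)
  for (v in seq_len(nv)) {
    w <- W2[, v]
    Xw <- X * w
    D1[, v] <- tryCatch(-solve(crossprod(Xw, X), crossprod(Xw, Y[, v])),
                        error = function(e) D0[, v])
  }
  arr <- array(NA_real_, c(d3, 6))
  for (c6 in 1:6) {
    vol <- arr[, , , c6]
    vol[vox] <- D1[c6, ]
    arr[, , , c6] <- vol
  }
  TensorVolume(arr, spacing = dwi@spacing,
               metadata = list(nFloored = nFloored, shell = shell))
}

#' Eigendecomposition of a tensor field
#'
#' Real symmetric eigendecomposition per voxel (equivalent to SVD for
#' symmetric positive semi-definite tensors), eigenvalues sorted
#' descending. Negative eigenvalues are clamped to 0 and counted.
#'
#' @param tv a [TensorVolume-class]
#' @param clamp clamp negative eigenvalues to zero (default TRUE)
#' @return list with `values` (x, y, z, 3 array, descending),
#'   `vectors` (x, y, z, 3, 3 array; `[, , , , k]` is the k-th
#'   eigenvector field) and `nClamped`
#' @export
tensorEigen <- function(tv, clamp = TRUE) {
  a <- voxelData(tv)
  d3 <- dim(a)[1:3]
  vals <- array(NA_real_, c(d3, 3))
  vecs <- array(NA_real_, c(d3, 3, 3))
  comp <- matrix(a, ncol = 6)
  ok <- which(rowSums(!is.finite(comp)) == 0)
  nClamped <- 0L
  M <- matrix(0, 3, 3)
  n3 <- prod(d3)
  for (i in ok) {
    M[1, 1] <- comp[i, 1]; M[2, 2] <- comp[i, 2]; M[3, 3] <- comp[i, 3]
    M[1, 2] <- M[2, 1] <- comp[i, 4]
    M[1, 3] <- M[3, 1] <- comp[i, 5]
    M[2, 3] <- M[3, 2] <- comp[i, 6]
    e <- eigen(M, symmetric = TRUE)
    ev <- e$values
    if (clamp && any(ev < 0)) {
      nClamped <- nClamped + 1L
      ev <- pmax(ev, 0)
    }
    for (k in 1:3) {
      vals[i + (k - 1) * n3] <- ev[k]
      for (r in 1:3)
        vecs[i + (r - 1) * n3 + (k - 1) * 3 * n3] <- e$vectors[r, k]
    }
  }
  list(values = vals, vectors = vecs, nClamped = nClamped)
}

#' Rescale the diffusion tensor to the extracellular tensor
#'
#' D_e = eta D with eta = 3 d_e / (d_xx + d_yy + d_zz); the trace of D_e
#' therefore equals 3 d_e exactly. Voxels where trace(D) = 0 get
#' D_e = 0 and are counted.
#'
#' @param D a [TensorVolume-class] diffusion tensor (mm^2/s)
#' @param dE [ScalarVolume-class] extracellular diffusivity map (mm^2/s)
#' @return [TensorVolume-class] D_e; metadata counts `nZeroTrace`
#' @export
extracellularTensor <- function(D, dE) {
  a <- voxelData(D)
  de <- voxelData(dE)
  d3 <- dim(a)[1:3]
  if (!identical(d3, dim(de)))
    stop("volumes are not on the same grid")
  comp <- matrix(a, ncol = 6)
  tr <- array(comp[, 1] + comp[, 2] + comp[, 3], d3)
  eta <- 3 * de / tr
  zero <- is.finite(tr) & tr == 0
  eta[zero] <- 0
  out <- a * as.vector(eta)            # recycles eta over 6 components
  TensorVolume(out, spacing = D@spacing,
               metadata = list(nZeroTrace = sum(zero)))
}

#' Assemble the low-frequency conductivity tensor
#'
#' C_LF = \[chi_e sigma_HF / (chi_e d_e + (1 - chi_e) d_i beta)\] D_e per
#' voxel. Undefined inputs propagate; zero denominators are counted and
#' give undefined voxels.
#'
#' @param sigmaHf [ScalarVolume-class] HF conductivity (S/m)
#' @param lf list with `chiE`, `dE`, `dI` maps ([deriveLfParams])
#' @param De [TensorVolume-class] extracellular tensor (mm^2/s)
#' @param const [ctiConstants]
#' @return [TensorVolume-class] C_LF in S/m; metadata counts
#'   `nZeroDenominator`
#' @export
conductivityTensor <- function(sigmaHf, lf, De, const = ctiConstants()) {
  s <- voxelData(sigmaHf)
  chi <- voxelData(lf$chiE); de <- voxelData(lf$dE); di <- voxelData(lf$dI)
  stopIfGridMismatch(s, chi)
  den <- chi * de + (1 - chi) * di * const$beta
  zero <- is.finite(den) & den <= 0
  pref <- chi * s / den
  pref[zero] <- NA_real_
  out <- voxelData(De) * as.vector(pref)
  TensorVolume(out, spacing = De@spacing,
               metadata = list(nZeroDenominator = sum(zero)))
}

#' Isotropic-equivalent conductivity map
#'
#' The geometric mean of the tensor's eigenvalues per voxel,
#' c_iso = (c_xx c_yy c_zz)^(1/3): the conductivity of the isotropic
#' tensor whose ellipsoid volume matches the measured one. Negative
#' eigenvalues are clamped to 0 upstream, so any clamped voxel maps
#' to 0.
#'
#' @param C a [TensorVolume-class] conductivity tensor (S/m)
#' @return [ScalarVolume-class] sigma_LF_iso (S/m); metadata counts
#'   `nClamped`
#' @export
isotropicEquivalent <- function(C) {
  e <- tensorEigen(C, clamp = TRUE)
  d3 <- dim(voxelData(C))[1:3]
  v <- matrix(e$values, ncol = 3)
  iso <- array((v[, 1] * v[, 2] * v[, 3])^(1 / 3), d3)
  ScalarVolume(iso, spacing = C@spacing,
               metadata = list(nClamped = e$nClamped))
}

#' Principal-eigenvector RGB map
#'
#' |e1| componentwise, scaled by an optional anisotropy or scalar map;
#' standard directional colour coding for visual inspection.
#'
#' @param tv a [TensorVolume-class]
#' @param scale optional [ScalarVolume-class] multiplier (e.g. FA)
#' @return 4-D array (x, y, z, 3) with values in \[0, 1\]
#' @export
principalEigenvectorRgb <- function(tv, scale = NULL) {
  e <- tensorEigen(tv)
  rgb <- abs(e$vectors[, , , , 1])
  if (!is.null(scale)) rgb <- rgb * as.vector(voxelData(scale))
  pmin(pmax(rgb, 0), 1)
}
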