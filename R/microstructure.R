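## Direction-averaged three-compartment microstructure model: signal
## prediction, per-voxel fitting, leave-one-out MIP stabilisation and
## derived low-frequency parameters.

#' Fixed compartment diffusivities of the three-compartment model
#'
#' The intracellular diffusivity d_ic and the isotropic (free-water)
#' diffusivity d_iso are fixed a priori from the literature to stabilise
#' the fit; they are not estimated.
#'
#' @param d_ic intracellular diffusivity, mm^2/s (default 1.7e-3)
#' @param d_iso isotropic water diffusivity, mm^2/s (default 3e-3)
#' @return classed list of constants
#' @export
modelConstants <- function(d_ic = 1.7e-3, d_iso = 3e-3) {
  stopifnot(d_ic > 0, d_iso > 0)
  structure(list(d_ic = d_ic, d_iso = d_iso), class = "modelConstants")
}

#' Optimiser settings for the compartment fit
#'
#' Nelder-Mead on logit/softplus-transformed parameters; `tol` is the
#' relative spread tolerance on the objective, `maxit` the iteration cap
#' per descent and `restarts` the number of incumbent restarts used to
#' polish the minimum.
#'
#' @param tol objective tolerance (default 1e-10)
#' @param maxit maximum iterations per descent (default 2000)
#' @param restarts incumbent restarts (default 4)
#' @param init initial conditions (v_ic, v_iso, d_e* in mm^2/s);
#'   default (0, 0.5, 0)
#' @return classed list of settings
#' @export
fitControl <- function(tol = 1e-10, maxit = 2000L, restarts = 4L,
                       init = c(0, 0.5, 0)) {
  stopifnot(tol > 0, maxit >= 1, restarts >= 0, length(init) == 3L)
  structure(list(tol = tol, maxit = as.integer(maxit),
                 restarts = as.integer(restarts), init = init),
            class = "fitControl")
}

#' Predicted direction-averaged signal of the three-compartment model
#'
#' S_b / S_0 = (1 - v_iso) \[v_ic exp(-b v_ic d_ic) +
#' (1 - v_ic) exp(-b (1 - v_ic) d_e*)\] + v_iso exp(-b d_iso).
#' Vectorised over `b` and over parameter vectors of equal length.
#'
#' @param b b-value(s), s/mm^2
#' @param vIc intracellular volume fraction in \[0, 1\]
#' @param vIso isotropic volume fraction in \[0, 1\]
#' @param dEStar extracellular mean diffusivity, mm^2/s (>= 0)
#' @param const fixed diffusivities from [modelConstants]
#' @return normalised signal(s)
#' @export
predictSignal <- function(b, vIc, vIso, dEStar, const = modelConstants()) {
  (1 - vIso) * (vIc * exp(-b * vIc * const$d_ic) +
                (1 - vIc) * exp(-b * (1 - vIc) * dEStar)) +
    vIso * exp(-b * const$d_iso)
}

#' Direction average of one shell
#'
#' Arithmetic mean over the (optionally subset) gradient directions of a
#' shell, per voxel.
#'
#' @param dwi a [DwiSeries-class]
#' @param shell nominal b-value of the shell (s/mm^2)
#' @param subset optional indices *within the shell* to average over
#'   (e.g. a leave-one-out subset)
#' @return [ScalarVolume-class] of the per-voxel mean signal
#' @export
directionAverage <- function(dwi, shell, subset = NULL) {
  idx <- shellIndices(gradients(dwi), shell)
  if (!is.null(subset)) {
    if (length(subset) == 0L || any(subset < 1L | subset > length(idx)))
      stop("invalid direction subset")
    idx <- idx[subset]
  }
  dat <- voxelData(dwi)
  d <- dim(dat)[1:3]
  acc <- array(0, d)
  for (j in idx) acc <- acc + dat[, , , j]
  ScalarVolume(acc / length(idx), spacing = dwi@spacing)
}

# mean b=0 volume of a series
s0Volume <- function(dwi) {
  b <- bValues(dwi)
  idx <- which(b <= 25)
  if (length(idx) == 0L) stop("series has no b = 0 volume")
  dat <- voxelData(dwi)
  acc <- array(0, dim(dat)[1:3])
  for (j in idx) acc <- acc + dat[, , , j]
  acc / length(idx)
}

#' Fit the three-compartment model to one voxel
#'
#' Minimises ||sbar/s0 - S_b(v_ic, v_iso, d_e*)||_2^2 over the box
#' v_ic, v_iso in \[0, 1\], d_e* >= 0, starting from
#' (v_ic, v_iso, d_e*) = (0, 0.5, 0) by default.
#'
#' @param sbar direction-averaged signals at the nonzero shells
#' @param bvals matching b-values (s/mm^2); at least 3 nonzero shells
#' @param s0 non-diffusion-weighted signal (> 0)
#' @param const fixed diffusivities ([modelConstants])
#' @param control optimiser settings ([fitControl])
#' @return list with `vIc`, `vIso`, `dEStar`, `objective`, `nIter`,
#'   `converged`
#' @export
fitVoxel <- function(sbar, bvals, s0, const = modelConstants(),
                     control = fitControl()) {
  if (any(!is.finite(sbar))) stop("non-finite signals")
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be a positive finite number")
  if (length(sbar) != length(bvals)) stop("sbar and bvals lengths differ")
  if (sum(bvals > 0) < 3L) stop("need at least 3 nonzero shells")
  r <- .fitCompartmentVoxel(as.numeric(sbar) / s0, as.numeric(bvals),
                            const$d_ic, const$d_iso,
                            control$init[1], control$init[2], control$init[3],
                            control$tol, control$maxit, control$restarts)
  list(vIc = r[1], vIso = r[2], dEStar = r[3], objective = r[4],
       nIter = as.integer(r[5]), converged = r[6] == 1)
}

#' Leave-one-out MIP compartment fitting over a volume
#'
#' Runs the voxelwise fit n times (n = directions per shell); run j uses
#' the direction average over the n - 1 directions excluding j, the same
#' exclusion index at every shell. The final maps are the voxelwise
#' maximum (MIP) over the n runs, which counteracts the systematic
#' underestimation of single fits. Per-run maps are retained for
#' diagnostics.
#'
#' @param dwi a [DwiSeries-class]; every nonzero shell must have the same
#'   direction count n >= 2
#' @param const fixed diffusivities ([modelConstants])
#' @param control optimiser settings ([fitControl])
#' @param mask optional logical array/ScalarVolume restricting the fit
#' @param keepRuns keep per-run maps (default TRUE)
#' @return list with [ScalarVolume-class] maps `vIc`, `vIso`, `dEStar`,
#'   `objective` (minimum over runs), a `runs` list of per-run parameter
#'   arrays, and a `report` (run count, non-converged and degenerate
#'   voxel counts)
#' @export
fitLooMip <- function(dwi, const = modelConstants(), control = fitControl(),
                      mask = NULL, keepRuns = TRUE) {
  sh <- identifyShells(gradients(dwi))
  nz <- which(sh$b > 25)
  if (length(nz) < 3L) stop("need at least 3 nonzero shells")
  ndir <- unique(sh$n[nz])
  if (length(ndir) != 1L)
    stop("all nonzero shells must have the same direction count")
  n <- ndir
  if (n < 2L) stop("need at least 2 directions per shell for leave-one-out")
  bv <- sh$b[nz]
  d3 <- dim(dwi)[1:3]
  m <- resolveMask(mask, d3)
  s0 <- s0Volume(dwi)
  m <- m & is.finite(s0) & s0 > 0
  vox <- which(m)
  nv <- length(vox)
  dat <- voxelData(dwi)

  # per-shell signal matrices (nvox x ndir), directions in shell order
  shellSig <- lapply(nz, function(k) {
    idx <- sh$index[[k]]
    out <- matrix(0, nv, length(idx))
    for (jj in seq_along(idx)) out[, jj] <- dat[, , , idx[jj]][vox]
    out
  })
  s0v <- s0[vox]

  runs <- vector("list", n)
  best <- matrix(NA_real_, 6, nv)
  final <- matrix(-Inf, 3, nv)
  nDegenerate <- 0L
  nNotConverged <- 0L
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    sbar <- matrix(0, length(nz), nv)               # nshell x nvox
    for (k in seq_along(nz))
      sbar[k, ] <- rowMeans(shellSig[[k]][, keep, drop = FALSE]) / s0v
    # voxels with identical signal vectors share one fit (piecewise-
    # constant data collapse to a handful of unique problems)
    key <- apply(sbar, 2, paste, collapse = "\r")
    uk <- !duplicated(key)
    fitU <- .fitCompartmentBatch(sbar[, uk, drop = FALSE], bv,
                                 const$d_ic, const$d_iso,
                                 control$init[1], control$init[2],
                                 control$init[3], control$tol,
                                 control$maxit, control$restarts)
    fit <- fitU[, match(key, key[uk]), drop = FALSE]
    bad <- !is.finite(fit[4, ])
    nDegenerate <- nDegenerate + sum(bad)
    nNotConverged <- nNotConverged + sum(fit[6, ] == 0, na.rm = TRUE)
    final[1, ] <- pmax(final[1, ], ifelse(bad, -Inf, fit[1, ]))
    final[2, ] <- pmax(final[2, ], ifelse(bad, -Inf, fit[2, ]))
    final[3, ] <- pmax(final[3, ], ifelse(bad, -Inf, fit[3, ]))
    best[4, ] <- pmin(best[4, ], fit[4, ], na.rm = TRUE)
    if (keepRuns) {
      runs[[j]] <- list(vIc = toVolumeArray(fit[1, ], vox, d3),
                        vIso = toVolumeArray(fit[2, ], vox, d3),
                        dEStar = toVolumeArray(fit[3, ], vox, d3))
    }
  }
  final[!is.finite(final)] <- NA_real_

  sp <- dwi@spacing
  mk <- function(row) ScalarVolume(toVolumeArray(row, vox, d3), spacing = sp)
  report <- list(nRuns = n, nVoxels = nv, nDegenerate = nDegenerate,
                 nNotConverged = nNotConverged)
  list(vIc = mk(final[1, ]), vIso = mk(final[2, ]), dEStar = mk(final[3, ]),
       objective = mk(best[4, ]),
       runs = if (keepRuns) runs else NULL,
       report = report)
}

# scatter a per-voxel vector back into a 3-D array (NA elsewhere)
toVolumeArray <- function(values, vox, d3) {
  a <- array(NA_real_, d3)
  a[vox] <- values
  a
}

#' Derived low-frequency parameters from the compartment fit
#'
#' chi_e = (1 - v_iso)(1 - v_ic) + v_iso;
#' d_e = \[(1 - v_iso)(1 - v_ic)^2 d_e* + v_iso d_iso\] / chi_e;
#' d_i = v_ic d_ic. Voxels with chi_e = 0 (v_iso = 0, v_ic = 1) have
#' undefined d_e; they are counted in the result's metadata.
#'
#' @param vIc,vIso,dEStar [ScalarVolume-class] fitted parameter maps
#' @param const fixed diffusivities ([modelConstants])
#' @return list of [ScalarVolume-class] maps `chiE`, `dE`, `dI`; the
#'   `dE` map's metadata counts `nUndefined` voxels
#' @export
deriveLfParams <- function(vIc, vIso, dEStar, const = modelConstants()) {
  stopIfGridMismatch(voxelData(vIc), voxelData(vIso))
  stopIfGridMismatch(voxelData(vIc), voxelData(dEStar))
  a <- voxelData(vIc); b <- voxelData(vIso); d <- voxelData(dEStar)
  chi <- (1 - b) * (1 - a) + b
  de <- ((1 - b) * (1 - a)^2 * d + b * const$d_iso) / chi
  zero <- is.finite(chi) & chi == 0
  de[zero] <- NA_real_
  di <- a * const$d_ic
  sp <- vIc@spacing
  list(chiE = ScalarVolume(chi, sp),
       dE = ScalarVolume(de, sp, metadata = list(nUndefined = sum(zero))),
       dI = ScalarVolume(di, sp))
}
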