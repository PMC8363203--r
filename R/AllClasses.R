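#' @import methods
#' @importFrom stats fft approx median rnorm sd setNames optim quantile
#' @importFrom utils packageVersion head tail
#' @useDynLib ctimaps, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Undefined voxels (outside mask, outside a transfer function's validity
## range, degenerate fits) are represented as NA_real_ and propagate through
## every downstream map.

#' ScalarVolume: a 3-D scalar field on a voxel grid
#'
#' Thin S4 container for one scalar quantity per voxel (a spin-echo image,
#' the water map, a conductivity map, a fitted parameter map, ...) together
#' with the voxel spacing in mm. Undefined voxels are `NA`.
#'
#' @slot data 3-D numeric array.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot metadata free-form list (warning counters, provenance).
#'
#' @examples
#' v <- ScalarVolume(array(1, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v)
#' @export
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric", metadata = "list"),
  prototype(spacing = c(1, 1, 1), metadata = list()))

setValidity("ScalarVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite numbers (mm)")
  TRUE
})

#' @param data 3-D numeric array.
#' @param spacing numeric(3), voxel size in mm.
#' @param metadata list of auxiliary metadata.
#' @rdname ScalarVolume-class
#' @export
ScalarVolume <- function(data, spacing = c(1, 1, 1), metadata = list()) {
  new("ScalarVolume", data = data, spacing = as.numeric(spacing),
      metadata = metadata)
}

#' GradientTable: diffusion sensitisation per DWI volume
#'
#' b-values (s/mm^2) and unit gradient directions, one per volume of a
#' 4-D DWI series. Zero direction vectors are only allowed where b = 0.
#'
#' @slot bvals numeric vector of b-values in s/mm^2.
#' @slot bvecs 3 x n matrix of gradient directions (columns), unit norm at
#'   b > 0 within 1e-6.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix"))

setValidity("GradientTable", function(object) {
  n <- length(object@bvals)
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L ||
      ncol(object@bvecs) != n)
    return("bvecs must be a numeric 3 x length(bvals) matrix")
  if (any(!is.finite(object@bvals)) || any(object@bvals < 0))
    return("bvals must be finite and non-negative")
  nrm <- sqrt(colSums(object@bvecs^2))
  bad <- object@bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    return(sprintf("%d gradient vectors at b > 0 are not unit norm", sum(bad)))
  TRUE
})

#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions (columns).
#' @rdname GradientTable-class
#' @export
GradientTable <- function(bvals, bvecs) {
  new("GradientTable", bvals = as.numeric(bvals),
      bvecs = matrix(as.numeric(bvecs), nrow = 3L))
}

#' DwiSeries: 4-D diffusion-weighted series plus gradient table
#'
#' @slot data 4-D numeric array (x, y, z, volume).
#' @slot gradients a [GradientTable-class] with one entry per 4th-axis volume.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot metadata free-form list (simulation ground truth, provenance).
#' @export
setClass("DwiSeries",
  representation(data = "array", gradients = "GradientTable",
                 spacing = "numeric", metadata = "list"),
  prototype(spacing = c(1, 1, 1), metadata = list()))

setValidity("DwiSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4-D array (x, y, z, volume)")
  if (d[4] != length(object@gradients@bvals))
    return("4th dimension must match the gradient table length")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers (mm)")
  TRUE
})

#' @param data 4-D numeric array.
#' @param gradients a [GradientTable-class].
#' @param spacing numeric(3) voxel size in mm.
#' @param metadata list of auxiliary metadata.
#' @rdname DwiSeries-class
#' @export
DwiSeries <- function(data, gradients, spacing = c(1, 1, 1),
                      metadata = list()) {
  new("DwiSeries", data = data, gradients = gradients,
      spacing = as.numeric(spacing), metadata = metadata)
}

#' TensorVolume: a symmetric 3 x 3 tensor per voxel
#'
#' Stores the six unique components per voxel in the order
#' (xx, yy, zz, xy, xz, yz) along the 4th array axis. Units are mm^2/s for
#' diffusion tensors and S/m for conductivity tensors.
#'
#' @slot data 4-D numeric array (x, y, z, 6).
#' @slot spacing numeric(3) voxel size in mm.
#' @slot metadata free-form list.
#' @export
setClass("TensorVolume",
  representation(data = "array", spacing = "numeric", metadata = "list"),
  prototype(spacing = c(1, 1, 1), metadata = list()))

setValidity("TensorVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 6L)
    return("data must be a 4-D array with 6 tensor components on axis 4")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers (mm)")
  TRUE
})

#' Component order of [TensorVolume-class] maps
#' @export
tensorComponentOrder <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' @param data 4-D numeric array (x, y, z, 6).
#' @param spacing numeric(3) voxel size in mm.
#' @param metadata list of auxiliary metadata.
#' @rdname TensorVolume-class
#' @export
TensorVolume <- function(data, spacing = c(1, 1, 1), metadata = list()) {
  new("TensorVolume", data = data, spacing = as.numeric(spacing),
      metadata = metadata)
}

#' PhantomSpec: geometry, ground truth and noise of the synthetic phantom
#'
#' Describes a piecewise-constant three-tissue head phantom: concentric
#' CSF rim, grey-matter ribbon and white-matter core plus a CSF ventricle
#' block, with per-tissue water content, T1, proton density and
#' three-compartment diffusion parameters. Label codes are 0 background,
#' 1 GM, 2 WM, 3 CSF.
#'
#' @slot gridShape integer(3) voxel counts, each >= 16.
#' @slot voxelSize numeric(3) voxel size in mm.
#' @slot tissues data.frame with rows GM, WM, CSF and columns `W` (water
#'   volume fraction, within the transfer function's validity range
#'   \[0.6, 1\]), `T1` (s), `pd` (proton density, a.u.), `v_ic`, `v_iso`
#'   (fractions), `d_e_star` (mm^2/s).
#' @slot wmOrientation unit 3-vector, principal fibre direction of the WM
#'   core (tensor mode).
#' @slot fractionalEccentricity non-negative scalar controlling WM tensor
#'   anisotropy (0 = isotropic).
#' @slot noiseModel one of "none", "gaussian", "rician".
#' @slot noiseSigma noise standard deviation in signal units.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 tissues = "data.frame", wmOrientation = "numeric",
                 fractionalEccentricity = "numeric", noiseModel = "character",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
    return("gridShape must be 3 integers, each >= 16")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers (mm)")
  t <- object@tissues
  need <- c("W", "T1", "pd", "v_ic", "v_iso", "d_e_star")
  if (!all(need %in% names(t)) ||
      !all(c("GM", "WM", "CSF") %in% rownames(t)))
    return("tissues must have rows GM/WM/CSF and columns W,T1,pd,v_ic,v_iso,d_e_star")
  if (any(t$W < 0.6 | t$W > 1))
    return("tissue water fractions must lie in [0.6, 1]")
  if (any(t$v_ic < 0 | t$v_ic > 1 | t$v_iso < 0 | t$v_iso > 1))
    return("volume fractions must lie in [0, 1]")
  if (any(t$d_e_star < 0) || any(t$T1 <= 0) || any(t$pd <= 0))
    return("d_e_star must be >= 0; T1 and pd must be > 0")
  if (abs(sqrt(sum(object@wmOrientation^2)) - 1) > 1e-6)
    return("wmOrientation must be a unit vector")
  if (object@fractionalEccentricity < 0)
    return("fractionalEccentricity must be >= 0")
  if (!object@noiseModel %in% c("none", "gaussian", "rician"))
    return("noiseModel must be none, gaussian or rician")
  if (object@noiseSigma < 0)
    return("noiseSigma must be >= 0")
  TRUE
})

#' Construct a phantom specification
#'
#' Defaults are literature-typical 3T values: GM T1 = 1.30 s, W = 0.846,
#' v_ic = 0.4, v_iso = 0.2, d_e* = 1.2e-3 mm^2/s; WM T1 = 0.83 s,
#' W = 0.727, v_ic = 0.6, v_iso = 0.2, d_e* = 0.8e-3; CSF T1 = 4.0 s,
#' W = 0.990, v_ic = 0, v_iso = 1, d_e* = 3.0e-3. The default noise level
#' corresponds to SNR of about 40 at b = 0 (proton density 100).
#'
#' @param gridShape integer(3) voxel counts (default 32^3).
#' @param voxelSize numeric(3) voxel size in mm.
#' @param tissues per-tissue parameter data.frame (see slots).
#' @param wmOrientation principal WM fibre direction (unit 3-vector).
#' @param fractionalEccentricity WM tensor anisotropy parameter.
#' @param noiseModel "none", "gaussian" or "rician".
#' @param noiseSigma noise sd in signal units (2.5 is SNR about 40 for the
#'   default proton density of 100).
#' @param seed integer RNG seed.
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 32L),
                        voxelSize = c(1, 1, 1),
                        tissues = defaultTissueParams(),
                        wmOrientation = c(1, 0, 0),
                        fractionalEccentricity = 0.6,
                        noiseModel = "none",
                        noiseSigma = 2.5,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), tissues = tissues,
      wmOrientation = as.numeric(wmOrientation) /
        sqrt(sum(wmOrientation^2)),
      fractionalEccentricity = as.numeric(fractionalEccentricity),
      noiseModel = noiseModel, noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}

#' Default per-tissue ground-truth parameters of the phantom
#'
#' @return data.frame with rows GM, WM, CSF.
#' @export
defaultTissueParams <- function() {
  data.frame(
    W        = c(0.846, 0.727, 0.990),
    T1       = c(1.30, 0.83, 4.0),
    pd       = c(100, 100, 100),
    v_ic     = c(0.4, 0.6, 0.0),
    v_iso    = c(0.2, 0.2, 1.0),
    d_e_star = c(1.2e-3, 0.8e-3, 3.0e-3),
    row.names = c("GM", "WM", "CSF"))
}

## ---- basic methods ----

#' @describeIn ScalarVolume-class voxel grid dimensions
#' @param x a ScalarVolume
#' @export
setMethod("dim", "ScalarVolume", function(x) dim(x@data))

#' @describeIn DwiSeries-class array dimensions (x, y, z, volumes)
#' @param x a DwiSeries
#' @export
setMethod("dim", "DwiSeries", function(x) dim(x@data))

#' @describeIn TensorVolume-class array dimensions (x, y, z, 6)
#' @param x a TensorVolume
#' @export
setMethod("dim", "TensorVolume", function(x) dim(x@data))

#' Voxel data accessor
#' @param x a ScalarVolume, DwiSeries or TensorVolume
#' @return the underlying numeric array
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "DwiSeries", function(x) x@data)
#' @rdname voxelData
#' @export
setMethod("voxelData", "TensorVolume", function(x) x@data)

#' Voxel spacing accessor (mm)
#' @param x a volume object
#' @return numeric(3)
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DwiSeries", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "TensorVolume", function(x) x@spacing)

#' Gradient table accessor
#' @param x a DwiSeries
#' @return the [GradientTable-class]
#' @export
setGeneric("gradients", function(x) standardGeneric("gradients"))

#' @rdname gradients
#' @export
setMethod("gradients", "DwiSeries", function(x) x@gradients)

#' b-values accessor
#' @param x a GradientTable or DwiSeries
#' @return numeric vector of b-values (s/mm^2)
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname bValues
#' @export
setMethod("bValues", "GradientTable", function(x) x@bvals)
#' @rdname bValues
#' @export
setMethod("bValues", "DwiSeries", function(x) x@gradients@bvals)

#' Gradient direction accessor
#' @param x a GradientTable or DwiSeries
#' @return 3 x n matrix of directions
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' @rdname bVectors
#' @export
setMethod("bVectors", "GradientTable", function(x) x@bvecs)
#' @rdname bVectors
#' @export
setMethod("bVectors", "DwiSeries", function(x) x@gradients@bvecs)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  rng <- suppressWarnings(range(object@data, na.rm = TRUE))
  cat(sprintf("ScalarVolume %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  range [%g, %g], %d undefined voxels\n",
              rng[1], rng[2], sum(is.na(object@data))))
})

setMethod("show", "DwiSeries", function(object) {
  d <- dim(object@data)
  sh <- identifyShells(object@gradients)
  cat(sprintf("DwiSeries %d x %d x %d, %d volumes, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  shells (s/mm^2): %s\n",
              paste(sprintf("%g (n=%d)", sh$b, sh$n), collapse = ", ")))
})

setMethod("show", "TensorVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TensorVolume %d x %d x %d, components (%s), spacing %s mm\n",
    d[1], d[2], d[3], paste(tensorComponentOrder, collapse = ", "),
    paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s voxels @ %s mm, noise %s (sigma %g), seed %d\n",
              paste(object@gridShape, collapse = " x "),
              paste(format(object@voxelSize), collapse = " x "),
              object@noiseModel, object@noiseSigma, object@seed))
  print(object@tissues)
})
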