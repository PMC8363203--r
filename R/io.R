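## NIfTI and FSL bval/bvec readers and writers.

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @return [ScalarVolume-class] with spacing taken from the header
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  ScalarVolume(a, spacing = sp)
}

#' Write a volume to NIfTI
#'
#' @param x [ScalarVolume-class], [TensorVolume-class] or numeric array
#' @param path output path (.nii or .nii.gz)
#' @param spacing voxel spacing override (mm)
#' @return `path`, invisibly
#' @export
writeVolume <- function(x, path, spacing = NULL) {
  if (is(x, "ScalarVolume") || is(x, "TensorVolume")) {
    a <- voxelData(x)
    if (is.null(spacing)) spacing <- voxelSpacing(x)
  } else {
    a <- x
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rep(spacing, length.out = length(dim(a)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read FSL-dialect bval/bvec files
#'
#' bvals: one whitespace-separated row; bvecs: three rows (x, y, z) of
#' per-volume components. Gradient vectors are interpreted in the image
#' coordinate frame.
#'
#' @param bvalPath,bvecPath text file paths
#' @return a [GradientTable-class]
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  rows <- strsplit(trimws(readLines(bvecPath)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 3L)
    stop("bvec file must have exactly 3 rows (x, y, z components)")
  bvecs <- do.call(rbind, lapply(rows, as.numeric))
  if (ncol(bvecs) != length(bvals))
    stop("bval/bvec volume counts are inconsistent")
  GradientTable(bvals, bvecs)
}

#' Write FSL-dialect bval/bvec files
#'
#' @param gtab a [GradientTable-class]
#' @param bvalPath,bvecPath output paths
#' @return invisibly, the two paths
#' @export
writeBvalBvec <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(bValues(gtab), trim = TRUE), collapse = " "),
             bvalPath)
  writeLines(apply(bVectors(gtab), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' Read a DWI series (NIfTI + bval/bvec)
#'
#' @param niftiPath 4-D NIfTI file
#' @param bvalPath,bvecPath FSL-dialect gradient table files
#' @return a validated [DwiSeries-class]; shells are identified by
#'   clustering b-values within +/- 25 s/mm^2
#' @export
readDwi <- function(niftiPath, bvalPath, bvecPath) {
  img <- RNifti::readNifti(niftiPath)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 4L) stop("DWI NIfTI must be 4-D")
  gtab <- readBvalBvec(bvalPath, bvecPath)
  if (dim(a)[4] != length(bValues(gtab)))
    stop("DWI volume count does not match the gradient table")
  DwiSeries(a, gtab, spacing = RNifti::pixdim(img)[1:3])
}

#' Write a DWI series (NIfTI + bval/bvec)
#'
#' @param dwi a [DwiSeries-class]
#' @param niftiPath,bvalPath,bvecPath output paths
#' @return invisibly, `niftiPath`
#' @export
writeDwi <- function(dwi, niftiPath, bvalPath, bvecPath) {
  img <- RNifti::asNifti(voxelData(dwi))
  RNifti::pixdim(img) <- c(voxelSpacing(dwi), 1)
  RNifti::writeNifti(img, niftiPath)
  writeBvalBvec(gradients(dwi), bvalPath, bvecPath)
  invisible(niftiPath)
}

#' Write a complete phantom dataset to a directory
#'
#' Writes the spin-echo pair, the DWI series with bval/bvec, the tissue
#' label volume, per-parameter ground-truth volumes and a YAML sidecar of
#' the specification. SE noise uses the Gaussian model and DWI noise the
#' Rician model whenever the spec's noise is enabled.
#'
#' @param spec a [PhantomSpec-class]
#' @param dir output directory (created if needed)
#' @param mode DWI simulation mode, "spherical" or "tensor"
#' @return invisibly, the output directory
#' @export
writePhantomDataset <- function(spec, dir, mode = "spherical") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seNoise <- if (spec@noiseModel == "none") "none" else "gaussian"
  dwiNoise <- if (spec@noiseModel == "none") "none" else "rician"
  se <- simulateSePair(spec, mode = "calibrated", noiseModel = seNoise)
  dwi <- simulateDwi(spec, mode = mode, noiseModel = dwiNoise)
  writeVolume(se$se1, file.path(dir, "se_tr1.nii.gz"))
  writeVolume(se$se2, file.path(dir, "se_tr2.nii.gz"))
  writeVolume(se$label, file.path(dir, "label.nii.gz"))
  writeDwi(dwi, file.path(dir, "dwi.nii.gz"),
           file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
  gt <- phantomGroundTruth(spec)
  for (nm in c("W", "vIc", "vIso", "dEStar"))
    writeVolume(gt[[nm]], file.path(dir, sprintf("truth_%s.nii.gz", nm)))
  yaml::write_yaml(list(
    gridShape = as.integer(spec@gridShape),
    voxelSize = as.numeric(spec@voxelSize),
    tissues = cbind(tissue = rownames(spec@tissues), spec@tissues),
    wmOrientation = as.numeric(spec@wmOrientation),
    fractionalEccentricity = spec@fractionalEccentricity,
    noiseModel = spec@noiseModel, noiseSigma = spec@noiseSigma,
    seed = spec@seed, dwiMode = mode),
    file.path(dir, "phantom.yaml"))
  invisible(dir)
}
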