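## internal helpers shared across modules

#' Identify b-value shells in a gradient table
#'
#' Clusters b-values that agree within a tolerance (default +/- 25 s/mm^2)
#' into shells and reports each shell's nominal b (mean) and volume indices.
#'
#' @param gtab a [GradientTable-class]
#' @param tol clustering tolerance in s/mm^2
#' @return data.frame-like list with elements `b` (nominal b per shell,
#'   ascending), `n` (volumes per shell) and `index` (list of volume
#'   indices per shell)
#' @export
identifyShells <- function(gtab, tol = 25) {
  b <- bValues(gtab)
  ord <- order(b)
  groups <- integer(length(b))
  gid <- 0L
  last <- -Inf
  for (i in ord) {
    if (b[i] - last > tol) gid <- gid + 1L
    groups[i] <- gid
    last <- b[i]
  }
  idx <- split(seq_along(b), groups)
  list(b = unname(vapply(idx, function(i) mean(b[i]), 0)),
       n = lengths(idx, use.names = FALSE),
       index = unname(idx))
}

# indices of the shell whose nominal b matches `shell` within tol
shellIndices <- function(gtab, shell, tol = 25) {
  sh <- identifyShells(gtab, tol)
  k <- which(abs(sh$b - shell) <= tol)
  if (length(k) != 1L)
    stop(sprintf("no unique shell at b = %g s/mm^2", shell))
  sh$index[[k]]
}

# coerce mask argument: NULL -> all finite voxels of reference array
resolveMask <- function(mask, refDim) {
  if (is.null(mask)) return(array(TRUE, refDim))
  m <- if (is(mask, "ScalarVolume")) voxelData(mask) else mask
  if (!identical(dim(m), as.integer(refDim)) &&
      !identical(dim(m), refDim))
    stop("mask dimensions do not match the volume")
  storage.mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}

stopIfGridMismatch <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes are not on the same grid")
  invisible(TRUE)
}

# population standard deviation
popSd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}
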