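## Artifact labelling and slice-wise Delaunay imputation of fitted maps.

#' Label sub-physiological voxels and impute them by 2-D interpolation
#'
#' Voxels whose value falls below `cutoff` (default 0.15, the assumed
#' physiological floor for the volume-fraction maps) are labelled invalid
#' and re-filled slice by slice via Delaunay triangulation of the valid
#' voxels with linear interpolation. Voxels in `excludeMask` (e.g. CSF
#' when labelling v_ic, which is legitimately 0 there) are excluded from
#' labelling and keep their fitted value. Invalid voxels outside the
#' convex hull of the valid voxels of their slice fall back to the
#' nearest valid neighbour; a slice with fewer than 3 valid voxels is
#' entirely nearest-neighbour filled (with a warning).
#'
#' @param map a [ScalarVolume-class] to repair
#' @param cutoff labelling threshold (values < cutoff are invalid);
#'   `NA` disables cutoff labelling so only voxels already `NA` inside
#'   the mask are imputed (used for d_e*, where only degenerate fits are
#'   re-filled)
#' @param excludeMask optional logical array / ScalarVolume of voxels
#'   exempt from labelling
#' @param mask optional processing mask (default: finite voxels)
#' @param axis slice axis for the 2-D interpolation (default 3, axial by
#'   array convention)
#' @return [ScalarVolume-class] with invalid voxels re-filled; metadata
#'   counts `nInvalid` (labelled) and `nFallback` (nearest-neighbour
#'   fills)
#' @export
labelAndImpute <- function(map, cutoff = 0.15, excludeMask = NULL,
                           mask = NULL, axis = 3L) {
  x <- voxelData(map)
  d <- dim(x)
  m <- if (is.null(mask)) is.finite(x) else resolveMask(mask, d)
  excl <- if (is.null(excludeMask)) array(FALSE, d)
          else resolveMask(excludeMask, d)
  invalid <- m & !excl &
    ((!is.na(cutoff) & !is.na(x) & x < cutoff) | is.na(x))
  if (!any(invalid))
    return(ScalarVolume(x, spacing = map@spacing,
                        metadata = list(nInvalid = 0L, nFallback = 0L)))

  perm <- switch(as.integer(axis), c(3, 1, 2), c(1, 3, 2), c(1, 2, 3))
  if (is.null(perm)) stop("axis must be 1, 2 or 3")
  nFallback <- 0L
  for (s in seq_len(d[axis])) {
    sl <- sliceGet(x, axis, s)
    inv <- sliceGet(invalid, axis, s)
    if (!any(inv)) next
    msl <- sliceGet(m, axis, s)
    valid <- msl & !inv & is.finite(sl)
    vi <- which(valid, arr.ind = TRUE)
    qi <- which(inv, arr.ind = TRUE)
    if (nrow(vi) < 3L) {
      warning(sprintf("slice %d has fewer than 3 valid voxels; nearest-neighbour fill", s))
      filled <- nearestFill(sl, vi, qi)
      nFallback <- nFallback + nrow(qi)
    } else {
      z <- sl[valid]
      est <- suppressWarnings(tryCatch(
        interp::interpp(as.numeric(vi[, 1]), as.numeric(vi[, 2]), z,
                        xo = as.numeric(qi[, 1]), yo = as.numeric(qi[, 2]))$z,
        error = function(e) rep(NA_real_, nrow(qi))))
      filled <- est
      miss <- !is.finite(filled)
      if (any(miss)) {
        filled[miss] <- nearestFill(sl, vi, qi[miss, , drop = FALSE])
        nFallback <- nFallback + sum(miss)
      }
    }
    sl[inv] <- filled
    x <- sliceSet(x, axis, s, sl)
  }
  ScalarVolume(x, spacing = map@spacing,
               metadata = list(nInvalid = sum(invalid),
                               nFallback = nFallback))
}

sliceGet <- function(a, axis, s) {
  switch(as.integer(axis),
         a[s, , ], a[, s, ], a[, , s])
}

sliceSet <- function(a, axis, s, value) {
  switch(as.integer(axis),
         a[s, , ] <- value, a[, s, ] <- value, a[, , s] <- value)
  a
}

# nearest valid neighbour values for query index rows
nearestFill <- function(sl, vi, qi) {
  if (nrow(vi) == 0L) return(rep(NA_real_, nrow(qi)))
  vals <- sl[vi]
  vapply(seq_len(nrow(qi)), function(i) {
    d2 <- (vi[, 1] - qi[i, 1])^2 + (vi[, 2] - qi[i, 2])^2
    vals[which.min(d2)]
  }, 0)
}
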