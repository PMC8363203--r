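## Tissue segmentation by conductivity threshold, distribution statistics
## and the PSD-based spatial resolution test.

#' CSF mask from the HF conductivity map
#'
#' CSF conductivity is far above GM/WM, so thresholding sigma_HF at
#' 2 S/m (default) segments CSF directly and more reliably than
#' anatomical segmentation at thin CSF/GM interfaces.
#'
#' @param sigmaHf [ScalarVolume-class] HF conductivity (S/m)
#' @param threshold S/m, default 2
#' @return logical array, TRUE where sigma_HF >= threshold
#' @export
csfMaskFromSigma <- function(sigmaHf, threshold = 2.0) {
  s <- voxelData(sigmaHf)
  m <- is.finite(s) & s >= threshold
  m
}

#' Per-tissue conductivity distribution statistics
#'
#' For each tissue mask: mean, population standard deviation, coefficient
#' of variation CV = std/mean (in %), and voxel count, over defined
#' in-mask voxels.
#'
#' @param map [ScalarVolume-class] (e.g. sigma_LF_iso)
#' @param masks named list of logical arrays / ScalarVolumes (typically
#'   GM, WM, CSF); masks must be pairwise disjoint
#' @return list with `stats` (data.frame tissue/mean/std/cv/n) and
#'   `values` (named list of raw in-mask samples)
#' @export
tissueDistributions <- function(map, masks) {
  x <- voxelData(map)
  ms <- lapply(masks, resolveMask, refDim = dim(x))
  if (length(ms) > 1L) {
    tot <- Reduce(`+`, lapply(ms, function(m) as.integer(m)))
    if (any(tot > 1L)) stop("tissue masks must be disjoint")
  }
  vals <- lapply(ms, function(m) x[m & is.finite(x)])
  if (any(lengths(vals) == 0L)) stop("empty tissue mask")
  stats <- data.frame(
    tissue = names(ms),
    mean = vapply(vals, mean, 0),
    std = vapply(vals, popSd, 0),
    n = lengths(vals),
    row.names = NULL)
  stats$cv <- ifelse(stats$mean != 0, 100 * stats$std / stats$mean, NA_real_)
  list(stats = stats[, c("tissue", "mean", "std", "cv", "n")],
       values = vals)
}

#' Coefficient of joint variation between the GM and WM distributions
#'
#' CJV = (std_GM + std_WM) / (mean_GM - mean_WM), reported in %. The
#' GM-minus-WM orientation is fixed by contract, so swapping the tissues
#' flips the sign. Lower values mean better GM/WM separability.
#'
#' @param statsGm,statsWm one-row data.frames (or lists) with `mean` and
#'   `std` fields, as produced by [tissueDistributions]
#' @return CJV in %
#' @export
cjv <- function(statsGm, statsWm) {
  dm <- statsGm$mean - statsWm$mean
  if (dm == 0) stop("GM and WM means are equal; CJV undefined")
  100 * (statsGm$std + statsWm$std) / dm
}

#' Power spectral density profile along one axis
#'
#' For every in-mask line along `axis`, the longest contiguous in-mask
#' segment of at least `minSamples` voxels is taken; segments are
#' truncated to the shortest qualifying length so frequency bins align,
#' their periodograms (|FFT|^2 / L, no windowing) are averaged across
#' lines, converted to dB (10 log10) and the DC bin is removed. Zero
#' power is floored at `floorDb`.
#'
#' @param volume a [ScalarVolume-class]
#' @param axis array axis along which lines run (1, 2 or 3)
#' @param mask optional logical array / ScalarVolume
#' @param minSamples minimum usable line length (default 16)
#' @param floorDb dB floor for zero-power bins (default -120)
#' @return list with `freq` (cycles/mm), `powerDb`, `axis`, `nLines`,
#'   `length` (samples per line used)
#' @export
psdProfile <- function(volume, axis = 2L, mask = NULL, minSamples = 16L,
                       floorDb = -120) {
  x <- voxelData(volume)
  d <- dim(x)
  m <- resolveMask(mask, d) & is.finite(x)
  perm <- switch(as.integer(axis),
                 c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  if (is.null(perm)) stop("axis must be 1, 2 or 3")
  xp <- aperm(x, perm)
  mp <- aperm(m, perm)
  L <- dim(xp)[1]
  nl <- prod(dim(xp)[2:3])
  dim(xp) <- c(L, nl); dim(mp) <- c(L, nl)
  segs <- list()
  for (i in seq_len(nl)) {
    r <- rle(mp[, i])
    if (!any(r$values & r$lengths >= minSamples)) next
    ends <- cumsum(r$lengths)
    k <- which(r$values & r$lengths >= minSamples)
    k <- k[which.max(r$lengths[k])]
    segs[[length(segs) + 1L]] <- xp[(ends[k] - r$lengths[k] + 1):ends[k], i]
  }
  if (length(segs) == 0L) stop("no usable lines for the PSD profile")
  Lc <- min(lengths(segs))
  P <- vapply(segs, function(s) {
    s <- s[seq_len(Lc)]
    Mod(fft(s))^2 / Lc
  }, numeric(Lc))
  Pm <- rowMeans(matrix(P, nrow = Lc))
  half <- seq_len(floor(Lc / 2) + 1L)     # one-sided incl. DC and Nyquist
  Pm <- Pm[half]
  db <- ifelse(Pm > 0, 10 * log10(Pm), floorDb)
  db <- pmax(db, floorDb)
  sp <- voxelSpacing(volume)[axis]
  freq <- (half - 1) / (Lc * sp)
  list(freq = freq[-1], powerDb = db[-1],     # DC bin removed
       axis = axis, nLines = length(segs), length = Lc)
}

#' Band-limited resolution reference by down/up-sampling
#'
#' Downsamples the volume in-plane (axes 1 and 2) to `targetSpacing` by
#' linear interpolation and upsamples it back onto the native grid,
#' producing a reference whose spectral content is limited by the coarser
#' grid (emulating maps acquired at lower resolution).
#'
#' @param volume a [ScalarVolume-class]
#' @param targetSpacing target in-plane spacing in mm (>= native)
#' @return [ScalarVolume-class] on the native grid
#' @export
resampleResolutionReference <- function(volume, targetSpacing) {
  x <- voxelData(volume)
  sp <- voxelSpacing(volume)
  if (any(targetSpacing < sp[1:2] - 1e-12))
    stop("targetSpacing must not be finer than the native spacing")
  for (ax in 1:2) {
    x <- resampleAxis(x, ax, sp[ax], targetSpacing)
  }
  ScalarVolume(x, spacing = sp,
               metadata = list(targetSpacing = targetSpacing))
}

# down/up-sample one axis by linear interpolation; undefined stretches
# (e.g. outside the head) survive as edge-extended values or, for lines
# with fewer than two defined samples, pass through unchanged
resampleAxis <- function(x, axis, native, target) {
  d <- dim(x)
  L <- d[axis]
  pos <- (seq_len(L) - 1) * native
  coarse <- seq(0, pos[L], by = target)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], dp[2] * dp[3])
  out <- apply(xp, 2, function(line) {
    if (sum(is.finite(line)) < 2L) return(line)
    down <- approx(pos, line, xout = coarse, rule = 2)$y
    approx(coarse, down, xout = pos, rule = 2)$y
  })
  dim(out) <- dp
  aperm(out, order(perm))
}
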