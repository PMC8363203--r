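## Water-content mapping from the two-TR spin-echo ratio and the
## water -> high-frequency conductivity transfer function.

#' Coefficients of the spin-echo-ratio water transfer function
#'
#' W = w1 exp(-w2 I_r), with I_r the ratio of the spin-echo images
#' acquired at TR1 = 700 ms and TR2 = 3000 ms. The default coefficients
#' were optimised for typical GM/WM/CSF water concentrations at 3T.
#'
#' @param w1,w2 dimensionless positive coefficients
#' @return classed list of coefficients
#' @export
waterMapParams <- function(w1 = 1.525, w2 = 1.443) {
  stopifnot(w1 > 0, w2 > 0)
  structure(list(w1 = w1, w2 = w2), class = "waterMapParams")
}

#' Coefficients of the water -> HF conductivity transfer function
#'
#' sigma_HF = c1 + c2 exp(c3 W), defined for water fractions within
#' `validRange` (default \[0.6, 1\]); voxels outside the range are set to
#' undefined rather than extrapolated, since the exponential amplifies
#' water-map errors at high W.
#'
#' @param c1 offset in S/m
#' @param c2 scale in S/m (> 0)
#' @param c3 dimensionless rate (> 0)
#' @param validRange length-2 ascending range of W over which the
#'   function is defined
#' @return classed list of coefficients
#' @export
hfConductivityParams <- function(c1 = 0.286, c2 = 1.526e-5, c3 = 11.852,
                                 validRange = c(0.6, 1.0)) {
  stopifnot(c2 > 0, c3 > 0, length(validRange) == 2L,
            validRange[1] < validRange[2])
  structure(list(c1 = c1, c2 = c2, c3 = c3, validRange = validRange),
            class = "hfConductivityParams")
}

#' Image ratio of the two spin-echo acquisitions
#'
#' I_r = S(TR1) / S(TR2), voxelwise. Voxels outside the mask are
#' undefined (NA). A receiver-gain sanity check warns when the global
#' medians of the two images differ by more than a factor of 10.
#'
#' @param seTr1,seTr2 [ScalarVolume-class] spin-echo images on the same
#'   grid (TR1 < TR2)
#' @param mask optional logical array or ScalarVolume; default: voxels
#'   where both images are finite and seTr2 > 0
#' @return [ScalarVolume-class] of ratios
#' @export
imageRatio <- function(seTr1, seTr2, mask = NULL) {
  stopIfGridMismatch(voxelData(seTr1), voxelData(seTr2))
  s1 <- voxelData(seTr1); s2 <- voxelData(seTr2)
  if (is.null(mask)) {
    m <- is.finite(s1) & is.finite(s2) & s2 > 0
  } else {
    m <- resolveMask(mask, dim(s1))
    if (any(!is.finite(s2[m]) | s2[m] == 0))
      stop("zero or non-finite TR2 signal inside the mask")
  }
  med1 <- median(s1[m]); med2 <- median(s2[m])
  if (is.finite(med1) && is.finite(med2) && med2 > 0 &&
      (med1 / med2 > 10 || med2 / med1 > 10))
    warning("spin-echo image medians differ by more than 10x; check receiver gain consistency")
  ir <- array(NA_real_, dim(s1))
  ir[m] <- s1[m] / s2[m]
  ScalarVolume(ir, spacing = seTr1@spacing)
}

#' Water volume-fraction map from the spin-echo ratio
#'
#' W = w1 exp(-w2 I_r); strictly decreasing in the ratio. Undefined
#' voxels propagate.
#'
#' @param ir [ScalarVolume-class] image ratio
#' @param params coefficients from [waterMapParams]
#' @return [ScalarVolume-class] water fraction map
#' @export
waterFromRatio <- function(ir, params = waterMapParams()) {
  x <- voxelData(ir)
  w <- params$w1 * exp(-params$w2 * x)
  ScalarVolume(w, spacing = ir@spacing)
}

#' High-frequency conductivity from the water map
#'
#' sigma_HF = c1 + c2 exp(c3 W) for W inside the validity range;
#' out-of-range voxels are set to undefined and counted in
#' `metadata(result)$nOutOfRange` rather than extrapolated.
#'
#' @param W [ScalarVolume-class] water fraction map
#' @param params coefficients from [hfConductivityParams]
#' @return [ScalarVolume-class] conductivity (S/m) with an
#'   `nOutOfRange` metadata counter
#' @export
hfConductivity <- function(W, params = hfConductivityParams()) {
  w <- voxelData(W)
  out <- is.finite(w) & (w < params$validRange[1] | w > params$validRange[2])
  s <- params$c1 + params$c2 * exp(params$c3 * w)
  s[out] <- NA_real_
  ScalarVolume(s, spacing = W@spacing,
               metadata = list(nOutOfRange = sum(out)))
}
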