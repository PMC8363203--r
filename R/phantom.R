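## Synthetic three-tissue head phantom: geometry, spin-echo pair and
## multi-shell DWI simulators with stored ground truth.

#' Deterministic quasi-uniform unit directions (Fibonacci sphere)
#'
#' @param n number of directions
#' @return 3 x n matrix of unit vectors
#' @export
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Multi-shell gradient table matching the reference acquisition
#'
#' One b = 0 volume followed by shells at b = 50, 150, 1000, 1800 and
#' 4500 s/mm^2, each with the same `nDir` directions (directions are
#' matched across shells).
#'
#' @param nDir directions per nonzero shell (default 16)
#' @param shells nonzero b-values in s/mm^2
#' @param nB0 number of b = 0 volumes
#' @return a [GradientTable-class]
#' @export
defaultGradientTable <- function(nDir = 16L,
                                 shells = c(50, 150, 1000, 1800, 4500),
                                 nB0 = 1L) {
  dirs <- fibonacciDirections(nDir)
  bvals <- c(rep(0, nB0), rep(shells, each = nDir))
  bvecs <- cbind(matrix(0, 3, nB0),
                 dirs[, rep(seq_len(nDir), times = length(shells))])
  GradientTable(bvals, bvecs)
}

#' Construct the default phantom geometry
#'
#' Concentric-shell geometry: a CSF rim, a grey-matter ribbon, a
#' white-matter core, and a central CSF "ventricle" block. Fully
#' deterministic for a given spec.
#'
#' @param spec a [PhantomSpec-class]
#' @return a [ScalarVolume-class] of integer labels (0 background, 1 GM,
#'   2 WM, 3 CSF)
#' @export
makeDefaultPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@gridShape
  if (any(d < 16L))
    stop("grid too small to contain all three tissues (need >= 16 voxels per axis)")
  ctr <- (d + 1) / 2
  m <- min(d)
  rOut <- 0.45 * m
  rGm  <- 0.36 * m
  rWm  <- 0.27 * m
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  r <- sqrt((ix - ctr[1])^2 + (iy - ctr[2])^2 + (iz - ctr[3])^2)
  lab <- array(0L, d)
  lab[r <= rOut] <- 3L          # CSF rim
  lab[r <= rGm]  <- 1L          # GM ribbon
  lab[r <= rWm]  <- 2L          # WM core
  # central CSF ventricle block
  vh <- pmax(1L, round(d * 0.08))
  vi <- lapply(1:3, function(k) {
    seq(max(1L, round(ctr[k] - vh[k])), min(d[k], round(ctr[k] + vh[k])))
  })
  lab[vi[[1]], vi[[2]], vi[[3]]] <- 3L
  if (!all(c(1L, 2L, 3L) %in% lab))
    stop("grid too small to contain all three tissues")
  ScalarVolume(lab, spacing = spec@voxelSize,
               metadata = list(labels = c(background = 0, GM = 1,
                                          WM = 2, CSF = 3)))
}

#' Per-voxel ground-truth parameter maps of a phantom
#'
#' @param spec a [PhantomSpec-class]
#' @param labels optional label volume (defaults to [makeDefaultPhantom])
#' @return list of [ScalarVolume-class] maps `W`, `T1`, `pd`, `vIc`,
#'   `vIso`, `dEStar` (NA outside tissue) plus the `label` volume
#' @export
phantomGroundTruth <- function(spec, labels = makeDefaultPhantom(spec)) {
  lab <- voxelData(labels)
  t <- spec@tissues[c("GM", "WM", "CSF"), ]
  lookup <- function(col) {
    v <- array(NA_real_, dim(lab))
    for (k in 1:3) v[lab == k] <- t[[col]][k]
    ScalarVolume(v, spacing = spec@voxelSize)
  }
  list(W = lookup("W"), T1 = lookup("T1"), pd = lookup("pd"),
       vIc = lookup("v_ic"), vIso = lookup("v_iso"),
       dEStar = lookup("d_e_star"), label = labels)
}

#' Simulate the two-TR spin-echo pair
#'
#' In `"relaxation"` mode the saturation-recovery model
#' S(TR) = PD (1 - exp(-TR/T1)) is evaluated per voxel (identical TE is
#' assumed for the two scans, so TE decay cancels in the ratio and is not
#' modelled). In `"calibrated"` mode the image ratio is set per tissue by
#' inverting the water transfer function, I_r = -ln(W/w1)/w2, and
#' S(TR1) = I_r S(TR2), so the water map round-trips the target exactly
#' when noise is off.
#'
#' @param spec a [PhantomSpec-class]
#' @param tr1,tr2 repetition times in seconds (defaults 0.7 and 3.0);
#'   `tr1 < tr2` is required
#' @param mode "relaxation" or "calibrated"
#' @param waterParams water transfer-function coefficients, used by the
#'   calibrated mode (see [waterMapParams])
#' @param noiseModel noise model override (defaults to the spec's;
#'   Gaussian is the appropriate model for magnitude SE images at
#'   reasonable SNR)
#' @return list with [ScalarVolume-class] elements `se1`, `se2` and the
#'   label volume
#' @export
simulateSePair <- function(spec, tr1 = 0.7, tr2 = 3.0,
                           mode = c("relaxation", "calibrated"),
                           waterParams = waterMapParams(),
                           noiseModel = spec@noiseModel) {
  mode <- match.arg(mode)
  if (!(tr1 < tr2)) stop("tr1 must be smaller than tr2")
  labels <- makeDefaultPhantom(spec)
  lab <- voxelData(labels)
  t <- spec@tissues[c("GM", "WM", "CSF"), ]
  se1 <- array(0, dim(lab)); se2 <- array(0, dim(lab))
  for (k in 1:3) {
    sel <- lab == k
    s2 <- t$pd[k] * (1 - exp(-tr2 / t$T1[k]))
    if (mode == "relaxation") {
      s1 <- t$pd[k] * (1 - exp(-tr1 / t$T1[k]))
    } else {
      W <- t$W[k]
      if (W <= 0 || W >= waterParams$w1)
        stop("calibrated mode requires 0 < W < w1 (transfer function not invertible)")
      ir <- -log(W / waterParams$w1) / waterParams$w2
      s1 <- ir * s2
    }
    se1[sel] <- s1
    se2[sel] <- s2
  }
  se1 <- addNoise(se1, noiseModel, spec@noiseSigma, seed = spec@seed + 101L)
  se2 <- addNoise(se2, noiseModel, spec@noiseSigma, seed = spec@seed + 102L)
  list(se1 = ScalarVolume(se1, spec@voxelSize),
       se2 = ScalarVolume(se2, spec@voxelSize),
       label = labels)
}

#' Simulate a multi-shell DWI series from the phantom
#'
#' `"spherical"` mode emits the direction-independent three-compartment
#' signal (so the direction average at each shell equals the model
#' exactly); `"tensor"` mode emits S = S0 exp(-b g' D g) from a per-tissue
#' ground-truth tensor, for testing the tensor-fit path. In tensor mode
#' the per-tissue mean diffusivity is the b = 1000 apparent diffusivity of
#' the spherical model, so the two modes agree at the tensor-fit shell;
#' the WM tensor is elongated along `spec@wmOrientation` with eigenvalues
#' md (1 + fe), md (1 - fe/2), md (1 - fe/2).
#'
#' @param spec a [PhantomSpec-class]
#' @param gtab a [GradientTable-class] (default [defaultGradientTable])
#' @param mode "spherical" or "tensor"
#' @param const fixed compartment diffusivities ([modelConstants])
#' @param noiseModel noise model override (defaults to the spec's; Rician
#'   is the appropriate model for magnitude DWI)
#' @return a [DwiSeries-class]; ground truth is stored in
#'   `metadata(x)$truth` (per-voxel parameter arrays, label array and, in
#'   tensor mode, the 6-component tensor array)
#' @export
simulateDwi <- function(spec, gtab = defaultGradientTable(),
                        mode = c("spherical", "tensor"),
                        const = modelConstants(),
                        noiseModel = spec@noiseModel) {
  mode <- match.arg(mode)
  labels <- makeDefaultPhantom(spec)
  lab <- voxelData(labels)
  d <- dim(lab)
  b <- bValues(gtab)
  g <- bVectors(gtab)
  nvol <- length(b)
  t <- spec@tissues[c("GM", "WM", "CSF"), ]
  dat <- array(0, c(d, nvol))
  truth <- list(label = lab,
                vIc = array(NA_real_, d), vIso = array(NA_real_, d),
                dEStar = array(NA_real_, d), s0 = array(NA_real_, d))

  # per-tissue signal per volume
  sig <- matrix(0, 3, nvol)
  if (mode == "spherical") {
    for (k in 1:3)
      sig[k, ] <- t$pd[k] *
        predictSignal(b, t$v_ic[k], t$v_iso[k], t$d_e_star[k], const)
  } else {
    Dt <- phantomTissueTensors(spec, const)
    truth$tensor6 <- array(NA_real_, c(d, 6))
    for (k in 1:3) {
      D <- Dt[[k]]
      q <- colSums(g * (D %*% g))        # g' D g per volume
      sig[k, ] <- t$pd[k] * exp(-b * q)
    }
  }
  for (k in 1:3) {
    sel <- lab == k
    truth$vIc[sel] <- t$v_ic[k]
    truth$vIso[sel] <- t$v_iso[k]
    truth$dEStar[sel] <- t$d_e_star[k]
    truth$s0[sel] <- t$pd[k]
    for (j in seq_len(nvol)) {
      vol <- dat[, , , j]
      vol[sel] <- sig[k, j]
      dat[, , , j] <- vol
    }
    if (mode == "tensor") {
      six <- tensorToSix(phantomTissueTensors(spec, const)[[k]])
      for (c6 in 1:6) {
        vol <- truth$tensor6[, , , c6]
        vol[sel] <- six[c6]
        truth$tensor6[, , , c6] <- vol
      }
    }
  }
  dat <- addNoise(dat, noiseModel, spec@noiseSigma, seed = spec@seed + 201L)
  DwiSeries(dat, gtab, spacing = spec@voxelSize,
            metadata = list(truth = truth, mode = mode))
}

# per-tissue ground-truth tensors for tensor mode (list GM, WM, CSF)
phantomTissueTensors <- function(spec, const = modelConstants()) {
  t <- spec@tissues[c("GM", "WM", "CSF"), ]
  out <- vector("list", 3)
  for (k in 1:3) {
    md <- -log(predictSignal(1000, t$v_ic[k], t$v_iso[k],
                             t$d_e_star[k], const)) / 1000
    if (k == 2L && spec@fractionalEccentricity > 0) {
      fe <- spec@fractionalEccentricity
      ev <- md * c(1 + fe, 1 - fe / 2, 1 - fe / 2)
      u1 <- spec@wmOrientation
      # complete an orthonormal basis around the fibre direction
      ref <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u2 <- ref - sum(ref * u1) * u1
      u2 <- u2 / sqrt(sum(u2^2))
      u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
              u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1])
      R <- cbind(u1, u2, u3)
      out[[k]] <- R %*% diag(ev) %*% t(R)
    } else {
      out[[k]] <- diag(rep(md, 3))
    }
  }
  names(out) <- c("GM", "WM", "CSF")
  out
}

# 3x3 symmetric matrix -> six components (xx, yy, zz, xy, xz, yz)
tensorToSix <- function(M) {
  c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

#' Add measurement noise to a signal array or volume
#'
#' Gaussian noise adds N(0, sigma); Rician noise returns
#' |signal + (n1 + i n2)| with independent N(0, sigma) real and imaginary
#' perturbations, the correct model for MR magnitude data. Reproducible
#' for a fixed seed.
#'
#' @param x numeric array, [ScalarVolume-class] or [DwiSeries-class]
#' @param model "none", "gaussian" or "rician"
#' @param sigma noise standard deviation (signal units, >= 0)
#' @param seed integer seed
#' @return object of the same type as `x`
#' @export
setGeneric("addNoise",
  function(x, model = c("none", "gaussian", "rician"), sigma = 0,
           seed = 1L) standardGeneric("addNoise"))

#' @rdname addNoise
#' @export
setMethod("addNoise", "array", function(x, model, sigma, seed) {
  model <- match.arg(model, c("none", "gaussian", "rician"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (model == "none" || sigma == 0) return(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  if (model == "gaussian") {
    x + array(rnorm(length(x), 0, sigma), dim(x))
  } else {
    re <- x + array(rnorm(length(x), 0, sigma), dim(x))
    im <- array(rnorm(length(x), 0, sigma), dim(x))
    sqrt(re^2 + im^2)
  }
})

#' @rdname addNoise
#' @export
setMethod("addNoise", "ScalarVolume", function(x, model, sigma, seed) {
  ScalarVolume(addNoise(voxelData(x), model, sigma, seed),
               spacing = x@spacing, metadata = x@metadata)
})

#' @rdname addNoise
#' @export
setMethod("addNoise", "DwiSeries", function(x, model, sigma, seed) {
  DwiSeries(addNoise(voxelData(x), model, sigma, seed), x@gradients,
            spacing = x@spacing, metadata = x@metadata)
})
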