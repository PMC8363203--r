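## End-to-end reconstruction: spin-echo pair + DWI -> conductivity tensor.

#' Pipeline configuration
#'
#' Bundles the input paths, all model constants (defaulting to the
#' reference values) and optimiser settings. Every override is recorded
#' in the provenance file written by [runPipeline].
#'
#' @param se1,se2 spin-echo NIfTI paths (TR1 < TR2)
#' @param dwi,bval,bvec DWI NIfTI and gradient table paths
#' @param mask optional brain mask NIfTI path
#' @param gmMask,wmMask optional tissue mask NIfTI paths (for the report)
#' @param outDir output directory
#' @param waterParams,hfParams,mdlConst,ctiConst parameter bundles (see
#'   [waterMapParams], [hfConductivityParams], [modelConstants],
#'   [ctiConstants])
#' @param control optimiser settings ([fitControl])
#' @param cutoff artifact labelling cutoff for the volume-fraction maps
#' @param csfThreshold CSF segmentation threshold on sigma_HF (S/m)
#' @param tensorShell b-value of the tensor shell (s/mm^2)
#' @param seed integer seed recorded in provenance
#' @return classed list
#' @export
pipelineConfig <- function(se1, se2, dwi, bval, bvec, mask = NULL,
                           gmMask = NULL, wmMask = NULL,
                           outDir = "cti_out",
                           waterParams = waterMapParams(),
                           hfParams = hfConductivityParams(),
                           mdlConst = modelConstants(),
                           ctiConst = ctiConstants(),
                           control = fitControl(),
                           cutoff = 0.15, csfThreshold = 2.0,
                           tensorShell = 1000, seed = 1L) {
  structure(list(se1 = se1, se2 = se2, dwi = dwi, bval = bval, bvec = bvec,
                 mask = mask, gmMask = gmMask, wmMask = wmMask,
                 outDir = outDir, waterParams = waterParams,
                 hfParams = hfParams, mdlConst = mdlConst,
                 ctiConst = ctiConst, control = control, cutoff = cutoff,
                 csfThreshold = csfThreshold, tensorShell = tensorShell,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full reconstruction pipeline
#'
#' Stages: water map and HF conductivity from the spin-echo ratio; CSF
#' mask by conductivity threshold; leave-one-out MIP compartment fit;
#' artifact labelling and Delaunay imputation (CSF excluded from v_ic
#' labelling); derived LF parameters; diffusion tensor at the tensor
#' shell; extracellular rescaling; conductivity tensor and its
#' isotropic-equivalent map. All intermediate maps, a JSON provenance
#' record and a per-stage warning-count log are written to the output
#' directory. Deterministic for a fixed configuration.
#'
#' All inputs must be pre-processed and co-registered on a common grid;
#' denoising, distortion correction and registration are upstream of this
#' package.
#'
#' @param config a [pipelineConfig]
#' @return invisibly, a list with the main in-memory results (`W`,
#'   `sigmaHf`, `fit`, `lf`, `D`, `De`, `Clf`, `sigmaLfIso`, `report`)
#' @export
runPipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "pipeline.log")
  logLines <- character()
  sayLog <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logLines <<- c(logLines, sprintf("[%s] %s", format(Sys.time()), msg))
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  warnCounts <- list()

  sayLog("stage water: spin-echo ratio -> W -> sigma_HF")
  res <- stage("water", {
    se1 <- readVolume(cfg$se1); se2 <- readVolume(cfg$se2)
    mask <- if (!is.null(cfg$mask)) voxelData(readVolume(cfg$mask)) > 0 else NULL
    ir <- imageRatio(se1, se2, mask)
    W <- waterFromRatio(ir, cfg$waterParams)
    sHf <- hfConductivity(W, cfg$hfParams)
    list(ir = ir, W = W, sigmaHf = sHf, mask = mask)
  })
  warnCounts$waterOutOfRange <- res$sigmaHf@metadata$nOutOfRange
  sayLog("  %d voxels outside the water validity range", warnCounts$waterOutOfRange)

  sayLog("stage csf: threshold sigma_HF at %g S/m", cfg$csfThreshold)
  csf <- csfMaskFromSigma(res$sigmaHf, cfg$csfThreshold)

  sayLog("stage microfit: leave-one-out MIP compartment fit")
  dwi <- stage("microfit input", {
    if (is.null(cfg$bvec) || !file.exists(cfg$bvec))
      stop("bvec file is missing")
    if (is.null(cfg$bval) || !file.exists(cfg$bval))
      stop("bval file is missing")
    readDwi(cfg$dwi, cfg$bval, cfg$bvec)
  })
  fitMask <- if (!is.null(res$mask)) res$mask else
    is.finite(voxelData(res$W))
  fit <- stage("microfit", fitLooMip(dwi, cfg$mdlConst, cfg$control,
                                     mask = fitMask, keepRuns = FALSE))
  warnCounts$fitDegenerate <- fit$report$nDegenerate
  warnCounts$fitNotConverged <- fit$report$nNotConverged
  sayLog("  %d runs x %d voxels; %d degenerate, %d not converged",
         fit$report$nRuns, fit$report$nVoxels,
         fit$report$nDegenerate, fit$report$nNotConverged)

  sayLog("stage impute: cutoff %g labelling + Delaunay refill", cfg$cutoff)
  imp <- stage("impute", {
    vIc <- labelAndImpute(fit$vIc, cutoff = cfg$cutoff, excludeMask = csf,
                          mask = fitMask)
    vIso <- labelAndImpute(fit$vIso, cutoff = cfg$cutoff, mask = fitMask)
    dEStar <- labelAndImpute(fit$dEStar, cutoff = NA, mask = fitMask)
    list(vIc = vIc, vIso = vIso, dEStar = dEStar)
  })
  warnCounts$imputedVic <- imp$vIc@metadata$nInvalid
  warnCounts$imputedViso <- imp$vIso@metadata$nInvalid
  warnCounts$imputedDeStar <- imp$dEStar@metadata$nInvalid

  sayLog("stage lf: derived extracellular parameters")
  lf <- stage("lf", deriveLfParams(imp$vIc, imp$vIso, imp$dEStar,
                                   cfg$mdlConst))

  sayLog("stage tensor: WLS diffusion tensor at b = %g", cfg$tensorShell)
  D <- stage("tensor", fitDiffusionTensor(dwi, cfg$tensorShell,
                                          mask = fitMask))
  warnCounts$flooredSignals <- D@metadata$nFloored
  De <- stage("tensor", extracellularTensor(D, lf$dE))
  Clf <- stage("tensor", conductivityTensor(res$sigmaHf, lf, De,
                                            cfg$ctiConst))
  sigmaLfIso <- stage("tensor", isotropicEquivalent(Clf))
  warnCounts$clampedEigenvalues <- sigmaLfIso@metadata$nClamped

  sayLog("stage write: maps, report, provenance")
  wv <- function(x, nm) writeVolume(x, file.path(cfg$outDir, nm))
  wv(res$W, "W.nii.gz"); wv(res$sigmaHf, "sigma_hf.nii.gz")
  wv(imp$vIc, "v_ic.nii.gz"); wv(imp$vIso, "v_iso.nii.gz")
  wv(imp$dEStar, "d_e_star.nii.gz")
  wv(lf$chiE, "chi_e.nii.gz"); wv(lf$dE, "d_e.nii.gz"); wv(lf$dI, "d_i.nii.gz")
  wv(D, "D.nii.gz"); wv(De, "D_e.nii.gz"); wv(Clf, "C_lf.nii.gz")
  wv(sigmaLfIso, "sigma_lf_iso.nii.gz")
  writeVolume(array(as.numeric(csf), dim(csf)),
              file.path(cfg$outDir, "csf_mask.nii.gz"),
              spacing = voxelSpacing(res$sigmaHf))

  report <- writeReport(sigmaLfIso, res$sigmaHf, csf,
                        gmMask = cfg$gmMask, wmMask = cfg$wmMask,
                        warnCounts = warnCounts,
                        path = file.path(cfg$outDir, "report.json"))

  prov <- list(
    package = "ctimaps",
    version = as.character(packageVersion("ctimaps")),
    timestamp = format(Sys.time()),
    seed = cfg$seed,
    constants = list(water = unclass(cfg$waterParams),
                     hf = unclass(cfg$hfParams),
                     model = unclass(cfg$mdlConst),
                     cti = unclass(cfg$ctiConst),
                     cutoff = cfg$cutoff,
                     csfThreshold = cfg$csfThreshold,
                     tensorShell = cfg$tensorShell),
    optimizer = unclass(cfg$control),
    inputs = cfg[c("se1", "se2", "dwi", "bval", "bvec", "mask",
                   "gmMask", "wmMask")],
    warningCounts = warnCounts)
  jsonlite::write_json(prov, file.path(cfg$outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(logLines, logPath)
  invisible(list(W = res$W, sigmaHf = res$sigmaHf, csfMask = csf,
                 fit = imp, lf = lf, D = D, De = De, Clf = Clf,
                 sigmaLfIso = sigmaLfIso, report = report))
}

#' Write the per-tissue statistics report
#'
#' JSON report with per-tissue mean, population std, CV (%), voxel
#' counts, the GM/WM coefficient of joint variation and the per-stage
#' warning counters. If GM/WM masks are absent the tissue table contains
#' only the CSF row and a notice.
#'
#' @param sigmaLfIso [ScalarVolume-class] isotropic-equivalent LF map
#' @param sigmaHf [ScalarVolume-class] HF map (for the CSF comparison)
#' @param csfMask logical array from [csfMaskFromSigma]
#' @param gmMask,wmMask optional NIfTI paths or logical arrays
#' @param warnCounts named list of warning counters
#' @param path output JSON path (NULL to skip writing)
#' @return the report list, invisibly when written
#' @export
writeReport <- function(sigmaLfIso, sigmaHf, csfMask, gmMask = NULL,
                        wmMask = NULL, warnCounts = list(), path = NULL) {
  loadMask <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.character(m)) voxelData(readVolume(m)) > 0 else
      resolveMask(m, dim(voxelData(sigmaLfIso)))
  }
  gm <- loadMask(gmMask); wm <- loadMask(wmMask)
  masks <- list(CSF = csfMask)
  notice <- NULL
  if (!is.null(gm) && !is.null(wm)) {
    masks <- list(GM = gm & !csfMask, WM = wm & !csfMask, CSF = csfMask)
  } else {
    notice <- "GM/WM masks absent; per-tissue statistics limited to CSF"
  }
  td <- tissueDistributions(sigmaLfIso, masks)
  rep <- list(tissues = td$stats, notice = notice,
              warningCounts = warnCounts)
  if (all(c("GM", "WM") %in% td$stats$tissue)) {
    s <- td$stats
    rep$cjvGmWm <- cjv(s[s$tissue == "GM", ], s[s$tissue == "WM", ])
  }
  csfLf <- mean(voxelData(sigmaLfIso)[csfMask], na.rm = TRUE)
  csfHf <- mean(voxelData(sigmaHf)[csfMask], na.rm = TRUE)
  rep$csfLfOverHf <- csfLf / csfHf
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    return(invisible(rep))
  }
  rep
}
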