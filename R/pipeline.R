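# End-to-end orchestration: specimen map -> color-artifact cut-off ->
# hemorrhage/fold classification -> vessel elimination -> cell extraction ->
# density map -> gradual-extinction selection -> report. Stages without
# mutual dependencies (vessel detection, artifact classification) are
# combined by set operations, so their completion order can never change
# the result; execution here is serial.

#' Pipeline configuration
#'
#' Every default repeats the documented default of the module it
#' configures. The serialized config is echoed into the run report.
#'
#' @param workingDownsample target pyramid downsample (default 8).
#' @param diskRadius specimen-map structuring element radius, in [5, 8].
#' @param trainRadiusPx,testRadiusPx texture neighborhood radii: training
#'   uses a slightly larger radius than testing for higher within-class
#'   data integrity (defaults 12 and 10).
#' @param lbpPoints LBP sampling points (default 16).
#' @param corf CORF configuration from \code{\link{corfConfig}}.
#' @param h extinction depth for immunopositive extraction (L-units).
#' @param hNeg extinction depth for the immunonegative pass (v-units).
#' @param artifactPercent luminance percentage removed by the color
#'   artifact cut-off (default 5).
#' @param artifactGap L-unit gap between minimum and cut-off luminance
#'   that flags an artifact (default 50).
#' @param artifactBand L-unit band above the region minimum excluded from
#'   analysis when an artifact is flagged; near-black foreign matter sits
#'   within a few L-units of the minimum while nuclei lie far above it
#'   (default 10).
#' @param vesselVetoDensity cell markers per pixel above which a vessel
#'   candidate component is vetoed as a nucleus cluster (default 1/150:
#'   one marker per 150 px, far above anything a genuine wall yields).
#' @param rho gradual-extinction penalty strength (default 0.3, FOV-width
#'   distance units).
#' @param nMax hard cap on selected fields (default 20).
#' @param strideFrac candidate grid stride as a fraction of the FOV
#'   (default 0.5).
#' @param coverage minimum tumour coverage per candidate FOV (default 0.5).
#' @param classifierStride grid step of texture classification, pixels
#'   (default: one testing radius).
#' @param seed seed recorded for stages that sample.
#' @param enableClassifier,enableVessels,enableArtifactCutoff stage
#'   toggles for ablation runs.
#' @return validated config list.
#' @export
pipelineConfig <- function(workingDownsample = 8,
                           diskRadius = 6L,
                           trainRadiusPx = 12L, testRadiusPx = 10L,
                           lbpPoints = 16L,
                           corf = corfConfig(),
                           h = 20, hNeg = 10,
                           artifactPercent = 5,
                           artifactGap = 50, artifactBand = 10,
                           vesselVetoDensity = 1 / 150,
                           rho = 0.3, nMax = 20L,
                           strideFrac = 0.5, coverage = 0.5,
                           classifierStride = testRadiusPx,
                           seed = 1L,
                           enableClassifier = TRUE,
                           enableVessels = TRUE,
                           enableArtifactCutoff = TRUE) {
  if (diskRadius < 5 || diskRadius > 8)
    stop("diskRadius must be in [5, 8]", call. = FALSE)
  if (h <= 0 || hNeg <= 0) stop("h values must be positive", call. = FALSE)
  if (rho < 0) stop("rho must be non-negative", call. = FALSE)
  list(workingDownsample = workingDownsample, diskRadius = diskRadius,
       trainRadiusPx = trainRadiusPx, testRadiusPx = testRadiusPx,
       lbpPoints = lbpPoints, corf = corf, h = h, hNeg = hNeg,
       artifactPercent = artifactPercent,
       artifactGap = artifactGap, artifactBand = artifactBand, rho = rho,
       vesselVetoDensity = vesselVetoDensity,
       nMax = as.integer(nMax), strideFrac = strideFrac,
       coverage = coverage, classifierStride = classifierStride,
       seed = as.integer(seed),
       enableClassifier = enableClassifier,
       enableVessels = enableVessels,
       enableArtifactCutoff = enableArtifactCutoff)
}

#' Run the full hot-spot selection pipeline
#'
#' Executes the stages in dependency order on a working-resolution slide
#' and returns the selected hot-spot fields plus all intermediate masks
#' and a QC report. With \code{model = NULL} the hemorrhage/fold
#' classification stage is skipped (equivalent to
#' \code{enableClassifier = FALSE}).
#'
#' @param slide a \linkS4class{SlideImage} (or path readable by
#'   \code{\link{readSlide}}).
#' @param config from \code{\link{pipelineConfig}}.
#' @param model optional trained \linkS4class{CascadeModel}.
#' @return list: \code{hotspots} (\linkS4class{HotspotSet}),
#'   \code{markers}, \code{negMarkers} (\linkS4class{CellMarkerMap}),
#'   \code{masks} (named list of \linkS4class{RegionMask}),
#'   \code{densityMap}, \code{qc} (list).
#' @export
runPipeline <- function(slide, config = pipelineConfig(), model = NULL) {
  if (is.character(slide))
    slide <- readSlide(slide, workingDownsample = config$workingDownsample)
  stopifnot(is(slide, "SlideImage"))
  ds <- downsample(slide)
  h <- dim(pixels(slide))[1]; w <- dim(pixels(slide))[2]
  emptyMask <- function(role) new("RegionMask",
                                  mask = matrix(FALSE, h, w),
                                  role = role, downsample = ds)

  tissue <- buildSpecimenMap(slide, diskRadius = config$diskRadius)
  planes <- colorPlanes(slide)
  fov <- fovGeometry(umPerPx(slide))

  qc <- list(config = config, umPerPx = umPerPx(slide),
             tissueAreaPx = sum(maskData(tissue)))
  if (!any(maskData(tissue))) {
    warning("empty tissue: returning empty result", call. = FALSE)
    empty <- selectHotspots(
      new("DensityMap", counts = matrix(0, 1, 1),
          valid = matrix(FALSE, 1, 1), x0 = 0, y0 = 0,
          fovWidthPx = fov@widthPx, fovHeightPx = fov@heightPx,
          downsample = ds),
      rho = config$rho, nMax = 0L)
    return(list(hotspots = empty, markers = NULL, negMarkers = NULL,
                masks = list(tissue = tissue), densityMap = NULL, qc = qc))
  }

  # color artifact detection on luminance within tissue. The cut-off value
  # is a robust minimum; when the gap to the true minimum flags an
  # artifact, the near-minimum band (foreign near-black matter) is
  # excluded from analysis. Extraction keeps the unclipped plane: well
  # depths are measured from the tissue plateau, and clipping dark nuclei
  # to the 5th percentile would erase sparse immunopositive wells.
  lum <- planes@L
  artifactMask <- emptyMask("artifact")
  artifactFlag <- FALSE
  if (config$enableArtifactCutoff) {
    cut <- colorArtifactCutoff(lum, tissue,
                               percent = config$artifactPercent,
                               gapThreshold = config$artifactGap)
    artifactFlag <- cut$artifactFlag
    if (artifactFlag)
      artifactMask <- new("RegionMask",
                          mask = maskData(tissue) &
                            (lum <= cut$minValue + config$artifactBand),
                          role = "artifact", downsample = ds)
    qc$artifactCutoff <- cut$cutoff
    qc$artifactMin <- cut$minValue
    qc$artifactFlag <- artifactFlag
  }

  # hemorrhage / fold elimination (texture cascade)
  hemorrhage <- emptyMask("hemorrhage")
  fold <- emptyMask("fold")
  if (config$enableClassifier && !is.null(model)) {
    cls <- classifyTissue(planes, tissue, model,
                          radiusPx = config$testRadiusPx,
                          stride = config$classifierStride)
    hemorrhage <- cls$hemorrhage
    fold <- cls$fold
  }

  # vessel wall elimination. At working resolution the texture detectors
  # cannot always tell a thin brown wall from a dense immunopositive
  # cluster, and hot-spot clusters must never be eliminated: a vessel
  # candidate whose area resolves into many separate cell markers in a
  # preliminary extraction pass is vetoed as a nucleus cluster.
  vessel <- emptyMask("vessel")
  if (config$enableVessels) {
    vessel <- detectVessels(planes, tissue, config = config$corf)
    if (any(maskData(vessel))) {
      preMask <- maskData(tissue) & !maskData(hemorrhage) &
        !maskData(fold) & !maskData(artifactMask)
      pre <- extractPositiveCells(lum, preMask, h = config$h)
      vessel <- new("RegionMask",
                    mask = .vetoCellDenseComponents(
                      maskData(vessel), centroids(pre),
                      config$vesselVetoDensity),
                    role = "vessel", downsample = ds)
    }
  }

  # analysis region identity: tissue minus every artifact class
  tumour <- new("RegionMask",
                mask = maskData(tissue) & !maskData(hemorrhage) &
                  !maskData(fold) & !maskData(vessel) &
                  !maskData(artifactMask),
                role = "tissue", downsample = ds)

  markers <- extractPositiveCells(lum, tumour, h = config$h,
                                  artifactFlag = artifactFlag)
  negMarkers <- extractNegativeCells(planes@v, tumour, positives = markers,
                                     h = config$hNeg)
  # the color planes are several full-size float rasters; release them
  # before the density/selection stage on large specimens
  planes <- NULL; lum <- NULL
  gc(FALSE)

  fovArea <- fov@widthPx * fov@heightPx
  areaInFovs <- sum(maskData(tumour)) / fovArea
  fovCircleRadius <- sqrt(fovArea / pi)
  effRadius <- max(EBImage::distmap(maskData(tumour) * 1))
  rhoUsed <- compactnessAdjustedRho(config$rho, areaInFovs,
                                    effRadius / fovCircleRadius)
  nMax <- min(config$nMax, maxHotspotCount(areaInFovs))

  dmap <- densityMap(markers, tumour, fov,
                     stride = c(fov@widthPx * config$strideFrac,
                                fov@heightPx * config$strideFrac),
                     coverage = config$coverage)

  pos <- centroids(markers); neg <- centroids(negMarkers)
  ki67PerField <- function(x0, y0) {
    inRect <- function(p) p[, 1] >= x0 & p[, 1] < x0 + fov@widthPx &
      p[, 2] >= y0 & p[, 2] < y0 + fov@heightPx
    np <- if (nrow(pos)) sum(inRect(pos)) else 0L
    nn <- if (nrow(neg)) sum(inRect(neg)) else 0L
    if (np + nn == 0L) return(NA_real_)
    ki67Index(np, nn)
  }
  hotspots <- selectHotspots(dmap, rho = rhoUsed, nMax = nMax,
                             ki67PerField = ki67PerField)

  qc <- c(qc, list(
    tumourAreaPx = sum(maskData(tumour)),
    areaInFovs = areaInFovs,
    effectiveRadiusInFovRadii = effRadius / fovCircleRadius,
    rhoUsed = rhoUsed, nMaxApplied = nMax,
    hemorrhageAreaPx = sum(maskData(hemorrhage)),
    foldAreaPx = sum(maskData(fold)),
    vesselAreaPx = sum(maskData(vessel)),
    posMarkers = nrow(pos), negMarkers = nrow(neg),
    overallKi67 = if (nrow(pos) + nrow(neg) > 0)
      ki67Index(nrow(pos), nrow(neg)) else NA_real_))

  list(hotspots = hotspots, markers = markers, negMarkers = negMarkers,
       masks = list(tissue = tissue, hemorrhage = hemorrhage, fold = fold,
                    vessel = vessel, artifact = artifactMask,
                    tumour = tumour),
       densityMap = dmap, qc = qc)
}

#' Write pipeline outputs to a directory
#'
#' Writes \code{hotspots.csv} (rank, level-0 rectangle, raw count,
#' penalized score, per-field Ki-67), one PNG per mask, a marker-overlay
#' PNG, and \code{report.json} with the QC block.
#'
#' @param result list from \code{\link{runPipeline}}.
#' @param slide the \linkS4class{SlideImage} that was processed.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writePipelineResult <- function(result, slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(hotspotFields(result$hotspots),
                   file.path(dir, "hotspots.csv"), row.names = FALSE)
  for (nm in names(result$masks))
    png::writePNG(maskData(result$masks[[nm]]) * 1,
                  file.path(dir, paste0("mask_", nm, ".png")))
  px <- pixels(slide) / 255
  f <- hotspotFields(result$hotspots)
  ds <- downsample(slide)
  for (i in seq_len(nrow(f))) {
    x0 <- round(f$x0[i] / ds); y0 <- round(f$y0[i] / ds)
    x1 <- min(ncol(px[, , 1]), x0 + round(f$width[i] / ds))
    y1 <- min(nrow(px[, , 1]), y0 + round(f$height[i] / ds))
    xs <- (x0 + 1):x1; ys <- (y0 + 1):y1
    px[c(ys[1], ys[length(ys)]), xs, 1] <- 1
    px[c(ys[1], ys[length(ys)]), xs, 2:3] <- 0
    px[ys, c(xs[1], xs[length(xs)]), 1] <- 1
    px[ys, c(xs[1], xs[length(xs)]), 2:3] <- 0
  }
  png::writePNG(px, file.path(dir, "overlay.png"))
  jsonlite::write_json(result$qc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
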