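# Central S4 containers. Pixel rasters are stored as base matrices/arrays
# indexed [y + 1, x + 1]; coordinates exposed to the user are 0-based.

.maskRoles <- c("tissue", "hemorrhage", "fold", "vessel", "artifact", "excluded")

#' SlideImage: an RGB raster with physical resolution metadata
#'
#' Holds a working-resolution RGB image together with its physical pixel
#' size (micrometres per pixel) and the pyramid level / downsample factor it
#' was read at. All downstream coordinates are 0-based pixel positions in
#' this raster; level-0 positions are recovered by multiplying with
#' \code{downsample(x)}.
#'
#' @slot pixels numeric array (height x width x 3), 8-bit RGB on the 0-255
#'   scale stored as doubles.
#' @slot umPerPx physical size of one pixel edge, micrometres.
#' @slot level pyramid level the raster was read from (0 = full resolution).
#' @slot downsample downsample factor relative to level 0.
#'
#' @exportClass SlideImage
setClass("SlideImage",
  representation(pixels = "array", umPerPx = "numeric", level = "integer",
                 downsample = "numeric"),
  prototype(level = 0L, downsample = 1)
)

setValidity("SlideImage", function(object) {
  px <- object@pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
    return("umPerPx must be a single positive number")
  if (object@downsample <= 0) return("downsample must be positive")
  TRUE
})

#' FovGeometry: evaluation field-of-view dimensions at a given resolution
#'
#' The microscope-equivalent evaluation rectangle is 1024 x 766 pixels at
#' the reference full resolution of 0.38895 um/px (about 0.12 mm^2, the
#' area of a 400x microscopic field). At other resolutions the rectangle is
#' rescaled and rounded to whole pixels.
#'
#' @slot widthPx,heightPx FOV size in pixels at \code{umPerPx}.
#' @slot umPerPx resolution the geometry is expressed at.
#' @slot areaMm2 physical FOV area in mm^2.
#'
#' @exportClass FovGeometry
setClass("FovGeometry",
  representation(widthPx = "integer", heightPx = "integer",
                 umPerPx = "numeric", areaMm2 = "numeric")
)

#' RegionMask: a labelled binary raster aligned to a SlideImage
#'
#' @slot mask logical matrix, same shape as the source raster.
#' @slot role one of tissue, hemorrhage, fold, vessel, artifact, excluded.
#' @slot downsample downsample factor of the raster the mask aligns to.
#'
#' @exportClass RegionMask
setClass("RegionMask",
  representation(mask = "matrix", role = "character", downsample = "numeric"),
  prototype(downsample = 1)
)

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (length(object@role) != 1L || !object@role %in% .maskRoles)
    return(paste("role must be one of:", paste(.maskRoles, collapse = ", ")))
  TRUE
})

#' ColorPlanes: the color representations the pipeline works on
#'
#' CIE Luv (sRGB companding, D65 white point), naive CMYK, and the
#' composite u*512 + C channel used for texture classification. u is kept
#' on its native CIE scale and C in [0, 1], so the 512 multiplier makes u
#' dominate the composite by construction.
#'
#' @slot L,u,v Luv planes; L in [0, 100].
#' @slot C,M,Y,K CMYK planes in [0, 1].
#' @slot compositeUC elementwise u * 512 + C.
#'
#' @exportClass ColorPlanes
setClass("ColorPlanes",
  representation(L = "matrix", u = "matrix", v = "matrix",
                 C = "matrix", M = "matrix", Y = "matrix", K = "matrix",
                 compositeUC = "matrix")
)

#' SyntheticSpec: parameters of the synthetic slide generator
#'
#' Describes a histology-like scene at working resolution: one or more
#' elliptical tissue lobes on a bright background, immunopositive (brown)
#' and immunonegative (blue) nuclei a few pixels across, optional dense
#' immunopositive clusters, hemorrhage patches, darkened fold bands,
#' thin brown vessel walls and near-black color artifacts.
#'
#' @slot widthPx,heightPx image size in pixels.
#' @slot umPerPx physical resolution (default 8 x 0.38895 um/px).
#' @slot nPosCells,nNegCells background nucleus counts.
#' @slot cellRadiusPx nucleus disk radius in pixels (2-4 at 8x reduction).
#' @slot posClusters list of \code{list(center = c(x, y), radius, n)} dense
#'   immunopositive clusters.
#' @slot tissueEllipses list of \code{list(center = c(x, y), radii = c(a, b))};
#'   empty means one default ellipse covering most of the image.
#' @slot hemorrhageBlobs list of \code{list(center = c(x, y), radius)}.
#' @slot foldBands list of \code{list(polyline = 2-col matrix, width)}.
#' @slot vesselWalls list of \code{list(polyline = 2-col matrix, thickness)}.
#' @slot artifactPixels approximate count of near-black artifact pixels.
#' @slot pinholes list of \code{list(center = c(x, y), radius)} holes punched
#'   in the tissue color (exercises hole filling in the specimen map).
#' @slot backgroundRgb,blurSigma rendering controls.
#' @slot seed RNG seed; identical spec + seed gives bit-identical output.
#'
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(widthPx = "integer", heightPx = "integer", umPerPx = "numeric",
                 nPosCells = "integer", nNegCells = "integer",
                 cellRadiusPx = "numeric", posClusters = "list",
                 tissueEllipses = "list", hemorrhageBlobs = "list",
                 foldBands = "list", vesselWalls = "list",
                 artifactPixels = "integer", pinholes = "list",
                 backgroundRgb = "numeric", blurSigma = "numeric",
                 seed = "integer")
)

#' GroundTruth: complete rendering ground truth for a synthetic slide
#'
#' @slot posCentroids,negCentroids n x 2 matrices of 0-based (x, y) nucleus
#'   centers actually placed (rejection sampling may place fewer than asked;
#'   achieved counts are \code{nrow()} of these).
#' @slot masks named list of \linkS4class{RegionMask}: tissue, hemorrhage,
#'   fold, vessel, artifact.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(posCentroids = "matrix", negCentroids = "matrix",
                 masks = "list")
)

#' CascadeModel: the two-stage SVM artifact classifier
#'
#' Stage 1 separates tumour tissue from hemorrhage/erythrocytes; stage 2 is
#' applied only inside the stage-1 tumour output and flags tissue folds.
#' Each stage carries its own Fisher-selected feature subset.
#'
#' @slot stage1,stage2 trained \code{e1071::svm} objects (Gaussian kernel).
#' @slot featIdx1,featIdx2 selected feature column indices per stage.
#' @slot featureNames full feature vector column names.
#' @slot metadata list: radii, planes, seed, grid-search records.
#'
#' @exportClass CascadeModel
setClass("CascadeModel",
  representation(stage1 = "ANY", stage2 = "ANY",
                 featIdx1 = "integer", featIdx2 = "integer",
                 featureNames = "character", metadata = "list")
)

#' DensityMap: immunopositive-cell counts per candidate FOV position
#'
#' @slot counts matrix of marker counts, rows indexing y positions and
#'   columns x positions of the candidate grid.
#' @slot valid logical matrix; FALSE where the candidate FOV covers too
#'   little of the tumour analysis mask.
#' @slot x0,y0 0-based top-left corners of the candidate FOVs (working px).
#' @slot fovWidthPx,fovHeightPx FOV size at working resolution.
#' @slot downsample downsample factor to map back to level-0 coordinates.
#'
#' @exportClass DensityMap
setClass("DensityMap",
  representation(counts = "matrix", valid = "matrix",
                 x0 = "numeric", y0 = "numeric",
                 fovWidthPx = "integer", fovHeightPx = "integer",
                 downsample = "numeric"),
  prototype(downsample = 1)
)

setValidity("DensityMap", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(dim(object@counts), dim(object@valid)))
    return("counts and valid must have identical shape")
  if (nrow(object@counts) != length(object@y0) ||
      ncol(object@counts) != length(object@x0))
    return("counts shape must match the x0/y0 grid")
  TRUE
})

#' HotspotSet: the ordered result of gradual-extinction selection
#'
#' @slot fields data.frame with one row per selected field, in selection
#'   order: rank, x0, y0, width, height (level-0 pixels), rawCount,
#'   penalizedScore, ki67Index (NA when per-field counting was not run).
#' @slot rho penalty strength actually used (after any compactness
#'   reduction).
#' @slot nMax field cap applied (specimen-size rule).
#'
#' @exportClass HotspotSet
setClass("HotspotSet",
  representation(fields = "data.frame", rho = "numeric", nMax = "integer")
)

setValidity("HotspotSet", function(object) {
  f <- object@fields
  need <- c("rank", "x0", "y0", "width", "height", "rawCount",
            "penalizedScore", "ki67Index")
  if (!all(need %in% names(f))) return("fields is missing required columns")
  if (nrow(f) > 1) {
    if (any(diff(f$rank) <= 0)) return("ranks must be strictly increasing")
    if (anyDuplicated(f[, c("x0", "y0")]))
      return("selected fields must have pairwise distinct positions")
  }
  TRUE
})

#' CellMarkerMap: extracted immunopositive-cell markers
#'
#' @slot centroids n x 2 matrix of 0-based (x, y) marker positions at
#'   working resolution (integer, ties rounded toward smaller coordinates).
#' @slot hValue extinction depth h used by the extended-minima transform.
#' @slot plane identifier of the altitude plane the transform ran on.
#' @slot artifactFlag TRUE when the color-artifact cut-off detected an
#'   individual artifact (gap between minimum and 5th-percentile luminance).
#'
#' @exportClass CellMarkerMap
setClass("CellMarkerMap",
  representation(centroids = "matrix", hValue = "numeric",
                 plane = "character", artifactFlag = "logical")
)

#' AgreementReport: Spearman + Bland-Altman comparison of two series
#'
#' @slot spearmanRho rank correlation in [-1, 1].
#' @slot pValue large-sample t approximation p-value.
#' @slot meanDifference mean of per-case differences (a - b).
#' @slot loaLower,loaUpper limits of agreement, mean +/- 1.96 SD.
#' @slot differences,means per-case plotting data on the chosen scale.
#' @slot scale "linear" or "log".
#'
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(spearmanRho = "numeric", pValue = "numeric",
                 meanDifference = "numeric", loaLower = "numeric",
                 loaUpper = "numeric", differences = "numeric",
                 means = "numeric", scale = "character")
)

setValidity("AgreementReport", function(object) {
  if (abs(object@spearmanRho) > 1 + 1e-12) return("|rho| must be <= 1")
  mid <- (object@loaLower + object@loaUpper) / 2
  if (abs(mid - object@meanDifference) > 1e-8)
    return("limits of agreement must be symmetric about the mean difference")
  TRUE
})
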