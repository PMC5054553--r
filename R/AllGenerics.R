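# Accessor generics. Slots are never touched directly by user code.

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))
#' @export
setGeneric("slideLevel", function(x) standardGeneric("slideLevel"))
#' @export
setGeneric("downsample", function(x) standardGeneric("downsample"))
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @export
setGeneric("hotspotFields", function(x) standardGeneric("hotspotFields"))
#' @export
setGeneric("densityCounts", function(x) standardGeneric("densityCounts"))
#' @export
setGeneric("validCandidates", function(x) standardGeneric("validCandidates"))

#' Accessors for Ki67Hotspot containers
#'
#' \code{pixels} returns the RGB array of a \linkS4class{SlideImage};
#' \code{umPerPx}, \code{slideLevel} and \code{downsample} its resolution
#' metadata. \code{maskData}/\code{maskRole} expose a
#' \linkS4class{RegionMask}. \code{centroids} returns marker positions from
#' a \linkS4class{CellMarkerMap}, \code{hotspotFields} the ordered field
#' table of a \linkS4class{HotspotSet}, and \code{densityCounts}/
#' \code{validCandidates} the grids of a \linkS4class{DensityMap}.
#'
#' @param x the object.
#' @return the slot value described above.
#' @name accessors
#' @aliases pixels umPerPx slideLevel downsample maskData maskRole centroids
#'   hotspotFields densityCounts validCandidates
#' @examples
#' slide <- generateSlide(syntheticSpec(widthPx = 64, heightPx = 48,
#'                                      nPosCells = 0, nNegCells = 0))$slide
#' dim(pixels(slide))
#' umPerPx(slide)
NULL

#' @rdname accessors
setMethod("pixels", "SlideImage", function(x) x@pixels)
#' @rdname accessors
setMethod("umPerPx", "SlideImage", function(x) x@umPerPx)
#' @rdname accessors
setMethod("umPerPx", "FovGeometry", function(x) x@umPerPx)
#' @rdname accessors
setMethod("slideLevel", "SlideImage", function(x) x@level)
#' @rdname accessors
setMethod("downsample", "SlideImage", function(x) x@downsample)
#' @rdname accessors
setMethod("downsample", "RegionMask", function(x) x@downsample)
#' @rdname accessors
setMethod("downsample", "DensityMap", function(x) x@downsample)
#' @rdname accessors
setMethod("maskData", "RegionMask", function(x) x@mask)
#' @rdname accessors
setMethod("maskRole", "RegionMask", function(x) x@role)
#' @rdname accessors
setMethod("centroids", "CellMarkerMap", function(x) x@centroids)
#' @rdname accessors
setMethod("hotspotFields", "HotspotSet", function(x) x@fields)
#' @rdname accessors
setMethod("densityCounts", "DensityMap", function(x) x@counts)
#' @rdname accessors
setMethod("validCandidates", "DensityMap", function(x) x@valid)

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat("SlideImage:", d[2], "x", d[1], "px,",
      signif(object@umPerPx, 6), "um/px (level", object@level,
      ", downsample", object@downsample, ")\n")
})

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask <", object@role, ">: ",
      ncol(object@mask), " x ", nrow(object@mask), " px, ",
      sum(object@mask), " set (",
      signif(100 * mean(object@mask), 3), "%)\n", sep = "")
})

setMethod("show", "FovGeometry", function(object) {
  cat("FovGeometry:", object@widthPx, "x", object@heightPx, "px at",
      signif(object@umPerPx, 6), "um/px =",
      signif(object@areaMm2, 4), "mm^2\n")
})

setMethod("show", "DensityMap", function(object) {
  cat("DensityMap:", ncol(object@counts), "x", nrow(object@counts),
      "candidate FOVs (", sum(object@valid), "valid ), FOV",
      object@fovWidthPx, "x", object@fovHeightPx, "px\n")
})

setMethod("show", "HotspotSet", function(object) {
  cat("HotspotSet:", nrow(object@fields), "field(s), rho =",
      signif(object@rho, 4), ", nMax =", object@nMax, "\n")
  if (nrow(object@fields)) print(utils::head(object@fields, 5))
  if (nrow(object@fields) > 5) cat("...\n")
})

setMethod("show", "CellMarkerMap", function(object) {
  cat("CellMarkerMap:", nrow(object@centroids), "marker(s), h =",
      object@hValue, ", plane =", object@plane,
      if (object@artifactFlag) "(artifact flagged)" else "", "\n")
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel: stage1 tumour-vs-hemorrhage (",
      length(object@featIdx1), " features), stage2 fold-in-tumour (",
      length(object@featIdx2), " features)\n", sep = "")
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport (", object@scale, " scale): rho = ",
      signif(object@spearmanRho, 4), " (p = ",
      format.pval(object@pValue), "), mean difference = ",
      signif(object@meanDifference, 4), ", LoA [",
      signif(object@loaLower, 4), ", ", signif(object@loaUpper, 4),
      "]\n", sep = "")
})
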