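# Immunopositive cell extraction. Nuclei are wells (low values) in the
# luminance plane; the non-immunoreactive region (background plus
# immunonegative cells, whose wells are shallower than h) is recognized as
# the extended regional minima of the inverted plane, and the complement
# within the tumour mask yields one connected component per cell, relocated
# to its centroid. Working with minima of the inverted plane rather than
# maxima avoids overestimating object areas when cells merge.

#' Grayscale morphological reconstruction by dilation
#'
#' Iteratively dilates \code{marker} (8-connectivity) while clamping below
#' \code{mask}, until stability. \code{marker} must be elementwise
#' less than or equal to \code{mask} (it is clamped if not).
#'
#' @param marker,mask numeric matrices of identical shape.
#' @return the reconstructed matrix.
#' @export
reconstructDilation <- function(marker, mask) {
  .sameShape(marker, mask, "marker and mask")
  .reconstructDilationCpp(marker, mask)
}

#' h-minima transform
#'
#' Suppresses all regional minima of depth less than \code{h} via
#' reconstruction by erosion of \code{plane + h} over \code{plane}.
#'
#' @param plane numeric matrix.
#' @param h suppression depth, positive.
#' @return transformed matrix.
#' @export
hMinima <- function(plane, h) {
  if (h <= 0) stop("h must be positive", call. = FALSE)
  -.reconstructDilationCpp(-(plane + h), -plane)
}

#' Extended regional minima
#'
#' Connected regions at least \code{h} deeper than their surroundings:
#' the regional minima of the h-minima transform.
#'
#' @param plane numeric matrix.
#' @param h depth, positive.
#' @param delta plateau tolerance used to detect regional minima of the
#'   transformed (floating point) plane.
#' @return logical matrix.
#' @export
extendedMinima <- function(plane, h, delta = 1e-3) {
  hm <- hMinima(plane, h)
  f <- -hm
  (f - .reconstructDilationCpp(f - delta, f)) > delta / 2
}

#' Color-artifact cut-off on the luminance plane
#'
#' Clips the lowest 5 percent (configurable) of in-region luminance values
#' to the cut-off percentile, protecting color-space transforms and
#' morphological processing from small dark artifacts. An individual
#' artifact is flagged when the gap between the region minimum and the
#' post-cut-off minimum exceeds \code{gapThreshold}.
#'
#' @param luminance L plane (0-100) from \code{\link{rgbToLuv}}.
#' @param regionMask \linkS4class{RegionMask} or logical matrix; must be
#'   non-empty.
#' @param percent percentage of lowest values removed (default 5).
#' @param gapThreshold L-unit gap between the region minimum and the
#'   cut-off value that triggers \code{artifactFlag}. DAB-stained nuclei
#'   span roughly L 30-70 (overlapping nuclei blend a few units deeper),
#'   so a clean slide's gap stays below about 45; near-black foreign
#'   artifacts (L below 10) push it well beyond (default 50).
#' @return list: \code{plane} (clipped), \code{artifactFlag},
#'   \code{cutoff}, \code{minValue}, \code{removedMask},
#'   \code{removedFraction}.
#' @export
colorArtifactCutoff <- function(luminance, regionMask, percent = 5,
                                gapThreshold = 50) {
  m <- if (is(regionMask, "RegionMask")) maskData(regionMask) else regionMask
  .sameShape(luminance, m, "luminance and region mask")
  vals <- luminance[m]
  if (length(vals) == 0L) stop("empty region mask", call. = FALSE)
  k <- ceiling(percent / 100 * length(vals))
  cutoff <- sort(vals, partial = k)[k]
  removed <- m & (luminance < cutoff)
  adjusted <- luminance
  adjusted[removed] <- cutoff
  list(plane = adjusted,
       artifactFlag = (cutoff - min(vals)) > gapThreshold,
       cutoff = cutoff,
       minValue = min(vals),
       removedMask = removed,
       removedFraction = sum(removed) / length(vals))
}

# generic well extractor: objects are connected wells deeper than h.
# The altitude reference is the tissue plateau: values above the in-mask
# capQuantile (bright glass, pinholes, or off-axis structures such as
# DAB-brown pixels on the chroma plane) are clipped to it, otherwise every
# well would be measured from the glass level and h would lose its meaning.
.extractWells <- function(plane, mask, h, delta = 1e-3, capQuantile = 0.8) {
  if (h <= 0) stop("h must be positive", call. = FALSE)
  .sameShape(plane, mask, "plane and mask")
  if (!any(mask))
    return(list(cells = mask, centroids = matrix(numeric(0), 0, 2,
                                                 dimnames = list(NULL, c("x", "y")))))
  cap <- stats::quantile(plane[mask], capQuantile, names = FALSE)
  plane <- pmin(plane, cap)
  g <- -plane
  barrier <- max(g[mask]) + 10 * h   # outside-mask pixels never join a basin
  g[!mask] <- barrier
  emin <- extendedMinima(g, h, delta)
  cells <- mask & !emin
  if (!any(cells))
    return(list(cells = cells, centroids = matrix(numeric(0), 0, 2,
                                                  dimnames = list(NULL, c("x", "y")))))
  lab <- EBImage::bwlabel(cells * 1)
  n <- max(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  xs <- (idx - 1L) %/% nrow(plane)
  ys <- (idx - 1L) %% nrow(plane)
  cx <- .roundHalfDown(tapply(xs, l, mean))
  cy <- .roundHalfDown(tapply(ys, l, mean))
  list(cells = cells,
       centroids = cbind(x = as.numeric(cx), y = as.numeric(cy)))
}

#' Extract immunopositive cell markers
#'
#' Applies the inverse extended-regional-minima transform to the luminance
#' plane restricted to the cleaned tumour mask: the extended minima (depth
#' h on the inverted plane) capture background and immunonegative cells;
#' the complement decomposes into connected components, each emitting its
#' centroid rounded to the nearest pixel (ties toward smaller coordinates).
#' The marker count is non-increasing in \code{h}.
#'
#' @param luminance L plane, after \code{\link{colorArtifactCutoff}}.
#' @param tumourMask \linkS4class{RegionMask} or logical matrix of the
#'   cleaned tumour analysis region.
#' @param h extinction depth in L-units (default 20: deeper than the
#'   immunonegative wells, shallower than DAB-brown nuclei).
#' @param artifactFlag carried into the result for reporting.
#' @param capQuantile in-mask quantile defining the tissue-plateau altitude
#'   reference; brighter pixels (glass, pinholes) are clipped to it so well
#'   depth is measured from the plateau (default 0.8).
#' @return a \linkS4class{CellMarkerMap}.
#' @export
extractPositiveCells <- function(luminance, tumourMask, h = 20,
                                 artifactFlag = FALSE, capQuantile = 0.8) {
  m <- if (is(tumourMask, "RegionMask")) maskData(tumourMask) else tumourMask
  res <- .extractWells(luminance, m, h, capQuantile = capQuantile)
  new("CellMarkerMap", centroids = res$centroids, hValue = h,
      plane = "L", artifactFlag = artifactFlag)
}

#' Extract immunonegative cell markers
#'
#' Companion pass for the substitute Ki-67 ratio: the same well transform
#' on the Luv v plane (blue-yellow chroma axis), where hematoxylin-blue
#' nuclei are wells while DAB-brown nuclei lie above the background level
#' and stay on the minima side. Components overlapping a positive marker
#' are dropped.
#'
#' @param vPlane Luv v plane.
#' @param tumourMask cleaned tumour mask (RegionMask or logical matrix).
#' @param positives \linkS4class{CellMarkerMap} of the positive pass.
#' @param h extinction depth in v-units (default 10).
#' @param capQuantile plateau cap quantile (see
#'   \code{\link{extractPositiveCells}}); on the chroma plane it also
#'   flattens DAB-brown maxima so they cannot become the basin reference.
#' @return a \linkS4class{CellMarkerMap}.
#' @export
extractNegativeCells <- function(vPlane, tumourMask, positives = NULL,
                                 h = 10, capQuantile = 0.8) {
  m <- if (is(tumourMask, "RegionMask")) maskData(tumourMask) else tumourMask
  res <- .extractWells(vPlane, m, h, capQuantile = capQuantile)
  cent <- res$centroids
  if (!is.null(positives) && nrow(centroids(positives)) && nrow(cent)) {
    pos <- centroids(positives)
    minSep2 <- 3^2
    keep <- vapply(seq_len(nrow(cent)), function(i)
      min((pos[, 1] - cent[i, 1])^2 + (pos[, 2] - cent[i, 2])^2) >= minSep2,
      logical(1))
    cent <- cent[keep, , drop = FALSE]
  }
  new("CellMarkerMap", centroids = cent, hValue = h, plane = "v",
      artifactFlag = FALSE)
}

#' Ki-67 index from marker counts
#'
#' The substitute proliferation index on this pipeline's own segmentation:
#' 100 * positives / (positives + negatives).
#'
#' @param posCount,negCount non-negative marker counts; their sum must be
#'   positive.
#' @return percentage in [0, 100].
#' @examples
#' ki67Index(30, 70)  # 30
#' @export
ki67Index <- function(posCount, negCount) {
  if (posCount < 0 || negCount < 0) stop("counts must be non-negative",
                                         call. = FALSE)
  if (posCount + negCount == 0) stop("no cells: Ki-67 index undefined",
                                     call. = FALSE)
  100 * posCount / (posCount + negCount)
}
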