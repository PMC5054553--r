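# Brown-stained vessel wall elimination. Two detectors run on the Y (CMYK)
# plane, where DAB-brown structures are bright: an LBP-gated texture channel
# and a CORF-style contour operator (collinear difference-of-Gaussians
# sub-fields combined by a geometric mean). Their union, cleaned of small
# objects, is the vessel map removed from the analysis region.

#' CORF operator configuration
#'
#' @param nOrientations number of line orientations (>= 4, default 8).
#' @param sigma DoG sub-field scale in pixels (default 2).
#' @param nSubfields number of collinear sub-fields (default 5).
#' @param subfieldSpacing centre-to-centre sub-field distance, pixels
#'   (default 2 * sigma).
#' @param thresholdQuantile in-tissue response quantile used when
#'   binarizing the response (default 0.95).
#' @param minResponse absolute response floor for binarization; on a
#'   vessel-free slide the quantile alone would threshold numerical noise
#'   (default 0.02 in plane units).
#' @return validated config list.
#' @export
corfConfig <- function(nOrientations = 8L, sigma = 2, nSubfields = 5L,
                       subfieldSpacing = 2 * sigma,
                       thresholdQuantile = 0.95, minResponse = 0.02) {
  if (nOrientations < 4L) stop("nOrientations must be >= 4", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (nSubfields < 1L) stop("nSubfields must be >= 1", call. = FALSE)
  if (thresholdQuantile <= 0 || thresholdQuantile >= 1)
    stop("thresholdQuantile must be in (0, 1)", call. = FALSE)
  list(nOrientations = as.integer(nOrientations), sigma = sigma,
       nSubfields = as.integer(nSubfields),
       subfieldSpacing = subfieldSpacing,
       thresholdQuantile = thresholdQuantile, minResponse = minResponse)
}

#' CORF contour response
#'
#' Center-surround contrast (difference of Gaussians, sigma vs 2 sigma,
#' positive part) is evaluated at \code{nSubfields} collinear positions per
#' orientation and combined by a geometric mean, so a sub-field chain only
#' responds where contrast is sustained along a line. The output is the
#' maximum over orientations; it is zero on constant images and invariant
#' to adding a constant to the plane.
#'
#' @param plane single-channel numeric matrix.
#' @param config from \code{\link{corfConfig}}.
#' @return non-negative response matrix.
#' @export
corfResponse <- function(plane, config = corfConfig()) {
  if (!is.matrix(plane)) stop("plane must be a single-channel matrix",
                              call. = FALSE)
  dog <- EBImage::gblur(plane, sigma = config$sigma) -
    EBImage::gblur(plane, sigma = 2 * config$sigma)
  dog <- pmax(dog, 0)
  eps <- 1e-6
  m <- config$nSubfields
  offs <- (seq_len(m) - (m + 1) / 2) * config$subfieldSpacing
  best <- matrix(0, nrow(plane), ncol(plane))
  for (k in seq_len(config$nOrientations)) {
    ang <- pi * (k - 1) / config$nOrientations
    acc <- matrix(0, nrow(plane), ncol(plane))
    for (o in offs) {
      dx <- round(o * cos(ang)); dy <- round(o * sin(ang))
      acc <- acc + log(.shiftMatrix(dog, dx, dy, 0) + eps)
    }
    resp <- exp(acc / m) - eps
    best <- pmax(best, resp)
  }
  pmax(best, 0)
}

#' Vessel candidates from the CORF response
#'
#' Thresholds the response at the configured in-tissue quantile and closes
#' small gaps. Empty tissue or a flat response gives an empty mask.
#'
#' @param plane Y (CMYK) plane.
#' @param tissueMask logical matrix or \linkS4class{RegionMask}.
#' @param config from \code{\link{corfConfig}}.
#' @return logical matrix.
#' @export
vesselsFromCorf <- function(plane, tissueMask, config = corfConfig()) {
  m <- if (is(tissueMask, "RegionMask")) maskData(tissueMask) else tissueMask
  .sameShape(plane, m, "plane and tissue mask")
  out <- matrix(FALSE, nrow(plane), ncol(plane))
  if (!any(m)) return(out)
  resp <- corfResponse(plane, config)
  vals <- resp[m]
  if (diff(range(vals)) < 1e-9) return(out)
  thr <- max(stats::quantile(vals, config$thresholdQuantile, names = FALSE),
             config$minResponse)
  out <- resp > thr & m
  .binClose(out, 1L)
}

#' Vessel candidates from LBP texture on the Y plane
#'
#' An LBP gate (rotation-invariant uniform codes, excluding the flat
#' all-ones pattern) marks locally contrasted pixels; the Y plane masked by
#' the gate is mean-filtered, thresholded by Otsu within tissue (with an
#' absolute response floor guarding the vessel-free case), then opened to
#' drop nucleus-scale specks and closed into coherent walls.
#'
#' @param yPlane Y plane from \code{\link{rgbToCmyk}}.
#' @param tissueMask logical matrix or \linkS4class{RegionMask}.
#' @param lbpRadius,nPoints LBP sampling geometry (default radius 1,
#'   8 points).
#' @param meanFilterSize mean filter side, pixels (default 5).
#' @param minResponse absolute floor on the filtered response; raising it
#'   trades thin-wall sensitivity for fewer false positives (default 0.1).
#' @param openRadius,closeRadius morphology radii; the opening radius must
#'   exceed the nucleus radius so isolated nuclei (bright in Y like any DAB
#'   structure) are erased while walls thicker than about twice the radius
#'   survive (defaults 3 and 2).
#' @param minSpeckPx components below this area are dropped: groups of
#'   merged nuclei that survive the opening are still an order of
#'   magnitude smaller than any coherent wall segment (default 100 px).
#' @return logical matrix.
#' @export
vesselsFromLbp <- function(yPlane, tissueMask, lbpRadius = 1, nPoints = 8L,
                           meanFilterSize = 5L, minResponse = 0.1,
                           openRadius = 3L, closeRadius = 2L,
                           minSpeckPx = 100L) {
  m <- if (is(tissueMask, "RegionMask")) maskData(tissueMask) else tissueMask
  .sameShape(yPlane, m, "Y plane and tissue mask")
  if (!any(m)) return(matrix(FALSE, nrow(yPlane), ncol(yPlane)))
  codes <- lbpCodes(yPlane, lbpRadius, nPoints)
  mapping <- .lbpMapping(nPoints, "uniform_rotation_invariant")
  mapped <- matrix(mapping$map[codes + 1L], nrow(codes), ncol(codes))
  gate <- !is.na(mapped) & mapped != nPoints   # exclude flat all-ones
  likeness <- yPlane * gate
  kern <- matrix(1 / meanFilterSize^2, meanFilterSize, meanFilterSize)
  likeness <- EBImage::filter2(likeness, kern)
  vals <- likeness[m]
  thr <- if (diff(range(vals)) < 1e-9) Inf else otsuThreshold(vals)
  thr <- max(thr, minResponse)
  mask <- likeness > thr & m
  mask <- .binOpen(mask, openRadius)
  mask <- .binClose(mask, closeRadius)
  .dropSmallComponents(mask, minSpeckPx)
}

#' Combine vessel detections into the vessel map
#'
#' Union of the LBP- and CORF-derived masks with connected components
#' smaller than \code{minObjectPx} removed, followed by an elongation
#' filter: vessel walls are thin curvilinear bands (filled area many times
#' the square of their thickness) whereas compact DAB-dense regions -
#' above all genuine hot-spot nucleus clusters, which must never be
#' eliminated - are blob-like. Commutative in its two mask arguments;
#' both cleanup steps are idempotent and anti-extensive.
#'
#' @param lbpMask,corfMask aligned logical matrices.
#' @param minObjectPx minimum component area kept; default the area of a
#'   15-px-diameter disk (smaller than any vessel wall of interest at the
#'   8x working level).
#' @param minElongation minimum filled-area / thickness^2 ratio of a kept
#'   component (a straight band of length L and thickness t scores L/t; a
#'   disk scores about 0.8). Default 3; set 0 to disable.
#' @param downsample provenance recorded in the result.
#' @return a \linkS4class{RegionMask} with role \code{"vessel"}.
#' @export
vesselMap <- function(lbpMask, corfMask, minObjectPx = round(pi * 7.5^2),
                      minElongation = 3, downsample = 1) {
  .sameShape(lbpMask, corfMask, "vessel masks")
  u <- .dropSmallComponents(lbpMask | corfMask, minObjectPx)
  if (minElongation > 0 && any(u)) u <- .keepElongated(u, minElongation)
  new("RegionMask", mask = u, role = "vessel", downsample = downsample)
}

# keep components whose filled area exceeds minElongation * (2 * max
# inscribed radius)^2; computed on cropped bounding boxes
.keepElongated <- function(mask, minElongation) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0) return(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    rows <- (idx - 1L) %% nrow(mask) + 1L
    cols <- (idx - 1L) %/% nrow(mask) + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    sub <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)  # 1-px pad for distmap
    sub[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1
    filled <- EBImage::fillHull(sub)
    rmax <- max(EBImage::distmap(filled))
    if (sum(filled) >= minElongation * (2 * rmax)^2)
      out[idx] <- TRUE
  }
  out
}

#' Detect vessel walls on a slide
#'
#' Convenience wrapper running both detectors on the Y plane and combining
#' them with \code{\link{vesselMap}}.
#'
#' @param planes a \linkS4class{ColorPlanes}.
#' @param tissueMask \linkS4class{RegionMask} or logical matrix.
#' @param config CORF configuration.
#' @param minObjectPx small-structure cut-off (see \code{\link{vesselMap}}).
#' @return a \linkS4class{RegionMask} with role \code{"vessel"}.
#' @export
detectVessels <- function(planes, tissueMask, config = corfConfig(),
                          minObjectPx = round(pi * 7.5^2)) {
  m <- if (is(tissueMask, "RegionMask")) maskData(tissueMask) else tissueMask
  ds <- if (is(tissueMask, "RegionMask")) downsample(tissueMask) else 1
  lbp <- vesselsFromLbp(planes@Y, m)
  corf <- vesselsFromCorf(planes@Y, m, config)
  vesselMap(lbp, corf, minObjectPx, downsample = ds)
}
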