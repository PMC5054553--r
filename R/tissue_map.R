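# Specimen map: black pixels are non-scanned background; the remaining
# region is thresholded on the (B - R) difference with Otsu's method and
# cleaned up by closing, hole filling and small-structure removal.

#' Otsu threshold of a numeric sample
#'
#' Builds a 256-bin histogram spanning the sample range and returns the cut
#' value maximizing the between-class variance. Works on any numeric scale
#' (the B - R difference can be negative); scaling the input scales the
#' threshold by the same factor.
#'
#' @param values numeric vector with at least two distinct values.
#' @param nbins number of histogram bins (default 256).
#' @return the threshold, on the scale of \code{values}; pixels strictly
#'   above it belong to the upper (foreground) class.
#' @examples
#' otsuThreshold(c(rep(0, 50), rep(255, 50)))
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    stop("Otsu threshold undefined: need at least two distinct values",
         call. = FALSE)
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / nbins
  bin <- pmin(floor((values - lo) / width), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  p <- counts / sum(counts)
  # exact per-bin value sums: avoids the quantization bias of bin centres
  sums <- numeric(nbins)
  rs <- rowsum(values, bin)
  sums[as.integer(rownames(rs)) + 1L] <- rs
  w0 <- cumsum(p)
  mu <- cumsum(sums / length(values))
  muT <- mu[nbins]
  # between-class variance for a cut after bin k
  valid <- w0 > 0 & w0 < 1
  sigmaB <- rep(-Inf, nbins)
  sigmaB[valid] <- (muT * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigmaB)
  lo + k * width   # upper edge of the optimal lower class
}

#' Build the specimen (tissue) map of a slide
#'
#' All-black pixels (R = G = B = 0) are treated as the non-scanned region
#' and excluded. The remaining pixels are thresholded on B - R with Otsu's
#' method, then cleaned by morphological closing (dilation followed by
#' erosion with a disk), hole filling, and removal of structures below a
#' minimum area.
#'
#' @param slide a \linkS4class{SlideImage} or RGB array (0-255).
#' @param diskRadius structuring-element radius in pixels; must lie in
#'   [5, 8].
#' @param minAreaPx minimum connected-component area kept, in pixels.
#'   Default: one FOV area at the slide resolution divided by 50, so that
#'   nucleus-scale holes close while genuine inter-lobe gaps survive.
#' @return a \linkS4class{RegionMask} with role \code{"tissue"}.
#' @export
buildSpecimenMap <- function(slide, diskRadius = 6L, minAreaPx = NULL) {
  if (diskRadius < 5 || diskRadius > 8)
    stop("diskRadius must be in [5, 8]", call. = FALSE)
  ds <- 1; ump <- NULL
  if (is(slide, "SlideImage")) {
    ds <- downsample(slide); ump <- umPerPx(slide); px <- pixels(slide)
  } else px <- slide
  .assertRgbArray(px, "slide")
  if (is.null(minAreaPx)) {
    fov <- if (is.null(ump)) fovGeometry(8 * .REF_UM_PER_PX) else fovGeometry(ump)
    minAreaPx <- (fov@widthPx * fov@heightPx) / 50
  }
  nonScanned <- px[, , 1] == 0 & px[, , 2] == 0 & px[, , 3] == 0
  diffBR <- px[, , 3] - px[, , 1]
  vals <- diffBR[!nonScanned]
  emptyMask <- function() {
    warning("empty or constant scanned region: returning empty tissue mask",
            call. = FALSE)
    new("RegionMask", mask = matrix(FALSE, dim(px)[1], dim(px)[2]),
        role = "tissue", downsample = ds)
  }
  if (length(vals) == 0L || diff(range(vals)) == 0) return(emptyMask())
  thr <- otsuThreshold(vals)
  mask <- diffBR > thr & !nonScanned
  mask <- .cleanupMask(mask, diskRadius, minAreaPx)
  mask <- mask & !nonScanned
  new("RegionMask", mask = mask, role = "tissue", downsample = ds)
}

# closing -> hole fill -> small-structure removal; idempotent
.cleanupMask <- function(mask, diskRadius, minAreaPx) {
  mask <- .binClose(mask, diskRadius)
  mask <- EBImage::fillHull(mask * 1) > 0.5
  .dropSmallComponents(mask, minAreaPx)
}
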