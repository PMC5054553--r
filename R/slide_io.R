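# Slide reading and field-of-view geometry. The reference acquisition is a
# 20x lens at 0.38895 um/px with a digitized FOV of 1024 x 766 px (about
# 0.12 mm^2); processing runs at a reduced pyramid level, by default the one
# closest to an eight-fold reduction.

.REF_UM_PER_PX <- 0.38895
.REF_FOV_W <- 1024L
.REF_FOV_H <- 766L

#' Construct a SlideImage from an RGB array
#'
#' @param pixels height x width x 3 RGB array, either 0-255 or 0-1 scale
#'   (0-1 inputs are rescaled to 0-255).
#' @param umPerPx physical pixel size in micrometres.
#' @param level pyramid level provenance (0 = full resolution).
#' @param downsample downsample factor relative to level 0.
#' @return a \linkS4class{SlideImage}.
#' @export
slideImage <- function(pixels, umPerPx, level = 0L, downsample = 1) {
  .assertRgbArray(pixels, "slide")
  if (max(pixels) <= 1 && min(pixels) >= 0) pixels <- pixels * 255
  new("SlideImage", pixels = pixels, umPerPx = as.numeric(umPerPx),
      level = as.integer(level), downsample = as.numeric(downsample))
}

.readRaster <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    px <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    px <- tiff::readTIFF(path)
  } else {
    stop("unsupported raster format: ", path, call. = FALSE)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Read a slide image at (or near) a requested working resolution
#'
#' Plain PNG/TIFF rasters are treated as level-0 images at a user-supplied
#' resolution. Multi-page TIFF files are treated as image pyramids: each
#' page is a level whose downsample factor is the width ratio to page 1,
#' and the level whose downsample is closest to \code{workingDownsample}
#' is returned with \code{umPerPx} scaled accordingly. Black (0,0,0)
#' pixels are preserved: they mark non-scanned regions and are excluded by
#' the specimen map.
#'
#' @param path path to a PNG or (possibly multi-page) TIFF file.
#' @param umPerPx physical pixel size of level 0, micrometres.
#' @param level explicit pyramid level to read (0-based), or \code{NULL} to
#'   auto-select by \code{workingDownsample}.
#' @param workingDownsample target downsample factor (default 8, the
#'   eight-fold reduction the pipeline operates at).
#' @return a \linkS4class{SlideImage}.
#' @export
readSlide <- function(path, umPerPx = .REF_UM_PER_PX, level = NULL,
                      workingDownsample = 8) {
  if (!file.exists(path)) stop("slide file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  pages <- NULL
  if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  if (is.null(pages) || length(pages) == 1L) {
    px <- .readRaster(path)
    if (!is.null(level) && level != 0L)
      stop("level ", level, " unavailable: plain rasters only have level 0",
           call. = FALSE)
    return(slideImage(px, umPerPx, level = 0L, downsample = 1))
  }
  widths <- vapply(pages, function(p) dim(p)[2], numeric(1))
  downs <- widths[1] / widths
  if (is.null(level)) {
    level <- which.min(abs(downs - workingDownsample)) - 1L
  } else if (level < 0L || level >= length(pages)) {
    stop("level ", level, " unavailable: pyramid has levels 0..",
         length(pages) - 1L, call. = FALSE)
  }
  px <- pages[[level + 1L]]
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  ds <- downs[level + 1L]
  slideImage(px * 255, umPerPx * ds, level = as.integer(level),
             downsample = ds)
}

#' Field-of-view geometry at a given resolution
#'
#' Rescales the reference 1024 x 766 px FOV (defined at 0.38895 um/px) to
#' the requested resolution, rounding each axis to the nearest integer, and
#' recomputes the physical area.
#'
#' @param umPerPx physical pixel size in micrometres; must be positive.
#' @return a \linkS4class{FovGeometry}.
#' @examples
#' fovGeometry(0.38895)        # 1024 x 766 px, ~0.12 mm^2
#' fovGeometry(8 * 0.38895)    # 128 x 96 px at the 8x working level
#' @export
fovGeometry <- function(umPerPx) {
  if (!is.numeric(umPerPx) || length(umPerPx) != 1L || umPerPx <= 0)
    stop("umPerPx must be a single positive number", call. = FALSE)
  w <- as.integer(round(.REF_FOV_W * .REF_UM_PER_PX / umPerPx))
  h <- as.integer(round(.REF_FOV_H * .REF_UM_PER_PX / umPerPx))
  new("FovGeometry", widthPx = w, heightPx = h, umPerPx = umPerPx,
      areaMm2 = w * h * (umPerPx / 1000)^2)
}

#' Map working-level pixel coordinates to level-0 coordinates
#'
#' A working-level pixel (x, y) under downsample d covers the level-0
#' half-open rectangle [d*x, d*(x+1)) x [d*y, d*(y+1)).
#'
#' @param x,y 0-based working-level coordinates (vectors allowed).
#' @param downsample downsample factor of the working level.
#' @return matrix with columns x0, y0 (level-0 top-left corners).
#' @export
toLevel0 <- function(x, y, downsample) {
  cbind(x0 = x * downsample, y0 = y * downsample)
}
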