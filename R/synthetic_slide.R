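# Seeded synthetic histology-like slides with complete ground truth. The
# scene emulates what the pipeline must cope with at the 8x working level:
# nuclei a few pixels across with mild blurring, hemorrhage patches, darkened
# compressed-texture fold bands, thin brown vessel walls and near-black color
# artifacts. It is not a staining simulation: colors are flat class palettes
# plus Gaussian noise.

#' Class palette of the synthetic slide generator
#'
#' Named RGB triples (0-255) used to render each scene class. DAB brown and
#' hematoxylin blue hues were picked so that, in CIE Luv luminance,
#' immunopositive nuclei are deep wells (depth > 40 L-units below the tissue
#' plateau) while immunonegative nuclei stay shallow (about 15 L-units), the
#' premise behind the default extinction depth h = 20.
#'
#' @return named list of numeric RGB triples.
#' @examples
#' hotspotPalette()$posNucleus
#' @export
hotspotPalette <- function() {
  list(
    background  = c(246, 244, 242),
    tissue      = c(205, 195, 228),
    posNucleus  = c(100, 60, 30),
    negNucleus  = c(150, 155, 200),
    hemorrhage  = c(160, 70, 55),
    foldFactor  = 0.55,            # multiplicative darkening of fold bands
    vessel      = c(150, 95, 45),
    artifact    = c(8, 8, 8)
  )
}

#' Specification of a synthetic slide
#'
#' Constructor with defaults chosen to emulate an 8x-reduced Ki-67 stained
#' meningioma field: nuclei rendered as anti-aliased disks of radius 2-4 px,
#' Gaussian blur sigma 0.8 px, physical resolution 8 x 0.38895 um/px.
#'
#' @param widthPx,heightPx image size in pixels.
#' @param umPerPx physical resolution (micrometres per pixel).
#' @param nPosCells,nNegCells background (non-cluster) nucleus counts.
#' @param cellRadiusPx nucleus disk radius, pixels (2-4 sensible).
#' @param posClusters list of \code{list(center = c(x, y), radius, n)}.
#' @param tissueEllipses list of \code{list(center = c(x, y), radii = c(a, b))};
#'   empty list means one centred ellipse covering most of the frame.
#' @param hemorrhageBlobs list of \code{list(center = c(x, y), radius)}.
#' @param foldBands list of \code{list(polyline = 2-col matrix, width)}.
#' @param vesselWalls list of \code{list(polyline = 2-col matrix, thickness)}.
#' @param artifactPixels approximate number of near-black artifact pixels.
#' @param pinholes list of \code{list(center = c(x, y), radius)} rendering
#'   holes inside the tissue color (the ground-truth tissue mask keeps them).
#' @param backgroundRgb background RGB triple (0-255).
#' @param blurSigma Gaussian blur sigma in pixels.
#' @param seed RNG seed; identical spec + seed => bit-identical outputs.
#' @return a validated \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(widthPx = 400L, heightPx = 300L,
                          umPerPx = 8 * 0.38895,
                          nPosCells = 50L, nNegCells = 200L,
                          cellRadiusPx = 2.5,
                          posClusters = list(),
                          tissueEllipses = list(),
                          hemorrhageBlobs = list(),
                          foldBands = list(),
                          vesselWalls = list(),
                          artifactPixels = 0L,
                          pinholes = list(),
                          backgroundRgb = hotspotPalette()$background,
                          blurSigma = 0.8,
                          seed = 1L) {
  spec <- new("SyntheticSpec",
    widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
    umPerPx = umPerPx,
    nPosCells = as.integer(nPosCells), nNegCells = as.integer(nNegCells),
    cellRadiusPx = cellRadiusPx, posClusters = posClusters,
    tissueEllipses = tissueEllipses, hemorrhageBlobs = hemorrhageBlobs,
    foldBands = foldBands, vesselWalls = vesselWalls,
    artifactPixels = as.integer(artifactPixels), pinholes = pinholes,
    backgroundRgb = backgroundRgb, blurSigma = blurSigma,
    seed = as.integer(seed))
  .validateSyntheticSpec(spec)
  spec
}

.inBounds <- function(xy, w, h) {
  all(xy[, 1] >= 0 & xy[, 1] <= w - 1 & xy[, 2] >= 0 & xy[, 2] <= h - 1)
}

.validateSyntheticSpec <- function(spec) {
  w <- spec@widthPx; h <- spec@heightPx
  if (w < 8L || h < 8L) stop("image must be at least 8 x 8 px", call. = FALSE)
  if (spec@nPosCells < 0L || spec@nNegCells < 0L || spec@artifactPixels < 0L)
    stop("counts must be non-negative", call. = FALSE)
  if (spec@cellRadiusPx <= 0) stop("cellRadiusPx must be positive", call. = FALSE)
  checkDisk <- function(el, name, i, rname = "radius") {
    c_ <- el$center; r <- el[[rname]]
    if (is.null(c_) || is.null(r) || r <= 0 ||
        !.inBounds(rbind(c_), w, h))
      stop("geometry out of bounds or invalid in ", name, "[[", i, "]]",
           call. = FALSE)
  }
  for (i in seq_along(spec@hemorrhageBlobs))
    checkDisk(spec@hemorrhageBlobs[[i]], "hemorrhageBlobs", i)
  for (i in seq_along(spec@pinholes))
    checkDisk(spec@pinholes[[i]], "pinholes", i)
  for (i in seq_along(spec@posClusters))
    checkDisk(spec@posClusters[[i]], "posClusters", i)
  checkLine <- function(el, name, i, wname) {
    p <- el$polyline
    if (is.null(p) || !is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L ||
        is.null(el[[wname]]) || el[[wname]] <= 0 || !.inBounds(p, w, h))
      stop("geometry out of bounds or invalid in ", name, "[[", i, "]]",
           call. = FALSE)
  }
  for (i in seq_along(spec@foldBands))
    checkLine(spec@foldBands[[i]], "foldBands", i, "width")
  for (i in seq_along(spec@vesselWalls))
    checkLine(spec@vesselWalls[[i]], "vesselWalls", i, "thickness")
  invisible(TRUE)
}

# --- geometric rasterizers (0-based coordinates) ---------------------------

.diskMask <- function(w, h, cx, cy, r) {
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)
  y <- matrix(0:(h - 1), h, w)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

.ellipseMask <- function(w, h, cx, cy, a, b) {
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)
  y <- matrix(0:(h - 1), h, w)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# band of given full width around a polyline
.polylineBand <- function(w, h, polyline, width) {
  mask <- matrix(FALSE, h, w)
  half <- width / 2
  for (s in seq_len(nrow(polyline) - 1L)) {
    p0 <- polyline[s, ]; p1 <- polyline[s + 1L, ]
    xmin <- max(0L, floor(min(p0[1], p1[1]) - half - 1))
    xmax <- min(w - 1L, ceiling(max(p0[1], p1[1]) + half + 1))
    ymin <- max(0L, floor(min(p0[2], p1[2]) - half - 1))
    ymax <- min(h - 1L, ceiling(max(p0[2], p1[2]) + half + 1))
    if (xmin > xmax || ymin > ymax) next
    xs <- xmin:xmax; ys <- ymin:ymax
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) X * 0 else pmin(pmax(((X - p0[1]) * dx + (Y - p0[2]) * dy) / len2, 0), 1)
    d2 <- (X - (p0[1] + t * dx))^2 + (Y - (p0[2] + t * dy))^2
    sub <- mask[ys + 1L, xs + 1L, drop = FALSE]
    mask[ys + 1L, xs + 1L] <- sub | (d2 <= half^2)
  }
  mask
}

# anti-aliased disk stamps for a whole point set at once (integer centres).
# Per-disk subassignment would copy the full canvas matrices on every call;
# here all pixel indices and alphas are built vectorized and each channel is
# touched once, taking the maximum alpha where disks of one batch overlap.
.stampDisks <- function(canvas, pts, r, color) {
  if (is.null(pts) || nrow(pts) == 0L) return(canvas)
  h <- nrow(canvas$R); w <- ncol(canvas$R)
  rad <- as.integer(ceiling(r + 0.5))
  offs <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  a0 <- pmin(pmax(r + 0.5 - sqrt(offs$dx^2 + offs$dy^2), 0), 1)
  keep <- a0 > 0
  offs <- offs[keep, , drop = FALSE]; a0 <- a0[keep]
  n <- nrow(pts); m <- nrow(offs)
  X <- rep(pts[, 1], each = m) + rep(offs$dx, n)
  Y <- rep(pts[, 2], each = m) + rep(offs$dy, n)
  alpha <- rep(a0, n)
  ok <- X >= 0 & X < w & Y >= 0 & Y < h
  idx <- X[ok] * h + Y[ok] + 1
  alpha <- alpha[ok]
  ord <- order(idx, -alpha)
  first <- !duplicated(idx[ord])
  idx <- idx[ord][first]; alpha <- alpha[ord][first]
  for (k in 1:3) {
    ch <- c("R", "G", "B")[k]
    canvas[[ch]][idx] <- alpha * color[k] + (1 - alpha) * canvas[[ch]][idx]
  }
  canvas
}

# rejection-sampled point set inside an allowed mask with minimum spacing;
# returns achieved (x, y) matrix (possibly fewer rows than n)
.placePoints <- function(allowedIdx, w, h, n, minDist, retryFactor = 200L) {
  if (n <= 0L || length(allowedIdx) == 0L) return(matrix(numeric(0), 0, 2))
  s <- max(1, ceiling(minDist / sqrt(2)))
  gw <- ceiling(w / s); gh <- ceiling(h / s)
  occ <- matrix(0L, gh, gw)
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  tries <- 0L; maxTries <- retryFactor * n
  reach <- ceiling(minDist / s)
  while (placed < n && tries < maxTries) {
    tries <- tries + 1L
    idx <- allowedIdx[sample.int(length(allowedIdx), 1L)]
    y <- (idx - 1L) %% h          # column-major: row index - 1
    x <- (idx - 1L) %/% h
    gx <- x %/% s + 1L; gy <- y %/% s + 1L
    ok <- TRUE
    for (ddy in -reach:reach) {
      for (ddx in -reach:reach) {
        gyy <- gy + ddy; gxx <- gx + ddx
        if (gyy < 1L || gyy > gh || gxx < 1L || gxx > gw) next
        j <- occ[gyy, gxx]
        if (j > 0L && (px[j] - x)^2 + (py[j] - y)^2 < minDist^2) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      px[placed] <- x; py[placed] <- y
      occ[gy, gx] <- placed
    }
  }
  cbind(x = px[seq_len(placed)], y = py[seq_len(placed)])
}

# --- generator -------------------------------------------------------------

#' Generate a synthetic slide with ground truth
#'
#' Renders the scene described by \code{spec} (deterministically for a given
#' spec + seed) and returns both the image and the complete ground truth.
#' Nucleus placement uses rejection sampling with a retry cap; the achieved
#' counts are the row counts of the returned centroid matrices.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{slide} (\linkS4class{SlideImage}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' out <- generateSlide(syntheticSpec(nPosCells = 20L, seed = 7L))
#' nrow(out$truth@posCentroids)
#' @export
generateSlide <- function(spec) {
  .validateSyntheticSpec(spec)
  .withSeed(spec@seed, .renderSlide(spec))
}

.renderSlide <- function(spec) {
  w <- spec@widthPx; h <- spec@heightPx
  pal <- hotspotPalette()
  bg <- spec@backgroundRgb
  canvas <- list(R = matrix(bg[1], h, w), G = matrix(bg[2], h, w),
                 B = matrix(bg[3], h, w))

  # tissue lobes
  ell <- spec@tissueEllipses
  if (length(ell) == 0L)
    ell <- list(list(center = c((w - 1) / 2, (h - 1) / 2),
                     radii = c(0.45 * w, 0.44 * h)))
  tissue <- matrix(FALSE, h, w)
  for (e in ell)
    tissue <- tissue | .ellipseMask(w, h, e$center[1], e$center[2],
                                    e$radii[1], e$radii[2])
  nt <- sum(tissue)
  for (k in 1:3) {
    ch <- c("R", "G", "B")[k]
    canvas[[ch]][tissue] <- pal$tissue[k] + stats::rnorm(nt, 0, 2.5)
  }

  # pinholes show background color but stay inside the ground-truth tissue
  for (p in spec@pinholes) {
    dm <- .diskMask(w, h, p$center[1], p$center[2], p$radius)
    for (k in 1:3) canvas[[c("R", "G", "B")[k]]][dm] <- bg[k]
  }

  # hemorrhage: granular red-brown patches
  hem <- matrix(FALSE, h, w)
  for (b in spec@hemorrhageBlobs) {
    dm <- .diskMask(w, h, b$center[1], b$center[2], b$radius)
    hem <- hem | dm
    nd <- sum(dm)
    for (k in 1:3)
      canvas[[c("R", "G", "B")[k]]][dm] <- pal$hemorrhage[k] + stats::rnorm(nd, 0, 9)
    # erythrocyte speckle
    ndots <- max(1L, nd %/% 60L)
    di <- which(dm)[sample.int(nd, min(ndots, nd))]
    for (k in 1:3) canvas[[c("R", "G", "B")[k]]][di] <- pal$hemorrhage[k] * 0.55
  }

  # folds: darkened tissue with duplicated dense nucleus texture
  fold <- matrix(FALSE, h, w)
  for (f in spec@foldBands) {
    bm <- .polylineBand(w, h, f$polyline, f$width)
    fold <- fold | bm
    for (k in 1:3)
      canvas[[c("R", "G", "B")[k]]][bm] <-
        canvas[[c("R", "G", "B")[k]]][bm] * pal$foldFactor
    nExtra <- max(1L, round(sum(bm) / 55))
    bi <- which(bm)
    pts <- bi[sample.int(length(bi), min(nExtra, length(bi)))]
    fx <- (pts - 1L) %/% h; fy <- (pts - 1L) %% h
    dark <- pal$negNucleus * pal$foldFactor
    canvas <- .stampDisks(canvas, cbind(fx, fy), spec@cellRadiusPx * 0.9, dark)
  }

  # vessel walls: thin brown curvilinear bands
  vessel <- matrix(FALSE, h, w)
  for (vw in spec@vesselWalls) {
    bm <- .polylineBand(w, h, vw$polyline, vw$thickness)
    vessel <- vessel | bm
    nd <- sum(bm)
    for (k in 1:3)
      canvas[[c("R", "G", "B")[k]]][bm] <- pal$vessel[k] + stats::rnorm(nd, 0, 5)
  }

  # nucleus placement: inside tissue, away from vessels/pinholes
  margin <- ceiling(spec@cellRadiusPx) + 1L
  blocked <- vessel
  for (p in spec@pinholes)
    blocked <- blocked | .diskMask(w, h, p$center[1], p$center[2],
                                   p$radius + margin)
  if (any(vessel)) blocked <- .binClose(blocked, margin)
  allowed <- tissue & !blocked
  # keep whole disks inside the frame
  allowed[c(seq_len(margin), h - seq_len(margin) + 1L), ] <- FALSE
  allowed[, c(seq_len(margin), w - seq_len(margin) + 1L)] <- FALSE
  allowedIdx <- which(allowed)

  posPts <- matrix(numeric(0), 0, 2)
  for (cl in spec@posClusters) {
    dm <- .diskMask(w, h, cl$center[1], cl$center[2], cl$radius)
    clIdx <- which(dm & allowed)
    pts <- .placePoints(clIdx, w, h, cl$n, 2 * spec@cellRadiusPx + 1)
    posPts <- rbind(posPts, pts)
  }
  posPts <- rbind(posPts,
                  .placePoints(allowedIdx, w, h, spec@nPosCells,
                               2 * spec@cellRadiusPx + 2))
  negPts <- .placePoints(allowedIdx, w, h, spec@nNegCells,
                         2 * spec@cellRadiusPx + 2)
  # drop negatives overlapping a positive nucleus (raster exclusion zone)
  if (nrow(negPts) && nrow(posPts)) {
    zone <- matrix(FALSE, h, w)
    zone[posPts[, 1] * h + posPts[, 2] + 1] <- TRUE
    brushSize <- 2L * as.integer(ceiling(2 * spec@cellRadiusPx + 1)) + 1L
    zone <- EBImage::dilate(zone * 1, EBImage::makeBrush(brushSize, "disc")) > 0.5
    keep <- !zone[negPts[, 2] + 1 + negPts[, 1] * h]
    negPts <- negPts[keep, , drop = FALSE]
  }
  canvas <- .stampDisks(canvas, posPts, spec@cellRadiusPx, pal$posNucleus)
  canvas <- .stampDisks(canvas, negPts, spec@cellRadiusPx, pal$negNucleus)

  # optical blur
  if (spec@blurSigma > 0) {
    for (ch in c("R", "G", "B"))
      canvas[[ch]] <- EBImage::gblur(canvas[[ch]], sigma = spec@blurSigma)
  }

  # color artifacts: compact near-black clusters, post-blur (foreign matter)
  artifact <- matrix(FALSE, h, w)
  if (spec@artifactPixels > 0L) {
    remaining <- spec@artifactPixels
    tIdx <- which(tissue)
    while (remaining > 0L && length(tIdx) > 0L) {
      quota <- min(remaining, 50L)
      seedIdx <- tIdx[sample.int(length(tIdx), 1L)]
      cy <- (seedIdx - 1L) %% h; cx <- (seedIdx - 1L) %/% h
      placedPx <- 0L
      x <- cx; y <- cy
      while (placedPx < quota) {
        if (x >= 0 && x < w && y >= 0 && y < h && !artifact[y + 1L, x + 1L]) {
          artifact[y + 1L, x + 1L] <- TRUE
          placedPx <- placedPx + 1L
        }
        step <- sample.int(4L, 1L)
        x <- x + c(1L, -1L, 0L, 0L)[step]
        y <- y + c(0L, 0L, 1L, -1L)[step]
      }
      remaining <- remaining - quota
    }
    for (k in 1:3) canvas[[c("R", "G", "B")[k]]][artifact] <- pal$artifact[k]
  }

  px <- array(0, c(h, w, 3))
  px[, , 1] <- canvas$R; px[, , 2] <- canvas$G; px[, , 3] <- canvas$B
  px <- round(pmin(pmax(px, 0), 255))

  .checkPaletteSeparation(px, tissue, hem, fold, vessel, artifact, bg)

  masks <- list(
    tissue = new("RegionMask", mask = tissue, role = "tissue"),
    hemorrhage = new("RegionMask", mask = hem, role = "hemorrhage"),
    fold = new("RegionMask", mask = fold, role = "fold"),
    vessel = new("RegionMask", mask = vessel, role = "vessel"),
    artifact = new("RegionMask", mask = artifact, role = "artifact")
  )
  truth <- new("GroundTruth", posCentroids = posPts, negCentroids = negPts,
               masks = masks)
  list(slide = slideImage(px, spec@umPerPx, level = 3L, downsample = 8),
       truth = truth)
}

# every rendered class must stay a minimum color distance from background
.checkPaletteSeparation <- function(px, tissue, hem, fold, vessel, artifact,
                                    bg, minDist = 15) {
  classes <- list(tissue = tissue, hemorrhage = hem, fold = fold,
                  vessel = vessel, artifact = artifact)
  for (nm in names(classes)) {
    m <- classes[[nm]]
    if (!any(m)) next
    mu <- c(mean(px[, , 1][m]), mean(px[, , 2][m]), mean(px[, , 3][m]))
    if (sqrt(sum((mu - bg)^2)) < minDist)
      warning("palette separation below ", minDist, " for class ", nm,
              call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a synthetic slide and its ground truth to disk
#'
#' Writes the rendered image as PNG, one 1-bit PNG mask per class, and a
#' JSON file with centroids and achieved counts.
#'
#' @param generated result of \code{\link{generateSlide}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeSyntheticSlide <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- pixels(generated$slide) / 255
  img <- file.path(dir, "slide.png")
  png::writePNG(px, img)
  paths <- img
  for (nm in names(generated$truth@masks)) {
    p <- file.path(dir, paste0("mask_", nm, ".png"))
    png::writePNG(maskData(generated$truth@masks[[nm]]) * 1, p)
    paths <- c(paths, p)
  }
  gt <- list(
    posCentroids = unname(generated$truth@posCentroids),
    negCentroids = unname(generated$truth@negCentroids),
    achievedPos = nrow(generated$truth@posCentroids),
    achievedNeg = nrow(generated$truth@negCentroids),
    umPerPx = umPerPx(generated$slide)
  )
  jp <- file.path(dir, "groundtruth.json")
  jsonlite::write_json(gt, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
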