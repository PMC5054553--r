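# Local texture descriptors over circular neighborhoods: Unser
# sum/difference-histogram features and local binary patterns. Both are
# computed on a single color plane (typically the composite u*512 + C
# channel); gray levels are quantized to a fixed number of bins computed
# from the global plane range, so descriptors are comparable across
# locations of one plane and invariant to a plane-wide intensity offset
# (Unser: all features except the mean; LBP: fully, by >= thresholding).

.UNSER_NAMES <- c("mean", "variance", "homogeneity", "contrast", "energy",
                  "correlation", "cluster_shade", "cluster_prominence")

# quantize a plane to nGrey levels 0..nGrey-1. The range defaults to the
# plane's global range; classification passes the training range stored in
# the model so quantized units are comparable across slides.
.quantizePlane <- function(plane, nGrey = 64L, range = NULL) {
  if (is.null(range)) {
    lo <- min(plane); hi <- max(plane)
  } else {
    lo <- range[1]; hi <- range[2]
    plane <- pmin(pmax(plane, lo), hi)
  }
  if (hi == lo) {
    list(q = matrix(0L, nrow(plane), ncol(plane)), lo = lo,
         step = 0, nGrey = nGrey)
  } else {
    step <- (hi - lo) / nGrey
    q <- pmin(floor((plane - lo) / step), nGrey - 1L)
    list(q = q, lo = lo, step = step, nGrey = nGrey)
  }
}

# in-disk pixel-pair index offsets for the four unit displacements (cached)
.unserPairCache <- new.env(parent = emptyenv())

.unserPairOffsets <- function(radius) {
  key <- as.character(radius)
  if (!is.null(.unserPairCache[[key]])) return(.unserPairCache[[key]])
  out <- .unserPairCompute(radius)
  .unserPairCache[[key]] <- out
  out
}

.unserPairCompute <- function(radius) {
  off <- .diskOffsets(radius)
  disp <- list(c(1L, 0L), c(1L, -1L), c(0L, 1L), c(1L, 1L))  # 0,45,90,135 deg
  lapply(disp, function(d) {
    a <- off
    b <- data.frame(dx = off$dx + d[1], dy = off$dy + d[2])
    keep <- b$dx^2 + b$dy^2 <= radius^2
    list(a = a[keep, , drop = FALSE], b = b[keep, , drop = FALSE])
  })
}

.unserFromHists <- function(Ps, Pd, sumLevels, diffLevels) {
  muS <- sum(sumLevels * Ps)              # mean of (g1 + g2)
  dev <- sumLevels - muS
  list(
    mean = muS / 2,
    variance = (sum(dev^2 * Ps) + sum(diffLevels^2 * Pd)) / 2,
    homogeneity = sum(Pd / (1 + diffLevels^2)),
    contrast = sum(diffLevels^2 * Pd),
    energy = sum(Ps^2) * sum(Pd^2),
    correlation = (sum(dev^2 * Ps) - sum(diffLevels^2 * Pd)) / 2,
    cluster_shade = sum(dev^3 * Ps),
    cluster_prominence = sum(dev^4 * Ps)
  )
}

#' Unser sum/difference-histogram features of a circular neighborhood
#'
#' Builds normalized histograms of pixel-pair sums and differences over the
#' disk Omega of radius \code{radiusPx} centred at \code{center}, using the
#' four unit displacements (0, 45, 90 and 135 degrees) with both pair
#' endpoints inside Omega, and derives the eight standard features: mean,
#' variance, homogeneity, contrast, energy, correlation, cluster shade and
#' cluster prominence. Averaging over the four displacement orientations
#' gives rotation-robust values. The mean is reported back on the plane's
#' original intensity scale.
#'
#' @param plane numeric matrix (one color plane).
#' @param center 0-based (x, y) of the neighborhood centre.
#' @param radiusPx neighborhood radius in pixels (8-12 typical).
#' @param nGrey number of quantization levels (default 64).
#' @param quant optional precomputed quantization (internal use for grids).
#' @return named numeric vector of the eight features, with attributes
#'   \code{radiusPx} and \code{nGrey}.
#' @examples
#' unserFeatures(matrix(7, 40, 40), center = c(20, 20), radiusPx = 10)
#' @export
unserFeatures <- function(plane, center, radiusPx, nGrey = 64L, quant = NULL) {
  h <- nrow(plane); w <- ncol(plane)
  cx <- center[1]; cy <- center[2]
  if (cx - radiusPx < 0 || cx + radiusPx > w - 1 ||
      cy - radiusPx < 0 || cy + radiusPx > h - 1)
    stop("neighborhood Omega exits the plane; pad or skip this location",
         call. = FALSE)
  if (is.null(quant)) quant <- .quantizePlane(plane, nGrey)
  pairs <- .unserPairOffsets(radiusPx)
  acc <- stats::setNames(numeric(8), .UNSER_NAMES)
  G <- quant$nGrey
  sumLevels <- 0:(2L * (G - 1L))
  diffLevels <- -(G - 1L):(G - 1L)
  for (pp in pairs) {
    ia <- (cx + pp$a$dx) * h + (cy + pp$a$dy) + 1L
    ib <- (cx + pp$b$dx) * h + (cy + pp$b$dy) + 1L
    qa <- quant$q[ia]; qb <- quant$q[ib]
    s <- tabulate(qa + qb + 1L, 2L * G - 1L)
    d <- tabulate(qa - qb + G, 2L * G - 1L)
    Ps <- s / sum(s); Pd <- d / sum(d)
    f <- .unserFromHists(Ps, Pd, sumLevels, diffLevels)
    acc <- acc + unlist(f)[.UNSER_NAMES]
  }
  acc <- acc / length(pairs)
  # report the mean on the original plane scale
  acc["mean"] <- quant$lo + (acc["mean"] + 0.5) * quant$step
  structure(acc, radiusPx = radiusPx, nGrey = quant$nGrey)
}

# --- local binary patterns -------------------------------------------------

# bilinear sample of plane at 0-based fractional (x, y) vectors
.bilinear <- function(plane, x, y) {
  h <- nrow(plane); w <- ncol(plane)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 0), w - 1); y0 <- pmin(pmax(y0, 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  at <- function(xx, yy) plane[xx * h + yy + 1L]
  (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x1, y0) +
    (1 - fx) * fy * at(x0, y1) + fx * fy * at(x1, y1)
}

# per-variant code mapping tables, cached (2^P entries; P = 16 is 65536)
.lbpMappingCache <- new.env(parent = emptyenv())

.lbpMapping <- function(P, variant) {
  key <- paste0(P, ":", variant)
  if (!is.null(.lbpMappingCache[[key]])) return(.lbpMappingCache[[key]])
  out <- .lbpMappingCompute(P, variant)
  .lbpMappingCache[[key]] <- out
  out
}

.lbpMappingCompute <- function(P, variant) {
  codes <- 0:(2^P - 1L)
  bits <- vapply(0:(P - 1L), function(k) bitwAnd(bitwShiftR(codes, k), 1L),
                 integer(length(codes)))
  trans <- rowSums(bits != bits[, c(2:P, 1L), drop = FALSE])
  ones <- rowSums(bits)
  if (variant == "uniform") {
    uni <- which(trans <= 2L)
    map <- rep(length(uni), 2^P)          # non-uniform bin, 0-based last
    map[uni] <- seq_along(uni) - 1L
    nb <- length(uni) + 1L
  } else if (variant == "rotation_invariant") {
    canon <- codes
    full <- 2^P - 1L
    for (r in 1:(P - 1L)) {
      rot <- bitwOr(bitwShiftR(codes, r),
                    bitwAnd(bitwShiftL(codes, P - r), full))
      canon <- pmin(canon, rot)
    }
    uc <- sort(unique(canon))
    map <- match(canon, uc) - 1L
    nb <- length(uc)
  } else if (variant == "uniform_rotation_invariant") {
    map <- ifelse(trans <= 2L, ones, P + 1L)   # riu2: P + 2 bins
    nb <- P + 2L
  } else stop("unknown LBP variant: ", variant, call. = FALSE)
  list(map = as.integer(map), nBins = as.integer(nb))
}

#' Per-pixel LBP codes of a plane
#'
#' Raw circular LBP codes: \code{nPoints} samples on a circle of radius
#' \code{radiusPx}, bilinearly interpolated, thresholded at the centre
#' value with a >= comparison. Pixels whose sampling circle exits the plane
#' are NA.
#'
#' @param plane numeric matrix.
#' @param radiusPx sampling circle radius, pixels.
#' @param nPoints number of sampling points (>= 4).
#' @return integer matrix of raw codes (0 .. 2^nPoints - 1), NA at borders.
#' @export
lbpCodes <- function(plane, radiusPx, nPoints = 8L) {
  if (nPoints < 4L) stop("nPoints must be at least 4", call. = FALSE)
  h <- nrow(plane); w <- ncol(plane)
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  code <- matrix(0, h, w)
  for (k in 0:(nPoints - 1L)) {
    ang <- 2 * pi * k / nPoints
    sx <- as.numeric(X) + radiusPx * cos(ang)
    sy <- as.numeric(Y) - radiusPx * sin(ang)
    val <- .bilinear(plane, sx, sy)
    code <- code + matrix(as.numeric(val >= plane), h, w) * 2^k
  }
  border <- ceiling(radiusPx)
  code[c(seq_len(border), h - seq_len(border) + 1L), ] <- NA
  code[, c(seq_len(border), w - seq_len(border) + 1L)] <- NA
  matrix(as.integer(code), h, w)
}

#' LBP descriptor of a circular neighborhood
#'
#' Computes raw LBP codes with sampling radius \code{radiusPx} for every
#' pixel of the disk Omega (radius \code{omegaRadiusPx}) around
#' \code{center}, maps them per \code{variant} (uniform,
#' rotation-invariant, or uniform rotation-invariant), and returns the
#' normalized histogram.
#'
#' @param plane numeric matrix.
#' @param center 0-based (x, y) centre of Omega.
#' @param radiusPx LBP sampling circle radius (default 12 px).
#' @param nPoints number of sampling points (default 16).
#' @param variant one of \code{"uniform"}, \code{"rotation_invariant"},
#'   \code{"uniform_rotation_invariant"} (default).
#' @param omegaRadiusPx radius of the accumulation disk (defaults to
#'   \code{radiusPx}).
#' @param codes optional precomputed result of \code{\link{lbpCodes}}.
#' @return numeric histogram summing to 1, with attributes \code{radiusPx},
#'   \code{nPoints}, \code{variant}.
#' @export
lbpDescriptor <- function(plane, center, radiusPx = 12, nPoints = 16L,
                          variant = "uniform_rotation_invariant",
                          omegaRadiusPx = radiusPx, codes = NULL) {
  h <- nrow(plane); w <- ncol(plane)
  cx <- center[1]; cy <- center[2]
  pad <- omegaRadiusPx + ceiling(radiusPx)
  if (cx - pad < 0 || cx + pad > w - 1 || cy - pad < 0 || cy + pad > h - 1)
    stop("sampling circles exit the plane for this Omega", call. = FALSE)
  if (is.null(codes)) codes <- lbpCodes(plane, radiusPx, nPoints)
  mapping <- .lbpMapping(nPoints, variant)
  off <- .diskOffsets(omegaRadiusPx)
  idx <- (cx + off$dx) * h + (cy + off$dy) + 1L
  cd <- codes[idx]
  cd <- cd[!is.na(cd)]
  hist <- tabulate(mapping$map[cd + 1L] + 1L, mapping$nBins)
  structure(hist / sum(hist), radiusPx = radiusPx, nPoints = nPoints,
            variant = variant)
}
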