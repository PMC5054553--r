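# Hot-spot field selection. A density map counts immunopositive markers in
# every candidate FOV window; fields are then picked greedily, each pick
# depressing the score of nearby candidates through the gradual-extinction
# penalty
#
#     penalty = 1 - rho * sum_i d_i^(-0.5),   d_i = Euclidean distance to
#                                             selected field i, in FOV widths
#
# clamped below at zero and applied multiplicatively to the raw count, so
# dense specimens yield spatially diversified selections while a strongly
# dominant region keeps all picks.

#' Candidate-FOV density map of cell markers
#'
#' Slides a FOV-sized window over a stride grid and counts markers inside
#' each half-open rectangle. Candidates whose window covers less than
#' \code{coverage} of the tumour mask are marked invalid.
#'
#' @param markers a \linkS4class{CellMarkerMap} or an n x 2 (x, y) matrix.
#' @param tumourMask \linkS4class{RegionMask} or logical matrix.
#' @param fov a \linkS4class{FovGeometry} expressed at the working
#'   resolution.
#' @param stride grid step per axis, pixels; default half the FOV.
#' @param coverage minimum tumour-coverage fraction per candidate
#'   (default 0.5).
#' @return a \linkS4class{DensityMap}.
#' @export
densityMap <- function(markers, tumourMask, fov,
                       stride = NULL, coverage = 0.5) {
  cent <- if (is(markers, "CellMarkerMap")) centroids(markers) else markers
  m <- if (is(tumourMask, "RegionMask")) maskData(tumourMask) else tumourMask
  ds <- if (is(tumourMask, "RegionMask")) downsample(tumourMask) else 1
  fw <- fov@widthPx; fh <- fov@heightPx
  h <- nrow(m); w <- ncol(m)
  if (fw > w || fh > h)
    stop("FOV (", fw, "x", fh, ") larger than the image (", w, "x", h, ")",
         call. = FALSE)
  if (is.null(stride)) stride <- c(fw / 2, fh / 2)
  if (length(stride) == 1L) stride <- c(stride, stride)
  x0 <- seq(0L, w - fw, by = max(1L, round(stride[1])))
  y0 <- seq(0L, h - fh, by = max(1L, round(stride[2])))

  ii <- .integralImage(m * 1)
  counts <- matrix(0, length(y0), length(x0))
  if (nrow(cent)) {
    # bin markers once, then window sums over the marker raster
    mr <- matrix(0, h, w)
    idx <- cbind(pmin(pmax(round(cent[, 2]), 0), h - 1) + 1L,
                 pmin(pmax(round(cent[, 1]), 0), w - 1) + 1L)
    for (i in seq_len(nrow(idx)))
      mr[idx[i, 1], idx[i, 2]] <- mr[idx[i, 1], idx[i, 2]] + 1
    im <- .integralImage(mr)
    for (j in seq_along(x0))
      counts[, j] <- vapply(y0, function(yy)
        .rectSum(im, x0[j], x0[j] + fw, yy, yy + fh), numeric(1))
  }
  cover <- matrix(0, length(y0), length(x0))
  for (j in seq_along(x0))
    cover[, j] <- vapply(y0, function(yy)
      .rectSum(ii, x0[j], x0[j] + fw, yy, yy + fh), numeric(1)) / (fw * fh)
  new("DensityMap", counts = counts, valid = cover >= coverage,
      x0 = as.numeric(x0), y0 = as.numeric(y0),
      fovWidthPx = as.integer(fw), fovHeightPx = as.integer(fh),
      downsample = ds)
}

#' Gradual-extinction penalty of a candidate field
#'
#' \code{1 - rho * sum_i d_i^(-0.5)}, with \code{d_i} the Euclidean
#' distance from the candidate to selected field i in FOV-width units,
#' clamped below at 0. Equals 1 for an empty selected set.
#'
#' @param candidate (x, y) candidate centre, working-resolution pixels.
#' @param selected n x 2 matrix of already-selected centres (may have zero
#'   rows).
#' @param rho penalty strength (default 0.3).
#' @param fovWidthPx FOV width defining the distance unit.
#' @return penalty in [0, 1].
#' @examples
#' hotspotPenalty(c(0, 0), matrix(c(512, 0), 1), rho = 0.3,
#'                fovWidthPx = 128)  # distance 4 FOV: 1 - 0.3/4^0.5 = 0.85
#' @export
hotspotPenalty <- function(candidate, selected, rho = 0.3, fovWidthPx = 128L) {
  if (is.null(selected) || nrow(selected) == 0L) return(1)
  d <- sqrt((selected[, 1] - candidate[1])^2 +
            (selected[, 2] - candidate[2])^2) / fovWidthPx
  if (any(d == 0))
    stop("candidate coincides with an already selected field", call. = FALSE)
  max(0, 1 - rho * sum(d^-0.5))
}

#' Specimen-size cap on the number of hot-spot fields
#'
#' For specimens smaller than 500 FOV-equivalents the number of selected
#' fields is restricted to floor(area * 20 / 500); otherwise the standard
#' 20 fields apply.
#'
#' @param specimenAreaInFovs tumour analysis area divided by the FOV area;
#'   non-negative.
#' @return integer cap.
#' @examples
#' maxHotspotCount(500)  # 20
#' maxHotspotCount(250)  # 10
#' @export
maxHotspotCount <- function(specimenAreaInFovs) {
  if (specimenAreaInFovs < 0) stop("area must be non-negative", call. = FALSE)
  if (specimenAreaInFovs >= 500) return(20L)
  as.integer(floor(specimenAreaInFovs * 20 / 500))
}

#' Compactness adjustment of the penalty strength
#'
#' Low-compactness specimens get a proportionally reduced penalty: the
#' reference margins are 100 FOV of area and six radii of a circle with
#' one FOV's area; rho is scaled by min(1, area/100, radius/6).
#'
#' @param rho nominal penalty strength.
#' @param specimenAreaInFovs specimen area in FOV-equivalents.
#' @param effectiveRadiusInFovRadii specimen effective radius divided by
#'   the radius of a circle with one FOV's area.
#' @return adjusted rho.
#' @examples
#' compactnessAdjustedRho(0.3, 200, 10)  # unchanged
#' compactnessAdjustedRho(0.3, 50, 10)   # halved
#' @export
compactnessAdjustedRho <- function(rho, specimenAreaInFovs,
                                   effectiveRadiusInFovRadii) {
  if (specimenAreaInFovs < 0 || effectiveRadiusInFovRadii < 0)
    stop("inputs must be non-negative", call. = FALSE)
  rho * min(1, specimenAreaInFovs / 100, effectiveRadiusInFovRadii / 6)
}

#' Select hot-spot fields by gradual extinction
#'
#' Iteratively scores every valid candidate as raw count times its current
#' penalty, picks the maximum (ties: higher raw count, then row-major grid
#' order), and repeats until \code{nMax} fields are chosen or no unselected
#' candidate with a positive raw count remains. With \code{rho = 0} this
#' reduces to plain greedy top-k by count.
#'
#' @param dmap a \linkS4class{DensityMap}.
#' @param rho penalty strength (default 0.3), after any compactness
#'   adjustment.
#' @param nMax field cap, e.g. from \code{\link{maxHotspotCount}}
#'   (default 20).
#' @param ki67PerField optional function(x0, y0) returning the per-field
#'   Ki-67 index, evaluated for each selected field.
#' @return a \linkS4class{HotspotSet} with fields in level-0 coordinates.
#' @export
selectHotspots <- function(dmap, rho = 0.3, nMax = 20L, ki67PerField = NULL) {
  cnt <- dmap@counts
  valid <- dmap@valid
  nx <- length(dmap@x0); ny <- length(dmap@y0)
  fw <- dmap@fovWidthPx; fh <- dmap@fovHeightPx
  ds <- dmap@downsample
  emptySet <- function() {
    warning("no valid hot-spot candidates", call. = FALSE)
    new("HotspotSet",
        fields = data.frame(rank = integer(0), x0 = numeric(0),
                            y0 = numeric(0), width = numeric(0),
                            height = numeric(0), rawCount = numeric(0),
                            penalizedScore = numeric(0),
                            ki67Index = numeric(0)),
        rho = rho, nMax = as.integer(nMax))
  }
  if (!any(valid)) return(emptySet())

  # candidate table in row-major grid order (y rows, then x)
  ord <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  ord <- ord[order(ord$iy, ord$ix), ]
  cx <- dmap@x0[ord$ix] + fw / 2
  cy <- dmap@y0[ord$iy] + fh / 2
  raw <- cnt[cbind(ord$iy, ord$ix)]
  ok <- valid[cbind(ord$iy, ord$ix)]

  selIdx <- integer(0)
  penal <- numeric(0)
  selected <- matrix(numeric(0), 0, 2)
  while (length(selIdx) < nMax) {
    avail <- which(ok & raw > 0 & !(seq_along(raw) %in% selIdx))
    if (length(avail) == 0L) break
    pen <- vapply(avail, function(i)
      hotspotPenalty(c(cx[i], cy[i]), selected, rho, fw), numeric(1))
    score <- raw[avail] * pen
    best <- avail[order(-score, -raw[avail], avail)][1]
    selIdx <- c(selIdx, best)
    penal <- c(penal, pen[match(best, avail)] * raw[best])
    selected <- rbind(selected, c(cx[best], cy[best]))
  }
  if (length(selIdx) == 0L) return(emptySet())

  ki <- rep(NA_real_, length(selIdx))
  if (!is.null(ki67PerField))
    ki <- vapply(selIdx, function(i)
      ki67PerField(cx[i] - fw / 2, cy[i] - fh / 2), numeric(1))
  fields <- data.frame(
    rank = seq_along(selIdx),
    x0 = (cx[selIdx] - fw / 2) * ds,
    y0 = (cy[selIdx] - fh / 2) * ds,
    width = fw * ds, height = fh * ds,
    rawCount = raw[selIdx],
    penalizedScore = penal,
    ki67Index = ki)
  new("HotspotSet", fields = fields, rho = rho, nMax = as.integer(nMax))
}
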