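# Internal helpers shared across modules. Matrices are indexed [row = y + 1,
# col = x + 1]; all user-facing coordinates are 0-based with x rightward and
# y downward, rectangles half-open.

#' @useDynLib Ki67Hotspot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.diskOffsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# shift matrix content by (dx, dy) in x/y convention, fill exposed border
.shiftMatrix <- function(m, dx, dy, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# summed-area table with zero-padded first row/col for O(1) rectangle sums
.integralImage <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# sum of m over half-open rectangle [x0, x1) x [y0, y1), 0-based
.rectSum <- function(ii, x0, x1, y0, y1) {
  ii[y1 + 1, x1 + 1] - ii[y0 + 1, x1 + 1] - ii[y1 + 1, x0 + 1] + ii[y0 + 1, x0 + 1]
}

# round halves toward smaller values so centroid ties are reproducible
.roundHalfDown <- function(x) ceiling(x - 0.5)

.assertRgbArray <- function(px, what = "image") {
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop(what, " must be an height x width x 3 RGB array", call. = FALSE)
  invisible(TRUE)
}

.sameShape <- function(a, b, what = "rasters") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(what, " have mismatched shapes (",
         paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

# evaluate expr under a local seed, restoring global RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# connected components (EBImage 4-connectivity label) + area filter
.dropSmallComponents <- function(mask, minPx) {
  if (!any(mask) || minPx <= 1) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minPx)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# drop mask components whose density of (x, y) markers exceeds the cut-off
.vetoCellDenseComponents <- function(mask, markers, densityCutoff) {
  if (!any(mask) || is.null(markers) || nrow(markers) == 0L) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0) return(mask)
  mlab <- lab[cbind(pmin(pmax(round(markers[, 2]), 0), nrow(mask) - 1) + 1L,
                    pmin(pmax(round(markers[, 1]), 0), ncol(mask) - 1) + 1L)]
  counts <- tabulate(mlab[mlab > 0], n)
  sizes <- tabulate(lab[lab > 0], n)
  drop <- which(counts / sizes > densityCutoff)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

.binClose <- function(mask, radius) {
  if (radius < 1) return(mask)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::erode(EBImage::dilate(mask * 1, k), k) > 0.5
}

.binOpen <- function(mask, radius) {
  if (radius < 1) return(mask)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::dilate(EBImage::erode(mask * 1, k), k) > 0.5
}
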