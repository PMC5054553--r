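workingFov <- function() fovGeometry(8 * 0.38895)  # 128 x 96 px

test_that("density map counts markers per window and conserves totals", {
  fov <- workingFov()
  mask <- matrix(TRUE, 480, 640)
  one <- matrix(c(300, 200), 1)
  dm <- densityMap(one, mask, fov)
  hit <- outer(dm@y0, dm@x0, function(y, x)
    300 >= x & 300 < x + 128 & 200 >= y & 200 < y + 96)
  expect_true(all(densityCounts(dm)[hit] == 1))
  expect_true(all(densityCounts(dm)[!hit] == 0))

  # non-overlapping tiling partitions the markers
  set.seed(71)
  pts <- cbind(runif(500, 0, 639.5), runif(500, 0, 479.5))
  tile <- densityMap(pts, mask, fov, stride = c(128, 96))
  expect_equal(sum(densityCounts(tile)), 500)
})

test_that("overlapping-window counts equal a brute-force recount", {
  fov <- workingFov()
  mask <- matrix(TRUE, 300, 400)
  set.seed(72)
  pts <- cbind(runif(200, 0, 399), runif(200, 0, 299))
  dm <- densityMap(pts, mask, fov)
  rp <- cbind(round(pts[, 1]), round(pts[, 2]))  # grid binning as documented
  for (j in seq_along(dm@x0)) for (i in seq_along(dm@y0)) {
    x0 <- dm@x0[j]; y0 <- dm@y0[i]
    want <- sum(rp[, 1] >= x0 & rp[, 1] < x0 + 128 &
                rp[, 2] >= y0 & rp[, 2] < y0 + 96)
    expect_equal(densityCounts(dm)[i, j], want)
  }
  expect_error(densityMap(pts, matrix(TRUE, 50, 50), fov), "larger")
})

test_that("coverage fraction invalidates windows off the tumour mask", {
  fov <- workingFov()
  mask <- matrix(FALSE, 480, 640)
  mask[, 1:300] <- TRUE
  dm <- densityMap(matrix(numeric(0), 0, 2), mask, fov, coverage = 0.5)
  covered <- outer(dm@y0, dm@x0, function(y, x) pmin(x + 128, 300) - x)
  expect_identical(validCandidates(dm), covered / 128 >= 0.5)
})

test_that("penalty evaluates the printed formula and clamps at zero", {
  expect_equal(hotspotPenalty(c(10, 10), matrix(numeric(0), 0, 2)), 1)
  expect_equal(hotspotPenalty(c(0, 0), matrix(c(512, 0), 1), rho = 0.3,
                              fovWidthPx = 128L), 0.85)
  # scalar-loop oracle over several selected fields
  set.seed(73)
  sel <- cbind(runif(5, 0, 1000), runif(5, 0, 1000))
  cand <- c(321, 456)
  want <- 1
  for (i in 1:5) {
    d <- sqrt(sum((sel[i, ] - cand)^2)) / 128
    want <- want - 0.3 / sqrt(d)
  }
  expect_equal(hotspotPenalty(cand, sel, rho = 0.3, fovWidthPx = 128L),
               max(0, want), tolerance = 1e-12)
  expect_error(hotspotPenalty(c(1, 2), matrix(c(1, 2), 1)), "coincides")
})

test_that("specimen-size rules cap the field count", {
  expect_equal(maxHotspotCount(500), 20L)
  expect_equal(maxHotspotCount(1000), 20L)
  expect_equal(maxHotspotCount(250), 10L)
  expect_equal(maxHotspotCount(0), 0L)
  expect_equal(maxHotspotCount(24.9), 0L)
  expect_error(maxHotspotCount(-1), "non-negative")
})

test_that("compactness reduces rho in proportion to the weaker margin", {
  expect_equal(compactnessAdjustedRho(0.3, 200, 10), 0.3)
  expect_equal(compactnessAdjustedRho(0.3, 50, 10), 0.15)
  expect_equal(compactnessAdjustedRho(0.3, 200, 3), 0.15)
  expect_equal(compactnessAdjustedRho(0.3, 25, 1.5), 0.3 * 0.25)
  expect_error(compactnessAdjustedRho(0.3, -1, 2), "non-negative")
})

mkDensity <- function(counts, fw = 128L, fh = 96L, stride = 64) {
  nx <- ncol(counts); ny <- nrow(counts)
  new("DensityMap", counts = counts,
      valid = matrix(TRUE, ny, nx),
      x0 = (seq_len(nx) - 1) * stride, y0 = (seq_len(ny) - 1) * stride,
      fovWidthPx = fw, fovHeightPx = fh, downsample = 1)
}

densityToCand <- function(dm) {
  ord <- expand.grid(ix = seq_along(dm@x0), iy = seq_along(dm@y0))
  ord <- ord[order(ord$iy, ord$ix), ]
  data.frame(cx = dm@x0[ord$ix] + dm@fovWidthPx / 2,
             cy = dm@y0[ord$iy] + dm@fovHeightPx / 2,
             raw = dm@counts[cbind(ord$iy, ord$ix)])
}

test_that("a single positive candidate is selected with its raw score", {
  counts <- matrix(0, 3, 3); counts[2, 2] <- 10
  hs <- selectHotspots(mkDensity(counts), rho = 0.3, nMax = 5)
  f <- hotspotFields(hs)
  expect_equal(nrow(f), 1L)
  expect_equal(f$rawCount, 10)
  expect_equal(f$penalizedScore, 10)
})

test_that("rho = 0 reduces to greedy top-k by count", {
  set.seed(74)
  counts <- matrix(rpois(100, 6), 10, 10)
  dm <- mkDensity(counts)
  hs <- selectHotspots(dm, rho = 0, nMax = 8)
  got <- hotspotFields(hs)$rawCount
  cand <- densityToCand(dm)
  want <- cand$raw[oracleGreedySelect(cand, 0, 8, 128)]
  expect_identical(got, want)
  # sort-based check: the k highest counts, in non-increasing order
  expect_identical(got, sort(cand$raw, decreasing = TRUE)[1:8])
})

test_that("selection matches the explicit greedy-extinction oracle", {
  set.seed(75)
  for (rep_ in 1:3) {
    counts <- matrix(rpois(144, 4), 12, 12)
    dm <- mkDensity(counts)
    cand <- densityToCand(dm)
    for (rho in c(0.1, 0.3, 0.6)) {
      got <- hotspotFields(selectHotspots(dm, rho = rho, nMax = 6))
      sel <- oracleGreedySelect(cand, rho, 6, 128)
      expect_equal(got$x0 + got$width / 2, cand$cx[sel])
      expect_equal(got$y0 + got$height / 2, cand$cy[sel])
    }
  }
})

test_that("equal far-apart clusters alternate; a dominant cluster keeps all", {
  # two tight 2x2 clusters of equal density, 25 FOV widths apart
  counts <- matrix(0, 40, 60)
  counts[3:4, 3:4] <- 50
  counts[3:4, 53:54] <- 50
  dm <- mkDensity(counts)
  f <- hotspotFields(selectHotspots(dm, rho = 0.3, nMax = 4))
  side <- ifelse(f$x0 < 1500, "A", "B")
  expect_equal(sort(table(side), decreasing = TRUE)[[1]], 2L)
  expect_setequal(unique(side), c("A", "B"))
  # oracle agreement
  cand <- densityToCand(dm)
  sel <- oracleGreedySelect(cand, 0.3, 4, 128)
  expect_equal(f$x0 + f$width / 2, cand$cx[sel])
  # with rho = 0 the picks are plain top-k with row-major tie-breaks
  f0 <- hotspotFields(selectHotspots(dm, rho = 0, nMax = 4))
  sel0 <- oracleGreedySelect(cand, 0, 4, 128)
  expect_equal(f0$x0 + f0$width / 2, cand$cx[sel0])

  # dominant spread-out cluster (count 100) vs remote single count-1 cell
  counts2 <- matrix(0, 40, 60)
  counts2[10:18, 10:18] <- 100
  counts2[30, 55] <- 1
  f2 <- hotspotFields(selectHotspots(mkDensity(counts2), rho = 0.3,
                                     nMax = 6))
  expect_true(all(f2$rawCount == 100))
})

test_that("penalized scores never increase along the selection sequence", {
  set.seed(76)
  counts <- matrix(rpois(400, 5), 20, 20)
  f <- hotspotFields(selectHotspots(mkDensity(counts), rho = 0.25,
                                    nMax = 10))
  expect_true(all(diff(f$penalizedScore) <= 1e-9))
  expect_false(any(duplicated(f[, c("x0", "y0")])))
})

test_that("selection is deterministic and warns when nothing qualifies", {
  counts <- matrix(0, 4, 4)
  expect_warning(hs <- selectHotspots(mkDensity(counts), nMax = 3),
                 "no valid")
  expect_equal(nrow(hotspotFields(hs)), 0L)
  set.seed(77)
  counts2 <- matrix(rpois(64, 3), 8, 8)
  a <- selectHotspots(mkDensity(counts2), rho = 0.3, nMax = 5)
  b <- selectHotspots(mkDensity(counts2), rho = 0.3, nMax = 5)
  expect_identical(hotspotFields(a), hotspotFields(b))
})
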