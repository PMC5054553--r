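test_that("artifact cut-off removes five percent up to pixel quantization", {
  set.seed(51)
  for (n in c(997L, 10000L, 4321L)) {
    lum <- matrix(runif(n, 20, 90), nrow = 1)
    mask <- matrix(TRUE, 1, n)
    cut <- colorArtifactCutoff(lum, mask)
    expect_lte(abs(sum(cut$removedMask) - 0.05 * n), 1)
  }
})

test_that("uniform luminance passes the cut-off untouched and unflagged", {
  lum <- matrix(50, 20, 20)
  cut <- colorArtifactCutoff(lum, matrix(TRUE, 20, 20))
  expect_identical(cut$plane, lum)
  expect_false(cut$artifactFlag)
  expect_equal(sum(cut$removedMask), 0L)
})

test_that("near-black outliers all fall inside the removed tail and flag", {
  set.seed(52)
  vals <- c(runif(10000, 60, 90), rep(0, 100))
  lum <- matrix(sample(vals), 101, 100)
  mask <- matrix(TRUE, 101, 100)
  cut <- colorArtifactCutoff(lum, mask)
  expect_true(all(cut$removedMask[lum == 0]))
  expect_true(cut$artifactFlag)
  expect_gte(min(cut$plane[mask]), cut$cutoff)
  expect_error(colorArtifactCutoff(lum, matrix(FALSE, 101, 100)), "empty")
})

wellPlane <- function() {
  p <- matrix(200, 64, 64)
  cent <- expand.grid(x = seq(8, 56, by = 16), y = seq(8, 56, by = 16))[1:12, ]
  for (i in 1:12)
    p[cent$y[i] + 1 + (-1:1), cent$x[i] + 1 + (-1:1)] <- 140
  list(plane = p, centers = cent)
}

test_that("constructed wells are recovered at their centres, gated by h", {
  wp <- wellPlane()
  mask <- matrix(TRUE, 64, 64)
  got <- extractPositiveCells(wp$plane, mask, h = 30)
  expect_equal(nrow(centroids(got)), 12L)
  # centroids within 1 px of the construction centres
  d <- sapply(seq_len(12), function(i)
    min(abs(centroids(got)[, 1] - wp$centers$x[i]) +
          abs(centroids(got)[, 2] - wp$centers$y[i])))
  expect_true(all(d <= 1))
  # h deeper than any well: nothing survives
  expect_equal(nrow(centroids(extractPositiveCells(wp$plane, mask, h = 80))),
               0L)
  expect_error(extractPositiveCells(wp$plane, mask, h = -1), "positive")
})

test_that("wells joined by a shallow saddle merge into one component", {
  p <- matrix(200, 64, 64)
  p[31, 11:21] <- 160                    # saddle channel, 40 below plateau
  p[30:32, 9:11] <- 140                  # wells, 60 below plateau
  p[30:32, 21:23] <- 140
  # cut plane at plateau - h: the channel stays above it, bridging the wells
  got <- extractPositiveCells(p, matrix(TRUE, 64, 64), h = 30)
  expect_equal(nrow(centroids(got)), 1L)
  # deeper h submerges the channel into the minima region: wells separate
  got2 <- extractPositiveCells(p, matrix(TRUE, 64, 64), h = 50)
  expect_equal(nrow(centroids(got2)), 2L)
})

test_that("marker count is non-increasing in h over isolated wells", {
  # twelve isolated wells, four each of depth 20, 40 and 60: increasing h
  # extinguishes them in depth order (saddle-free geometry, where the
  # count-vs-h relation is exact)
  p <- matrix(200, 64, 64)
  cent <- expand.grid(x = seq(8, 56, by = 16), y = seq(8, 56, by = 16))[1:12, ]
  depth <- rep(c(20, 40, 60), each = 4)
  for (i in 1:12)
    p[cent$y[i] + 1 + (-1:1), cent$x[i] + 1 + (-1:1)] <- 200 - depth[i]
  mask <- matrix(TRUE, 64, 64)
  counts <- vapply(c(10, 30, 50, 70), function(h)
    nrow(centroids(extractPositiveCells(p, mask, h = h))), numeric(1))
  expect_equal(counts, c(12, 8, 4, 0))
  expect_true(all(diff(counts) <= 0))
})

test_that("extended minima and cells partition the mask", {
  sl <- cleanSlide(23L)
  m <- maskData(sl$tissue)
  res <- Ki67Hotspot:::.extractWells(sl$planes@L, m, 20)
  cap <- quantile(sl$planes@L[m], 0.8, names = FALSE)
  g <- -pmin(sl$planes@L, cap)
  g[!m] <- max(g[m]) + 200
  emin <- extendedMinima(g, 20)
  expect_true(all((emin | res$cells) | !m))   # union covers the mask
  expect_false(any(emin & res$cells))         # disjoint
})

test_that("h-minima equals the naive reconstruction oracle", {
  set.seed(61)
  for (rep_ in 1:3) {
    plane <- matrix(sample(0:40, 24 * 24, replace = TRUE), 24, 24)
    h <- sample(3:12, 1)
    got <- hMinima(plane, h)
    want <- -oracleReconstruct(-(plane + h), -plane)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # reconstruction wrapper itself
  marker <- matrix(0, 16, 16); marker[8, 8] <- 30
  mask <- matrix(10, 16, 16); mask[4:12, 4:12] <- 25
  expect_equal(reconstructDilation(marker, mask),
               oracleReconstruct(marker, mask))
})

test_that("positive and negative passes agree with the generator truth", {
  sl <- cleanSlide(23L)
  pos <- extractPositiveCells(sl$planes@L, sl$tissue, h = 20)
  neg <- extractNegativeCells(sl$planes@v, sl$tissue, positives = pos,
                              h = 10)
  expect_equal(nrow(centroids(pos)), nrow(sl$truth@posCentroids),
               tolerance = 0.05)
  expect_equal(nrow(centroids(neg)), nrow(sl$truth@negCentroids),
               tolerance = 0.05)
})

test_that("Ki-67 index is the positive fraction with guarded inputs", {
  expect_equal(ki67Index(50, 50), 50)
  expect_equal(ki67Index(0, 100), 0)
  expect_equal(ki67Index(30, 70), 30)
  expect_error(ki67Index(0, 0), "undefined")
  expect_error(ki67Index(-1, 5), "non-negative")
})
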