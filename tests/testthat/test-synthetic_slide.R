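test_that("empty spec renders pure background with empty ground truth", {
  out <- generateSlide(syntheticSpec(widthPx = 64L, heightPx = 48L,
                                     nPosCells = 0L, nNegCells = 0L,
                                     tissueEllipses = list(), blurSigma = 0,
                                     seed = 1L))
  expect_equal(nrow(out$truth@posCentroids), 0L)
  expect_equal(nrow(out$truth@negCentroids), 0L)
  px <- pixels(out$slide)
  bg <- hotspotPalette()$background
  # outside the default tissue ellipse the canvas is exactly background
  outside <- !maskData(out$truth@masks$tissue)
  for (k in 1:3) expect_true(all(px[, , k][outside] == bg[k]))
})

test_that("identical spec and seed give byte-identical outputs", {
  spec <- syntheticSpec(nPosCells = 100L, nNegCells = 50L, seed = 7L,
                        hemorrhageBlobs = list(list(center = c(100, 100),
                                                    radius = 30)),
                        artifactPixels = 60L)
  a <- generateSlide(spec)
  b <- generateSlide(spec)
  expect_identical(pixels(a$slide), pixels(b$slide))
  expect_identical(a$truth@posCentroids, b$truth@posCentroids)
  expect_identical(maskData(a$truth@masks$artifact),
                   maskData(b$truth@masks$artifact))
})

test_that("rendered non-overlapping cells match the flood-fill count", {
  out <- generateSlide(syntheticSpec(widthPx = 300L, heightPx = 200L,
                                     nPosCells = 50L, nNegCells = 0L,
                                     seed = 13L))
  expect_equal(nrow(out$truth@posCentroids), 50L)
  # binarize the red channel: brown nuclei are far darker than tissue
  dark <- pixels(out$slide)[, , 1] < 150
  expect_equal(oracleComponentCount(dark), 50L)
})

test_that("achieved counts are reported when placement saturates", {
  # tiny tissue cannot hold 500 separated nuclei; generator reports what fit
  out <- generateSlide(syntheticSpec(widthPx = 80L, heightPx = 60L,
                                     nPosCells = 500L, seed = 3L))
  expect_lt(nrow(out$truth@posCentroids), 500L)
  expect_gt(nrow(out$truth@posCentroids), 10L)
})

test_that("all centroids lie inside the tissue mask", {
  out <- generateSlide(syntheticSpec(nPosCells = 80L, nNegCells = 120L,
                                     seed = 9L))
  tm <- maskData(out$truth@masks$tissue)
  pts <- rbind(out$truth@posCentroids, out$truth@negCentroids)
  expect_true(all(tm[cbind(pts[, 2] + 1, pts[, 1] + 1)]))
})

test_that("out-of-bounds geometry is rejected naming the element", {
  expect_error(syntheticSpec(hemorrhageBlobs = list(
    list(center = c(50, 50), radius = 10),
    list(center = c(1000, 50), radius = 10))),
    "hemorrhageBlobs\\[\\[2\\]\\]")
  expect_error(syntheticSpec(vesselWalls = list(
    list(polyline = cbind(c(10, 5000), c(10, 20)), thickness = 5))),
    "vesselWalls\\[\\[1\\]\\]")
  expect_error(syntheticSpec(nPosCells = -1L), "non-negative")
})

test_that("rendered class palettes stay separated from background", {
  out <- generateSlide(syntheticSpec(
    widthPx = 400L, heightPx = 300L, nPosCells = 30L, nNegCells = 100L,
    hemorrhageBlobs = list(list(center = c(120, 120), radius = 40)),
    vesselWalls = list(list(polyline = cbind(c(220, 330), c(100, 200)),
                            thickness = 7)),
    artifactPixels = 50L, seed = 17L))
  px <- pixels(out$slide)
  bg <- hotspotPalette()$background
  for (nm in c("tissue", "hemorrhage", "vessel", "artifact")) {
    m <- maskData(out$truth@masks[[nm]])
    mu <- c(mean(px[, , 1][m]), mean(px[, , 2][m]), mean(px[, , 3][m]))
    expect_gt(sqrt(sum((mu - bg)^2)), 15)
  }
})

test_that("writer emits image, masks and ground-truth JSON", {
  out <- generateSlide(syntheticSpec(widthPx = 80L, heightPx = 60L,
                                     nPosCells = 5L, seed = 2L))
  dir <- file.path(tempdir(), "synthout")
  writeSyntheticSlide(out, dir)
  expect_true(file.exists(file.path(dir, "slide.png")))
  expect_true(file.exists(file.path(dir, "mask_tissue.png")))
  gt <- jsonlite::read_json(file.path(dir, "groundtruth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$achievedPos, nrow(out$truth@posCentroids))
})
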