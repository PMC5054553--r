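test_that("CORF response is zero on constant planes and offset-invariant", {
  cc <- corfConfig()
  expect_equal(max(corfResponse(matrix(5, 50, 50), cc)), 0, tolerance = 1e-9)
  set.seed(12)
  plane <- matrix(runif(50 * 50), 50, 50)
  a <- corfResponse(plane, cc)
  b <- corfResponse(plane + 3, cc)
  expect_equal(a, b, tolerance = 1e-6)
  expect_error(corfConfig(nOrientations = 2), ">= 4")
  expect_error(corfConfig(sigma = 0), "positive")
})

test_that("CORF peaks adjacent to a step edge and decays away from it", {
  step <- matrix(0, 60, 60); step[, 31:60] <- 10
  r <- corfResponse(step, corfConfig())
  prof <- apply(r, 2, max)
  peak <- which.max(prof)
  # the positive DoG lobe of a step peaks ~1.4 sigma into the bright side
  expect_gte(peak, 31); expect_lte(peak, 31 + 4)
  expect_lt(prof[45], prof[peak] / 10)
  expect_lt(prof[15], 1e-6)
})

test_that("thresholded CORF recovers a bright curvilinear wall", {
  plane <- matrix(0, 80, 120)
  # diagonal-ish polyline of thickness 3
  xs <- 10:109
  ys <- round(20 + 0.35 * (xs - 10) + 5 * sin(xs / 15))
  for (i in seq_along(xs))
    plane[(ys[i] - 1):(ys[i] + 1) + 1, xs[i] + 1] <- 1
  mask <- matrix(TRUE, 80, 120)
  got <- vesselsFromCorf(plane, mask, corfConfig(minResponse = 0.01))
  centerHit <- mean(got[cbind(ys + 1, xs + 1)])
  expect_gte(centerHit, 0.8)
})

test_that("LBP vessel channel finds thick walls and ignores clean tissue", {
  wall <- withFixture("vesselSlide", function() {
    out <- generateSlide(syntheticSpec(
      widthPx = 400L, heightPx = 300L, nPosCells = 30L, nNegCells = 120L,
      vesselWalls = list(list(polyline = cbind(c(60, 150, 250, 330),
                                               c(80, 140, 120, 200)),
                              thickness = 7)), seed = 11L))
    out$planes <- colorPlanes(out$slide)
    out$tissue <- buildSpecimenMap(out$slide)
    out
  })
  lbp <- vesselsFromLbp(wall$planes@Y, wall$tissue)
  gtv <- maskData(wall$truth@masks$vessel)
  expect_gte(sum(lbp & gtv) / sum(lbp | gtv), 0.5)

  cl <- cleanSlide(12L)
  lbp0 <- vesselsFromLbp(cl$planes@Y, cl$tissue)
  expect_lt(sum(lbp0) / sum(maskData(cl$tissue)), 0.005)

  empty <- matrix(FALSE, 300, 400)
  expect_false(any(vesselsFromLbp(wall$planes@Y, empty)))
})

test_that("vessel map is a commutative union with small-object removal", {
  a <- matrix(FALSE, 60, 60); b <- matrix(FALSE, 60, 60)
  a[10:40, 10:13] <- TRUE          # elongated, 124 px
  b[20:23, 30:59] <- TRUE          # elongated, 120 px
  b[50, 50] <- TRUE                # 1-px speck
  m1 <- vesselMap(a, b, minObjectPx = 20, minElongation = 0)
  m2 <- vesselMap(b, a, minObjectPx = 20, minElongation = 0)
  expect_identical(maskData(m1), maskData(m2))
  expect_equal(oracleComponentCount(maskData(m1)), 2L)
  expect_false(maskData(m1)[50, 50])
  # oracle equivalence on random masks: union then component filtering
  set.seed(33)
  ra <- matrix(runif(40 * 40) < 0.2, 40, 40)
  rb <- matrix(runif(40 * 40) < 0.2, 40, 40)
  got <- maskData(vesselMap(ra, rb, minObjectPx = 5, minElongation = 0))
  u <- ra | rb
  lab <- EBImage::bwlabel(u * 1)
  keep <- which(tabulate(lab[lab > 0]) >= 5)
  expect_identical(got, matrix(lab %in% keep, 40, 40))
  # anti-extensive and idempotent
  expect_true(all(got <= u))
  expect_identical(maskData(vesselMap(got, got, minObjectPx = 5,
                                      minElongation = 0)), got)
  expect_error(vesselMap(a, matrix(FALSE, 10, 10)), "mismatch")
})

test_that("elongation filter keeps bands and drops compact blobs", {
  band <- matrix(FALSE, 80, 80); band[38:44, 5:75] <- TRUE
  blob <- matrix(FALSE, 80, 80)
  blob[Ki67Hotspot:::.diskMask(80, 80, 40, 40, 18)] <- TRUE
  expect_true(any(maskData(vesselMap(band, matrix(FALSE, 80, 80),
                                     minObjectPx = 20))))
  expect_false(any(maskData(vesselMap(blob, matrix(FALSE, 80, 80),
                                      minObjectPx = 20))))
})

test_that("combined detector eliminates the wall from the analysis region", {
  wall <- withFixture("vesselSlide", function() stop("built above"))
  vm <- detectVessels(wall$planes, wall$tissue)
  gtv <- maskData(wall$truth@masks$vessel)
  expect_gte(sum(maskData(vm) & gtv) / sum(maskData(vm) | gtv), 0.5)
})
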