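test_that("constant regions give degenerate Unser features", {
  f <- unserFeatures(matrix(7, 40, 40), center = c(20, 20), radiusPx = 10)
  expect_equal(unname(f["mean"]), 7)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["homogeneity"]), 1)
})

test_that("Unser features equal the pair-enumeration oracle", {
  set.seed(21)
  cases <- list(
    matrix(sample(c(0, 255), 32 * 32, replace = TRUE), 32, 32),  # checkerboard-like
    matrix((outer(1:32, 1:32, "+") %% 2) * 255, 32, 32),         # exact checkerboard
    matrix(runif(32 * 32, 0, 100), 32, 32))
  for (plane in cases) {
    got <- unserFeatures(plane, center = c(15, 15), radiusPx = 9)
    q <- Ki67Hotspot:::.quantizePlane(plane)
    want <- oracleUnser(q$q, 15, 15, 9, q$lo, q$step)
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-9)
  }
})

test_that("intensity offset shifts only the Unser mean", {
  set.seed(5)
  plane <- matrix(runif(40 * 40, 10, 60), 40, 40)
  a <- unserFeatures(plane, c(20, 20), 10)
  b <- unserFeatures(plane + 17, c(20, 20), 10)
  expect_equal(unname(b["mean"] - a["mean"]), 17, tolerance = 1e-9)
  for (nm in c("variance", "contrast", "energy", "homogeneity",
               "correlation", "cluster_shade", "cluster_prominence"))
    expect_equal(unname(a[nm]), unname(b[nm]), tolerance = 1e-9)
})

test_that("Omega exiting the plane raises a boundary error", {
  expect_error(unserFeatures(matrix(0, 20, 20), c(3, 10), 8), "Omega")
  expect_error(lbpDescriptor(matrix(0, 20, 20), c(10, 10), radiusPx = 8),
               "exit")
})

test_that("LBP codes equal a naive per-pixel loop oracle", {
  set.seed(31)
  plane <- matrix(runif(16 * 16), 16, 16)
  for (geom in list(c(1, 8), c(2, 12))) {
    r <- geom[1]; P <- geom[2]
    codes <- lbpCodes(plane, r, P)
    for (y in c(3L, 7L, 12L)) for (x in c(3L, 8L, 12L)) {
      expect_equal(codes[y + 1, x + 1], oracleLbpCode(plane, x, y, r, P))
    }
  }
})

test_that("riu2 histogram of a constant image is all-ones-pattern mass", {
  d <- lbpDescriptor(matrix(4, 40, 40), c(20, 20), radiusPx = 3,
                     nPoints = 8L, omegaRadiusPx = 10)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  # all samples >= centre everywhere: riu2 code 8 ("all bits set")
  expect_equal(unname(d[9]), 1)
})

test_that("rotation-invariant histograms survive a 90-degree rotation", {
  set.seed(41)
  n <- 41  # odd size: the grid centre (20, 20) is the rotation fixed point
  plane <- matrix(runif(n * n), n, n)
  rot <- t(plane)[, rev(seq_len(n))]  # 90-degree rotation
  for (variant in c("rotation_invariant", "uniform_rotation_invariant")) {
    a <- lbpDescriptor(plane, c(20, 20), radiusPx = 2,
                       nPoints = 8L, variant = variant, omegaRadiusPx = 12)
    b <- lbpDescriptor(rot, c(20, 20), radiusPx = 2,
                       nPoints = 8L, variant = variant, omegaRadiusPx = 12)
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
  }
})

test_that("riu2 mapping matches the bit-level oracle and bin count", {
  m <- Ki67Hotspot:::.lbpMapping(8L, "uniform_rotation_invariant")
  expect_equal(m$nBins, 10L)  # P + 2
  for (code in c(0L, 1L, 3L, 7L, 15L, 255L, 86L, 170L))
    expect_equal(m$map[code + 1], oracleRiu2(code, 8L))
})

test_that("descriptors accept independent training and testing radii", {
  set.seed(6)
  plane <- matrix(runif(64 * 64, 0, 50), 64, 64)
  train <- lbpDescriptor(plane, c(32, 32), radiusPx = 12, nPoints = 16L)
  test_ <- lbpDescriptor(plane, c(32, 32), radiusPx = 10, nPoints = 16L,
                         omegaRadiusPx = 10)
  expect_equal(length(train), length(test_))  # same histogram layout
  expect_equal(sum(train), 1, tolerance = 1e-9)
  expect_equal(sum(test_), 1, tolerance = 1e-9)
  expect_error(lbpDescriptor(plane, c(32, 32), nPoints = 3L), "at least 4")
})
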