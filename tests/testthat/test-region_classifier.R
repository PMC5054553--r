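test_that("Fisher score matches hand arithmetic and its invariances", {
  expect_equal(fisherScore(c(0, 1, 2, 3), c("a", "a", "b", "b")), 8)
  set.seed(2)
  x <- c(rnorm(20), rnorm(20))
  lab <- rep(c("p", "q"), each = 20)
  expect_equal(fisherScore(x, lab), fisherScore(x * 10, lab),
               tolerance = 1e-6)
  expect_equal(fisherScore(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0)
  expect_error(fisherScore(1:4, rep("a", 4)), "two classes")
  expect_error(fisherScore(1:3, c("a", "b", "b")), "at least two samples")
})

test_that("linearly separable classes train to perfect accuracy", {
  set.seed(14)
  n <- 60
  df <- data.frame(
    f1 = c(rnorm(n, 0, 0.3), rnorm(n, 5, 0.3), rnorm(n, 0, 0.3)),
    f2 = c(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3), rnorm(n, 5, 0.3)),
    label = rep(c("tumour", "hemorrhage", "fold"), each = n))
  model <- trainCascade(df, topK = 2L, seed = 1L)
  X <- as.matrix(df[, c("f1", "f2")])
  p1 <- predict(model@stage1,
                X[df$label != "fold", model@featIdx1, drop = FALSE])
  expect_equal(mean(p1 == ifelse(df$label[df$label != "fold"] == "hemorrhage",
                                 "hemorrhage", "tumour")), 1)
  expect_gte(model@metadata$stage1$heldOutAccuracy, 0.99)
})

test_that("cascade training is reproducible and serializable", {
  fx <- trainedCascade()
  again <- trainCascade(fx$samples, seed = 5L)
  expect_identical(fx$model@featIdx1, again@featIdx1)
  expect_identical(fx$model@featIdx2, again@featIdx2)
  expect_identical(fx$model@stage1$coefs, again@stage1$coefs)

  path <- file.path(tempdir(), "cascade.rds")
  saveCascade(fx$model, path)
  loaded <- loadCascade(path)
  expect_identical(loaded@featureNames, fx$model@featureNames)
})

test_that("training rejects missing or undersized classes", {
  df <- data.frame(f1 = rnorm(80), f2 = rnorm(80),
                   label = rep(c("tumour", "hemorrhage"), each = 40))
  expect_error(trainCascade(df), "fold")
  df2 <- data.frame(f1 = rnorm(70), f2 = rnorm(70),
                    label = rep(c("tumour", "hemorrhage", "fold"),
                                c(30, 30, 10)))
  expect_error(trainCascade(df2), "at least 30")
})

test_that("held-out accuracy reaches 0.9 per stage on synthetic textures", {
  fx <- trainedCascade()
  expect_gte(fx$model@metadata$stage1$heldOutAccuracy, 0.9)
  expect_gte(fx$model@metadata$stage2$heldOutAccuracy, 0.9)
})

test_that("classification recovers hemorrhage and fold regions on a fresh slide", {
  fx <- trainedCascade()
  te <- artifactSlide(22L)
  cls <- classifyTissue(te$planes, te$tissue, fx$model)
  gth <- maskData(te$truth@masks$hemorrhage)
  gtf <- maskData(te$truth@masks$fold)
  hm <- maskData(cls$hemorrhage); fm <- maskData(cls$fold)
  expect_gte(sum(hm & gth) / sum(hm | gth), 0.7)
  expect_gte(sum(fm & gtf) / sum(fm | gtf), 0.5)
  # cascade structure: masks disjoint, tumour excludes both
  expect_false(any(hm & fm))
  expect_false(any(maskData(cls$tumour) & (hm | fm)))
  expect_true(all((maskData(cls$tumour) | hm | fm) == maskData(te$tissue)))
})

test_that("artifact-free slides stay essentially unflagged", {
  fx <- trainedCascade()
  cl <- cleanSlide(23L)
  cls <- classifyTissue(cl$planes, cl$tissue, fx$model)
  tissueArea <- sum(maskData(cl$tissue))
  expect_lt(sum(maskData(cls$hemorrhage)) / tissueArea, 0.01)
  expect_lt(sum(maskData(cls$fold)) / tissueArea, 0.01)
})

test_that("empty tissue mask classifies to empty outputs", {
  fx <- trainedCascade()
  cl <- cleanSlide(23L)
  empty <- matrix(FALSE, nrow(cl$planes@L), ncol(cl$planes@L))
  cls <- classifyTissue(cl$planes, empty, fx$model)
  expect_false(any(maskData(cls$hemorrhage)))
  expect_false(any(maskData(cls$fold)))
  expect_false(any(maskData(cls$tumour)))
})
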