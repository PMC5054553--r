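# Shared seeded fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

withFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# medium slide with hemorrhage blob and fold band (training scene)
artifactSlide <- function(seed = 21L) {
  withFixture(paste0("artifact", seed), function() {
    out <- generateSlide(syntheticSpec(
      widthPx = 600L, heightPx = 450L, nPosCells = 60L, nNegCells = 400L,
      hemorrhageBlobs = list(list(center = c(150, 120), radius = 70)),
      foldBands = list(list(polyline = cbind(c(320, 420, 520),
                                             c(330, 280, 350)), width = 64)),
      seed = seed))
    out$planes <- colorPlanes(out$slide)
    out$tissue <- buildSpecimenMap(out$slide)
    out
  })
}

# cascade trained on the seed-21 artifact slide
trainedCascade <- function() {
  withFixture("cascade", function() {
    tr <- artifactSlide(21L)
    masks <- list(
      tumour = maskData(tr$tissue) &
        !maskData(tr$truth@masks$hemorrhage) &
        !maskData(tr$truth@masks$fold),
      hemorrhage = maskData(tr$truth@masks$hemorrhage),
      fold = maskData(tr$truth@masks$fold))
    samp <- sampleTextureVectors(tr$planes, masks, n = 100L,
                                 radiusPx = 12L, seed = 5L)
    list(model = trainCascade(samp, seed = 5L), samples = samp)
  })
}

# clean slide without artifacts
cleanSlide <- function(seed = 23L) {
  withFixture(paste0("clean", seed), function() {
    out <- generateSlide(syntheticSpec(
      widthPx = 400L, heightPx = 300L, nPosCells = 40L, nNegCells = 160L,
      seed = seed))
    out$planes <- colorPlanes(out$slide)
    out$tissue <- buildSpecimenMap(out$slide)
    out
  })
}

# the large specimen used for the 20-field selection check: one elliptical
# lobe of ~529 FOV-equivalents with 51 dense immunopositive clusters
largeSpecimenResult <- function() {
  withFixture("largeSpecimen", function() {
    w <- 3800L; h <- 2750L
    gx <- seq(0.14, 0.86, length.out = 9)
    gy <- seq(0.16, 0.84, length.out = 7)
    cent <- expand.grid(x = gx * w, y = gy * h)
    inside <- ((cent$x - w / 2) / (0.88 * 0.45 * w))^2 +
      ((cent$y - h / 2) / (0.88 * 0.44 * h))^2 <= 1
    cent <- cent[inside, ]
    clusters <- lapply(seq_len(nrow(cent)), function(i)
      list(center = c(cent$x[i], cent$y[i]), radius = 45, n = 70))
    spec <- syntheticSpec(widthPx = w, heightPx = h,
                          nPosCells = 2000L, nNegCells = 12000L,
                          posClusters = clusters, seed = 1L)
    slide <- generateSlide(spec)$slide
    res <- runPipeline(slide, config = pipelineConfig())
    # keep only the scalars and the field table: the full result holds
    # half a dozen 10-megapixel masks
    out <- list(fields = hotspotFields(res$hotspots),
                areaInFovs = res$qc$areaInFovs,
                nMaxApplied = res$qc$nMaxApplied,
                nClusters = nrow(cent))
    rm(res, slide); gc(FALSE)
    out
  })
}
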