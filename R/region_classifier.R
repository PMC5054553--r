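# Artifact region classification: Fisher's linear discriminant ranks the
# texture features; two Gaussian-kernel SVMs run in cascade - stage 1
# separates tumour tissue from hemorrhage/erythrocytes, stage 2 flags folds
# inside the stage-1 tumour output. Feature vectors are Unser features plus
# an LBP histogram on the composite u*512 + C plane.

#' Fisher discriminant score of a single feature
#'
#' \eqn{(\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2 + \epsilon)} with
#' population variances and a 1e-12 guard. Zero when the class means are
#' equal; invariant to affine rescaling of the feature.
#'
#' @param values numeric feature vector.
#' @param labels two-level factor/vector aligned with \code{values}.
#' @return non-negative score.
#' @examples
#' fisherScore(c(0, 1, 2, 3), c("a", "a", "b", "b"))  # 8
#' @export
fisherScore <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("fisherScore needs exactly two classes", call. = FALSE)
  sp <- split(values, droplevels(labels))
  if (any(lengths(sp) < 2L))
    stop("each class needs at least two samples", call. = FALSE)
  m <- vapply(sp, mean, numeric(1))
  popvar <- vapply(sp, function(v) mean((v - mean(v))^2), numeric(1))
  unname((m[1] - m[2])^2 / (popvar[1] + popvar[2] + 1e-12))
}

# feature vector at one location: Unser(8) on the composite plane, Unser(8)
# on luminance (fixed 0-100 quantization, so it transfers across slides),
# and the LBP riu2 histogram on the composite plane
.N_TEXTURE_FEATURES <- 8L + 8L + 18L

.textureVector <- function(planeC, planeL, center, radiusPx, lbpPoints = 16L,
                           quantC = NULL, quantL = NULL, codes = NULL) {
  unC <- unserFeatures(planeC, center, radiusPx, quant = quantC)
  unL <- unserFeatures(planeL, center, radiusPx, quant = quantL)
  lb <- lbpDescriptor(planeC, center, radiusPx = radiusPx,
                      nPoints = lbpPoints, omegaRadiusPx = radiusPx,
                      codes = codes)
  v <- c(as.numeric(unC), as.numeric(unL), as.numeric(lb))
  names(v) <- c(.UNSER_NAMES, paste0("L_", .UNSER_NAMES),
                paste0("lbp", seq_along(lb) - 1L))
  v
}

#' Sample labelled texture vectors from class masks
#'
#' Draws up to \code{n} locations per class whose whole neighborhood
#' (2 Omega from the class boundary, implemented by mask erosion) stays
#' inside the class, and computes the texture feature vector at each.
#' Sampling is seeded and reproducible.
#'
#' @param planes a \linkS4class{ColorPlanes} object (features are computed
#'   on the composite u*512 + C plane and on luminance).
#' @param classMasks named list of logical matrices, one per class.
#' @param n samples per class.
#' @param radiusPx neighborhood radius used for the features.
#' @param seed RNG seed.
#' @return data.frame of features plus a \code{label} column; the
#'   composite-plane quantization range is attached as attribute
#'   \code{quantRange}.
#' @export
sampleTextureVectors <- function(planes, classMasks, n = 100L, radiusPx = 12L,
                                 seed = 1L) {
  plane <- planes@compositeUC
  planeL <- planes@L
  h <- nrow(plane); w <- ncol(plane)
  quant <- .quantizePlane(plane)
  quantL <- .quantizePlane(planeL, range = c(0, 100))
  codes <- lbpCodes(plane, radiusPx, 16L)
  .withSeed(seed, {
    rows <- list()
    for (nm in names(classMasks)) {
      m <- classMasks[[nm]]
      core <- EBImage::erode(m * 1, EBImage::makeBrush(
        2L * as.integer(2 * radiusPx) + 1L, "disc")) > 0.5
      pad <- as.integer(ceiling(2 * radiusPx)) + 1L
      core[c(seq_len(pad), h - seq_len(pad) + 1L), ] <- FALSE
      core[, c(seq_len(pad), w - seq_len(pad) + 1L)] <- FALSE
      idx <- which(core)
      if (length(idx) == 0L) next
      take <- idx[sample.int(length(idx), min(n, length(idx)))]
      xs <- (take - 1L) %/% h; ys <- (take - 1L) %% h
      fv <- t(vapply(seq_along(take), function(i)
        .textureVector(plane, planeL, c(xs[i], ys[i]), radiusPx,
                       quantC = quant, quantL = quantL, codes = codes),
        numeric(.N_TEXTURE_FEATURES)))
      df <- as.data.frame(fv)
      df$label <- nm
      rows[[nm]] <- df
    }
    out <- do.call(rbind, rows)
    # the quantization range is part of the learned representation
    attr(out, "quantRange") <- c(quant$lo, quant$lo + quant$step * 64)
    out
  })
}

.fisherRank <- function(X, labels) {
  scores <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (stats::sd(v) == 0) return(0)
    fisherScore(v, labels)
  }, numeric(1))
  order(scores, decreasing = TRUE)
}

# small seeded grid search for one binary Gaussian SVM
.trainBinarySvm <- function(X, y, seed) {
  y <- factor(y)
  # median-distance heuristic on standardized features: e1071 computes the
  # Gaussian kernel on internally scaled columns, so gamma must match
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  grid <- expand.grid(sigmaMul = c(0.1, 1, 10), cost = c(0.1, 1, 10))
  .withSeed(seed, {
    d2 <- as.numeric(stats::dist(Xs[sample.int(nrow(Xs), min(200L, nrow(Xs))), ,
                                    drop = FALSE]))
    sigma0 <- stats::median(d2[d2 > 0])
    if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 1
    holdout <- sample.int(nrow(X), max(2L, round(nrow(X) / 4)))
    train <- setdiff(seq_len(nrow(X)), holdout)
    accs <- vapply(seq_len(nrow(grid)), function(g) {
      gamma <- 1 / (2 * (sigma0 * grid$sigmaMul[g])^2)
      fit <- e1071::svm(X[train, , drop = FALSE], y[train], kernel = "radial",
                        gamma = gamma, cost = grid$cost[g], scale = TRUE)
      mean(stats::predict(fit, X[holdout, , drop = FALSE]) == y[holdout])
    }, numeric(1))
    best <- which.max(accs)
    gamma <- 1 / (2 * (sigma0 * grid$sigmaMul[best])^2)
    fit <- e1071::svm(X, y, kernel = "radial", gamma = gamma,
                      cost = grid$cost[best], scale = TRUE)
    list(fit = fit, heldOutAccuracy = accs[best],
         gamma = gamma, cost = grid$cost[best])
  })
}

#' Train the two-stage artifact SVM cascade
#'
#' Stage 1 learns tumour vs hemorrhage, stage 2 tumour vs fold (applied
#' downstream only inside the stage-1 tumour output). For each stage the
#' top-k Fisher-ranked features are kept and a Gaussian-kernel SVM is
#' fitted with a small seeded grid search (kernel width over
#' \{0.1, 1, 10\} times the median-distance heuristic, cost over
#' \{0.1, 1, 10\}) on a held-out split.
#'
#' @param samples data.frame from \code{\link{sampleTextureVectors}} with a
#'   \code{label} column containing tumour, hemorrhage and fold.
#' @param topK number of Fisher-selected features per stage (default 8).
#' @param radiusPx training neighborhood radius recorded in the metadata.
#' @param seed RNG seed for splits and the grid search.
#' @return a \linkS4class{CascadeModel}.
#' @export
trainCascade <- function(samples, topK = 8L, radiusPx = 12L, seed = 1L) {
  need <- c("tumour", "hemorrhage", "fold")
  missing <- setdiff(need, unique(samples$label))
  if (length(missing))
    stop("missing training class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cnt <- table(samples$label)
  if (any(cnt[need] < 30L))
    stop("need at least 30 samples per class (got ",
         paste(paste0(need, "=", as.integer(cnt[need])), collapse = ", "),
         ")", call. = FALSE)
  featNames <- setdiff(names(samples), "label")
  X <- as.matrix(samples[, featNames])

  s1 <- samples$label %in% c("tumour", "hemorrhage")
  y1 <- factor(ifelse(samples$label[s1] == "hemorrhage", "hemorrhage", "tumour"))
  idx1 <- .fisherRank(X[s1, , drop = FALSE], y1)[seq_len(min(topK, ncol(X)))]
  m1 <- .trainBinarySvm(X[s1, idx1, drop = FALSE], y1, seed)

  s2 <- samples$label %in% c("tumour", "fold")
  y2 <- factor(ifelse(samples$label[s2] == "fold", "fold", "tumour"))
  idx2 <- .fisherRank(X[s2, , drop = FALSE], y2)[seq_len(min(topK, ncol(X)))]
  m2 <- .trainBinarySvm(X[s2, idx2, drop = FALSE], y2, seed + 1L)

  new("CascadeModel", stage1 = m1$fit, stage2 = m2$fit,
      featIdx1 = as.integer(idx1), featIdx2 = as.integer(idx2),
      featureNames = featNames,
      metadata = list(radiusPx = radiusPx, seed = seed,
                      plane = "compositeUC",
                      quantRange = attr(samples, "quantRange"),
                      stage1 = m1[c("heldOutAccuracy", "gamma", "cost")],
                      stage2 = m2[c("heldOutAccuracy", "gamma", "cost")]))
}

#' Save / load a trained cascade model
#'
#' The archive is a single RDS file holding the \linkS4class{CascadeModel}
#' (SVM objects, selected feature indices and training metadata).
#'
#' @param model a \linkS4class{CascadeModel}.
#' @param path file path.
#' @return \code{loadCascade} returns the model; \code{saveCascade} the
#'   path, invisibly.
#' @export
saveCascade <- function(model, path) {
  stopifnot(is(model, "CascadeModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCascade
#' @export
loadCascade <- function(path) {
  model <- readRDS(path)
  if (!is(model, "CascadeModel")) stop("not a CascadeModel archive", call. = FALSE)
  model
}

#' Classify tissue into tumour / hemorrhage / fold region masks
#'
#' Evaluates the texture feature vector on a stride grid of locations whose
#' neighborhood stays inside the tissue mask, runs the cascade (stage 2
#' only on stage-1 tumour locations), and rasterizes the grid predictions
#' back to pixel masks by nearest-location assignment. Hemorrhage and fold
#' masks are disjoint by construction and subtracted from the tissue mask
#' to give the cleaned tumour analysis region.
#'
#' @param planes a \linkS4class{ColorPlanes} object.
#' @param tissueMask \linkS4class{RegionMask} (role tissue) or logical matrix.
#' @param model a trained \linkS4class{CascadeModel}.
#' @param radiusPx testing neighborhood radius (default 10, slightly
#'   smaller than the training radius).
#' @param stride grid step in pixels (default: one radius).
#' @return list of \linkS4class{RegionMask}: \code{hemorrhage}, \code{fold},
#'   \code{tumour}.
#' @export
classifyTissue <- function(planes, tissueMask, model, radiusPx = 10L,
                           stride = radiusPx) {
  tm <- if (is(tissueMask, "RegionMask")) maskData(tissueMask) else tissueMask
  ds <- if (is(tissueMask, "RegionMask")) downsample(tissueMask) else 1
  plane <- planes@compositeUC
  .sameShape(plane, tm, "plane and tissue mask")
  h <- nrow(tm); w <- ncol(tm)
  empty <- function(role) new("RegionMask", mask = matrix(FALSE, h, w),
                              role = role, downsample = ds)
  if (!any(tm))
    return(list(hemorrhage = empty("hemorrhage"), fold = empty("fold"),
                tumour = empty("tissue")))

  # candidate grid: Omega entirely inside the tissue mask (skip, not pad);
  # the frame border needs Omega plus the LBP sampling radius
  inside <- EBImage::erode(tm * 1, EBImage::makeBrush(
    2L * as.integer(radiusPx) + 1L, "disc")) > 0.5
  pad <- 2L * as.integer(radiusPx) + 1L
  inside[c(seq_len(pad), h - seq_len(pad) + 1L), ] <- FALSE
  inside[, c(seq_len(pad), w - seq_len(pad) + 1L)] <- FALSE
  gx <- seq(pad, w - pad - 1L, by = stride)
  gy <- seq(pad, h - pad - 1L, by = stride)
  grid <- expand.grid(x = gx, y = gy)
  keep <- inside[cbind(grid$y + 1L, grid$x + 1L)]
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(list(hemorrhage = empty("hemorrhage"), fold = empty("fold"),
                tumour = new("RegionMask", mask = tm, role = "tissue",
                             downsample = ds)))

  quant <- .quantizePlane(plane, range = model@metadata$quantRange)
  quantL <- .quantizePlane(planes@L, range = c(0, 100))
  codes <- lbpCodes(plane, radiusPx, 16L)
  fv <- t(vapply(seq_len(nrow(grid)), function(i)
    .textureVector(plane, planes@L, c(grid$x[i], grid$y[i]), radiusPx,
                   quantC = quant, quantL = quantL, codes = codes),
    numeric(.N_TEXTURE_FEATURES)))
  if (!identical(colnames(fv), model@featureNames))
    stop("feature/plane layout does not match the trained model", call. = FALSE)

  p1 <- stats::predict(model@stage1, fv[, model@featIdx1, drop = FALSE])
  isHem <- p1 == "hemorrhage"
  isFold <- rep(FALSE, nrow(grid))
  if (any(!isHem)) {
    p2 <- stats::predict(model@stage2,
                         fv[!isHem, model@featIdx2, drop = FALSE])
    isFold[!isHem] <- p2 == "fold"
  }

  # rasterize by nearest grid location within the tissue mask
  lab <- integer(nrow(grid))
  lab[isHem] <- 1L; lab[isFold] <- 2L
  tIdx <- which(tm)
  pyy <- (tIdx - 1L) %% h; pxx <- (tIdx - 1L) %/% h
  nearGx <- pmin(pmax(round((pxx - gx[1]) / stride), 0), length(gx) - 1L)
  nearGy <- pmin(pmax(round((pyy - gy[1]) / stride), 0), length(gy) - 1L)
  # map grid (x index, y index) -> row in `grid`/lab; unevaluated cells -> 0
  gridId <- matrix(0L, length(gy), length(gx))
  gi <- match(grid$x, gx); gj <- match(grid$y, gy)
  gridId[cbind(gj, gi)] <- seq_len(nrow(grid))
  nearest <- gridId[cbind(nearGy + 1L, nearGx + 1L)]
  pixLab <- ifelse(nearest > 0L, lab[pmax(nearest, 1L)], 0L)

  hemM <- foldM <- matrix(FALSE, h, w)
  hemM[tIdx[pixLab == 1L]] <- TRUE
  foldM[tIdx[pixLab == 2L]] <- TRUE
  list(
    hemorrhage = new("RegionMask", mask = hemM, role = "hemorrhage",
                     downsample = ds),
    fold = new("RegionMask", mask = foldM, role = "fold", downsample = ds),
    tumour = new("RegionMask", mask = tm & !hemM & !foldM, role = "tissue",
                 downsample = ds)
  )
}
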