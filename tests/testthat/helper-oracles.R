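# Independent oracle implementations used to verify the package's
# operations. These are deliberately naive (scalar loops, exhaustive
# search, fixpoint iteration) and share no code with the implementation.

# exhaustive Otsu: best of 256 equal-width cut points by direct two-class
# variance computation on the raw values
oracleOtsuVariance <- function(values) {
  lo <- min(values); hi <- max(values)
  edges <- lo + (1:255) * (hi - lo) / 256
  best <- -Inf
  for (t in edges) {
    a <- values[values <= t]; b <- values[values > t]
    if (!length(a) || !length(b)) next
    w0 <- length(a) / length(values)
    v <- w0 * (1 - w0) * (mean(a) - mean(b))^2
    if (v > best) best <- v
  }
  best
}

# between-class variance realized by a given threshold
thresholdVariance <- function(values, thr) {
  a <- values[values <= thr]; b <- values[values > thr]
  if (!length(a) || !length(b)) return(0)
  w0 <- length(a) / length(values)
  w0 * (1 - w0) * (mean(a) - mean(b))^2
}

# scalar CIE Luv conversion written from the standard formulas
oracleLuv <- function(rgb255) {
  comp <- function(c) {
    c <- c / 255
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  }
  r <- comp(rgb255[1]); g <- comp(rgb255[2]); b <- comp(rgb255[3])
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  Xn <- 0.95047; Yn <- 1; Zn <- 1.08883
  yr <- Y / Yn
  L <- if (yr > (6 / 29)^3) 116 * yr^(1 / 3) - 16 else (29 / 3)^3 * yr
  den <- X + 15 * Y + 3 * Z
  denN <- Xn + 15 * Yn + 3 * Zn
  up <- if (den > 0) 4 * X / den else 4 * Xn / denN
  vp <- if (den > 0) 9 * Y / den else 9 * Yn / denN
  c(L = L, u = 13 * L * (up - 4 * Xn / denN), v = 13 * L * (vp - 9 * Yn / denN))
}

# Unser features by explicit pair enumeration over the disk, on an already
# quantized integer plane; mirrors the documented contract, not the code
oracleUnser <- function(qplane, cx, cy, radius, lo, step) {
  G <- 64L
  disp <- list(c(1, 0), c(1, -1), c(0, 1), c(1, 1))
  acc <- numeric(8)
  for (d in disp) {
    sh <- rep(0, 2 * G - 1); dh <- rep(0, 2 * G - 1)
    for (dx in -radius:radius) for (dy in -radius:radius) {
      if (dx^2 + dy^2 > radius^2) next
      bx <- dx + d[1]; by <- dy + d[2]
      if (bx^2 + by^2 > radius^2) next
      qa <- qplane[cy + dy + 1, cx + dx + 1]
      qb <- qplane[cy + by + 1, cx + bx + 1]
      sh[qa + qb + 1] <- sh[qa + qb + 1] + 1
      dh[qa - qb + G] <- dh[qa - qb + G] + 1
    }
    Ps <- sh / sum(sh); Pd <- dh / sum(dh)
    i <- 0:(2 * G - 2); j <- -(G - 1):(G - 1)
    mu <- sum(i * Ps)
    acc <- acc + c(
      mu / 2,
      (sum((i - mu)^2 * Ps) + sum(j^2 * Pd)) / 2,
      sum(Pd / (1 + j^2)),
      sum(j^2 * Pd),
      sum(Ps^2) * sum(Pd^2),
      (sum((i - mu)^2 * Ps) - sum(j^2 * Pd)) / 2,
      sum((i - mu)^3 * Ps),
      sum((i - mu)^4 * Ps))
  }
  acc <- acc / 4
  acc[1] <- lo + (acc[1] + 0.5) * step
  names(acc) <- c("mean", "variance", "homogeneity", "contrast", "energy",
                  "correlation", "cluster_shade", "cluster_prominence")
  acc
}

# raw LBP code of one pixel by explicit circle sampling + bilinear loop
oracleLbpCode <- function(plane, x, y, radius, nPoints) {
  centre <- plane[y + 1, x + 1]
  code <- 0
  for (k in 0:(nPoints - 1)) {
    sx <- x + radius * cos(2 * pi * k / nPoints)
    sy <- y - radius * sin(2 * pi * k / nPoints)
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    v <- (1 - fx) * (1 - fy) * plane[y0 + 1, x0 + 1] +
      fx * (1 - fy) * plane[y0 + 1, x0 + 2] +
      (1 - fx) * fy * plane[y0 + 2, x0 + 1] +
      fx * fy * plane[y0 + 2, x0 + 2]
    if (v >= centre) code <- code + 2^k
  }
  code
}

# riu2 mapping of one raw code by direct bit manipulation
oracleRiu2 <- function(code, P) {
  bits <- integer(P)
  for (k in 1:P) bits[k] <- (code %/% 2^(k - 1)) %% 2
  trans <- sum(bits != bits[c(2:P, 1)])
  if (trans <= 2) sum(bits) else P + 1
}

# morphological reconstruction by dilation: naive fixpoint iteration with
# an 8-connected 3x3 max filter
oracleReconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  nr <- nrow(J); nc <- ncol(J)
  repeat {
    old <- J
    up <- J
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      sh <- matrix(-Inf, nr, nc)
      ys <- max(1, 1 + dy):min(nr, nr + dy)
      xs <- max(1, 1 + dx):min(nc, nc + dx)
      sh[ys, xs] <- J[ys - dy, xs - dx]
      up <- pmax(up, sh)
    }
    J <- pmin(up, mask)
    if (identical(J, old)) break
  }
  J
}

# connected components (8-connectivity) by BFS flood fill
oracleComponentCount <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nrow(mask) + 1L
      c <- (p - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
        q <- (cc - 1L) * nrow(mask) + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- n
          queue <- c(queue, q)
        }
      }
    }
  }
  n
}

# explicit greedy gradual-extinction loop over a candidate table
oracleGreedySelect <- function(cand, rho, nMax, fovW) {
  sel <- integer(0)
  while (length(sel) < nMax) {
    avail <- setdiff(which(cand$raw > 0), sel)
    if (!length(avail)) break
    score <- numeric(length(avail))
    for (i in seq_along(avail)) {
      p <- 1
      if (length(sel)) {
        d <- sqrt((cand$cx[sel] - cand$cx[avail[i]])^2 +
                  (cand$cy[sel] - cand$cy[avail[i]])^2) / fovW
        p <- max(0, 1 - rho * sum(1 / sqrt(d)))
      }
      score[i] <- cand$raw[avail[i]] * p
    }
    best <- avail[order(-score, -cand$raw[avail], avail)][1]
    sel <- c(sel, best)
  }
  sel
}
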