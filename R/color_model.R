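# Color representations: CIE Luv, naive CMYK, and the composite u*512 + C
# channel used for texture description. Conventions fixed here: sRGB
# companding with the D65 white point; u on its native CIE scale; C in [0,1].

# white point taken as the sRGB matrix row sums, so that RGB white maps to
# exactly L = 100, u = v = 0 (the nominal D65 values differ in the 7th digit)
.D65 <- c(X = 0.4124564 + 0.3575761 + 0.1804375,
          Y = 0.2126729 + 0.7151522 + 0.0721750,
          Z = 0.0193339 + 0.1191920 + 0.9503041)
.uvPrime <- function(X, Y, Z) {
  den <- X + 15 * Y + 3 * Z
  bad <- den <= 0
  den[bad] <- 1
  up <- 4 * X / den
  vp <- 9 * Y / den
  # colorless pixels take the white point chromaticity so u = v = 0
  upn <- 4 * .D65["X"] / (.D65["X"] + 15 * .D65["Y"] + 3 * .D65["Z"])
  vpn <- 9 * .D65["Y"] / (.D65["X"] + 15 * .D65["Y"] + 3 * .D65["Z"])
  up[bad] <- upn
  vp[bad] <- vpn
  list(up = up, vp = vp, upn = as.numeric(upn), vpn = as.numeric(vpn))
}

.srgbToLinear <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

#' Convert an 8-bit RGB raster to CIE Luv planes
#'
#' Standard sRGB -> XYZ (D65) -> Luv conversion applied per pixel. L is on
#' the usual 0-100 scale; the white point maps to u = v = 0.
#'
#' @param image height x width x 3 RGB array on the 0-255 scale.
#' @return list with matrices \code{L}, \code{u}, \code{v}.
#' @examples
#' rgbToLuv(array(255, c(1, 1, 3)))  # white: L = 100, u = v = 0
#' @export
rgbToLuv <- function(image) {
  .assertRgbArray(image, "rgbToLuv input")
  d <- dim(image)
  R <- .srgbToLinear(image[, , 1] / 255)
  G <- .srgbToLinear(image[, , 2] / 255)
  B <- .srgbToLinear(image[, , 3] / 255)
  X <- 0.4124564 * R + 0.3575761 * G + 0.1804375 * B
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  Z <- 0.0193339 * R + 0.1191920 * G + 0.9503041 * B
  yr <- Y / .D65["Y"]
  L <- ifelse(yr > (6 / 29)^3, 116 * yr^(1 / 3) - 16, (29 / 3)^3 * yr)
  uv <- .uvPrime(X, Y, Z)
  u <- 13 * L * (uv$up - uv$upn)
  v <- 13 * L * (uv$vp - uv$vpn)
  shape <- function(m) matrix(m, d[1], d[2])
  list(L = shape(L), u = shape(u), v = shape(v))
}

#' Convert an 8-bit RGB raster to naive CMYK planes
#'
#' K = 1 - max(R, G, B)/255; C = (1 - R/255 - K)/(1 - K) and analogously M
#' and Y. Pure black (K = 1) takes C = M = Y = 0 by convention.
#'
#' @param image height x width x 3 RGB array on the 0-255 scale.
#' @return list with matrices \code{C}, \code{M}, \code{Y}, \code{K}, each
#'   in [0, 1].
#' @examples
#' rgbToCmyk(array(c(255, 255, 0), c(1, 1, 3)))  # yellow: Y = 1
#' @export
rgbToCmyk <- function(image) {
  .assertRgbArray(image, "rgbToCmyk input")
  d <- dim(image)
  r <- image[, , 1] / 255; g <- image[, , 2] / 255; b <- image[, , 3] / 255
  K <- 1 - pmax(r, g, b)
  den <- 1 - K
  black <- den <= 0
  den[black] <- 1
  C <- (1 - r - K) / den; M <- (1 - g - K) / den; Y <- (1 - b - K) / den
  C[black] <- 0; M[black] <- 0; Y[black] <- 0
  shape <- function(m) matrix(pmin(pmax(m, 0), 1), d[1], d[2])
  list(C = shape(C), M = shape(M), Y = shape(Y), K = shape(matrix(K, d[1], d[2])))
}

#' Composite u*512 + C texture channel
#'
#' The stain-robust channel used for texture classification: the Luv u
#' plane scaled by 512 plus the CMYK C plane. Linear in both arguments.
#'
#' @param u CIE Luv u plane.
#' @param C CMYK C plane in [0, 1].
#' @return matrix \code{u * 512 + C}.
#' @examples
#' compositeChannel(matrix(1, 2, 2), matrix(0.5, 2, 2))  # all 512.5
#' @export
compositeChannel <- function(u, C) {
  .sameShape(u, C, "u and C planes")
  u * 512 + C
}

#' Compute all color planes the pipeline consumes
#'
#' @param image a \linkS4class{SlideImage} or an RGB array (0-255).
#' @return a \linkS4class{ColorPlanes} object.
#' @examples
#' slide <- generateSlide(syntheticSpec(widthPx = 64, heightPx = 48))$slide
#' planes <- colorPlanes(slide)
#' range(planes@L)
#' @export
colorPlanes <- function(image) {
  if (is(image, "SlideImage")) image <- pixels(image)
  luv <- rgbToLuv(image)
  cmyk <- rgbToCmyk(image)
  # slot-wise assignment: an argument named C would partially match new()'s
  # Class formal
  obj <- new("ColorPlanes")
  obj@L <- luv$L; obj@u <- luv$u; obj@v <- luv$v
  obj@C <- cmyk$C; obj@M <- cmyk$M; obj@Y <- cmyk$Y; obj@K <- cmyk$K
  obj@compositeUC <- compositeChannel(luv$u, cmyk$C)
  validObject(obj)
  obj
}
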