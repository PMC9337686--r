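#' @include AllClasses.R
NULL

#' Mean absolute difference between two images
#'
#' @param a,b numeric matrices of identical shape.
#' @return mean over pixels of `|a - b|`.
#' @examples
#' l1Mean(matrix(0, 2, 2), matrix(0.25, 2, 2))  # 0.25
#' @export
l1Mean <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("l1Mean: shape mismatch")
  mean(abs(a - b))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(dataRange^2 / MSE)` in decibels. Identical images have
#' zero MSE; the value is capped at `cap` (100 dB) instead of infinity.
#'
#' @param a,b numeric matrices of identical shape.
#' @param dataRange intensity range of the data (1 for \[0,1\] images).
#' @param cap value returned for (near-)identical images.
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(0.5, 2, 2))  # 6.0206
#' @export
psnr <- function(a, b, dataRange = 1, cap = 100) {
  if (!identical(dim(a), dim(b))) stop("psnr: shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(dataRange^2 / mse))
}

#' Structural similarity index
#'
#' Mean local SSIM over the image, computed with the canonical
#' parameters: 11 x 11 Gaussian window (sigma 1.5), stabilizers
#' K1 = 0.01 and K2 = 0.03, and the stated data range. SSIM compares
#' luminance, contrast and structure; 1 means identical, values below 0
#' indicate anti-correlated structure.
#'
#' @param a,b numeric matrices of identical shape, min side >= 11.
#' @param dataRange intensity range (1 for \[0,1\] images).
#' @return mean SSIM in \[-1, 1\].
#' @examples
#' x <- matrix(runif(256), 16, 16)
#' ssim(x, x)  # 1
#' @export
ssim <- function(a, b, dataRange = 1) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  win <- 11L
  if (min(dim(a)) < win)
    stop("ssim: image smaller than the ", win, "-pixel window")
  g <- outer(dnorm(seq(-5, 5), sd = 1.5), dnorm(seq(-5, 5), sd = 1.5))
  g <- g / sum(g)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  f <- function(x) EBImage::filter2(x, g, boundary = "replicate")
  mu1 <- f(a)
  mu2 <- f(b)
  s11 <- f(a * a) - mu1 * mu1
  s22 <- f(b * b) - mu2 * mu2
  s12 <- f(a * b) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Image-quality metrics over a test set
#'
#' @param generated,groundTruth lists of image matrices (same order).
#' @return data.frame with per-image `l1_mean`, `psnr_db`, `ssim` and
#'   attribute-free aggregate rows accessible via `colMeans`.
#' @export
metricsReport <- function(generated, groundTruth) {
  stopifnot(length(generated) == length(groundTruth))
  data.frame(
    index = seq_along(generated),
    l1_mean = mapply(l1Mean, generated, groundTruth),
    psnr_db = mapply(psnr, generated, groundTruth),
    ssim = mapply(ssim, generated, groundTruth))
}
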