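#' @include AllClasses.R matching.R
NULL

#' Image-level random-placement probability
#'
#' If a nucleus centroid is placed uniformly at random in a square
#' image of side `LUm`, the chance of landing within `rUm` of the true
#' position is the area ratio `pi r^2 / L^2`. With the mean nuclear
#' radius r = 4 um and the 159.41-um test images this is about 1/500 —
#' the per-trial success probability of the image-level null model.
#'
#' @param rUm match radius in micrometers (> 0).
#' @param LUm image side in micrometers (must exceed `2 * rUm`).
#' @return a [PlacementNull-class] of kind `"image"`.
#' @examples
#' nullProbability(placementNullImage(4, 159.41))  # ~ 1/505
#' @export
placementNullImage <- function(rUm, LUm) {
  if (rUm <= 0 || LUm <= 0)
    stop("placementNullImage: radius and image side must be positive")
  if (2 * rUm >= LUm)
    stop("placementNullImage: need 2 * rUm < LUm for a meaningful null")
  new("PlacementNull", kind = "image", rUm = rUm, LUm = LUm,
      p = pi * rUm^2 / LUm^2)
}

#' @rdname placementNullImage
#' @export
pRandomImage <- function(rUm, LUm) nullProbability(placementNullImage(rUm, LUm))

#' Cell-level random-placement probability
#'
#' Restricts the null model to the cytoplasm: positions closer than the
#' nuclear radius to the cell edge are discarded (the whole nucleus
#' must fit inside the cell), implemented as morphological erosion of
#' the cell mask by a disc of radius `rUm`. The success probability is
#' the pixel-count ratio of allowed positions within `rUm` of the true
#' center to all allowed positions.
#'
#' @param cellMask binary matrix (1 = inside the cell).
#' @param pixelSizeUm physical pixel size of the mask.
#' @param rUm match radius (and nuclear radius) in micrometers.
#' @param trueCenter 0-based `(row, col)` pixel coordinates of the true
#'   nucleus centroid; must lie in the eroded (allowed) region.
#' @return a [PlacementNull-class] of kind `"cell"`.
#' @examples
#' m <- matrix(0, 64, 64)
#' m[as.matrix(expand.grid(1:64, 1:64))[
#'   (rep(1:64, 64) - 32)^2 + (rep(1:64, each = 64) - 32)^2 < 25^2]] <- 1
#' placementNullCell(m, 1, 5, c(31, 31))
#' @export
placementNullCell <- function(cellMask, pixelSizeUm, rUm, trueCenter) {
  if (rUm <= 0) stop("placementNullCell: rUm must be positive")
  m <- (cellMask != 0) + 0
  rPx <- round(rUm / pixelSizeUm)
  allowed <- if (rPx >= 1) {
    brush <- EBImage::makeBrush(2L * rPx + 1L, shape = "disc")
    EBImage::erode(m, brush)
  } else m
  nAllowed <- sum(allowed)
  if (nAllowed == 0)
    stop("placementNullCell: eroded region is empty (cell too small for ",
         "the nucleus)")
  ctr <- as.integer(round(trueCenter)) + 1L
  if (ctr[1] < 1 || ctr[1] > nrow(m) || ctr[2] < 1 || ctr[2] > ncol(m) ||
      allowed[ctr[1], ctr[2]] == 0)
    stop("placementNullCell: trueCenter must lie inside the allowed ",
         "(eroded) region")
  d2 <- .distUmSq(nrow(m), ncol(m), trueCenter, pixelSizeUm)
  nMatched <- sum(allowed == 1 & d2 < rUm^2)
  if (nMatched >= nAllowed)
    stop("placementNullCell: match radius covers the whole allowed ",
         "region; the null is degenerate")
  new("PlacementNull", kind = "cell", rUm = rUm, LUm = NA_real_,
      p = nMatched / nAllowed)
}

#' @rdname placementNullCell
#' @export
pRandomCell <- function(cellMask, pixelSizeUm, rUm, trueCenter)
  nullProbability(placementNullCell(cellMask, pixelSizeUm, rUm, trueCenter))

#' Binomial proportion confidence intervals
#'
#' Three interval constructions for a binomial proportion `k/n`:
#' the exact Clopper-Pearson interval via Beta quantiles, the Wilson
#' score interval (inverting the score test), and the Wald normal
#' approximation. The score interval reproduces the +/- 1.0 percentage
#' point intervals quoted for the matched fractions (e.g. 5785/8151 at
#' the 4-um threshold gives 71.0 +/- 1.0%).
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level confidence level (default 0.95).
#' @param method `"clopper_pearson"`, `"wilson_score"` or `"normal"`.
#' @return list with `k`, `n`, `pHat`, `level`, `lower`, `upper`,
#'   `method`.
#' @examples
#' ci <- proportionCI(5785, 8151, method = "wilson_score")
#' round(100 * c(ci$lower, ci$pHat, ci$upper), 1)
#' @export
proportionCI <- function(k, n, level = 0.95,
                         method = c("clopper_pearson", "wilson_score",
                                    "normal")) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n)
    stop("proportionCI: need 0 <= k <= n and n >= 1")
  if (level <= 0 || level >= 1)
    stop("proportionCI: level must lie in (0,1)")
  pHat <- k / n
  a <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
    upper <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  } else if (method == "wilson_score") {
    z <- qnorm(1 - a / 2)
    denom <- n + z^2
    center <- (k + z^2 / 2) / denom
    hw <- z / denom * sqrt(k * (n - k) / n + z^2 / 4)
    lower <- max(0, center - hw)
    upper <- min(1, center + hw)
  } else {
    z <- qnorm(1 - a / 2)
    hw <- z * sqrt(pHat * (1 - pHat) / n)
    lower <- max(0, pHat - hw)
    upper <- min(1, pHat + hw)
  }
  list(k = k, n = n, pHat = pHat, level = level, lower = lower,
       upper = upper, method = method)
}

#' Upper-tail binomial log10 p-value
#'
#' `log10 P(X >= k)` for `X ~ Binomial(n, p0)`. The matched-nucleus
#' counts are so far above any random-placement null that the p-values
#' underflow double precision; all arithmetic therefore stays in log
#' space. `"exact_log"` sums the binomial terms with a log-sum-exp;
#' `"normal"` uses the Gaussian upper tail with continuity correction
#' (the standard approximation at these trial counts). The two agree
#' closely for moderate z-scores.
#'
#' @param n trials; `k` successes (0 <= k <= n); `p0` null success
#'   probability in (0,1).
#' @param k successes.
#' @param p0 null success probability.
#' @param approximation `"exact_log"` or `"normal"`.
#' @return log10 of the upper-tail p-value (finite for any k <= n).
#' @examples
#' binomialTailLog10(10, 10, 0.5)   # log10(2^-10) = -3.0103
#' binomialTailLog10(8151, 5785, pRandomImage(4, 159.41))
#' @export
binomialTailLog10 <- function(n, k, p0,
                              approximation = c("exact_log", "normal")) {
  approximation <- match.arg(approximation)
  if (k < 0 || k > n) stop("binomialTailLog10: need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("binomialTailLog10: p0 must be in (0,1)")
  if (k == 0) return(0)
  if (approximation == "exact_log") {
    j <- k:n
    lt <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
    m <- max(lt)
    (m + log(sum(exp(lt - m)))) / log(10)
  } else {
    z <- (k - 0.5 - n * p0) / sqrt(n * p0 * (1 - p0))
    pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
}

#' Placement statistics report
#'
#' The package's statistical bottom line: for each distance threshold,
#' the matched count and fraction, all three confidence intervals, and
#' the binomial tail probability of observing at least that many
#' matches if nuclei were placed at random per the null model.
#'
#' @param report a [MatchingReport-class].
#' @param null a [PlacementNull-class].
#' @param thresholdsUm distance thresholds in micrometers.
#' @param denominator passed to [matchedFraction()].
#' @return nested list, one element per threshold, each with `k`, `n`,
#'   `fraction`, `ci` (three methods) and `log10_pvalue` (exact and
#'   normal), plus top-level `count_error_pct`, `n_gt`, `n_gen` and the
#'   null description.
#' @examples
#' img <- matrix(0, 64, 64); img[10:20, 10:20] <- 1
#' rec <- detectNuclei(img, 1, detectionConfig("fixed", 0.5, minAreaPx = 1))
#' rep <- matchNuclei(rec, rec)
#' placementReport(rep, placementNullImage(4, 52.5))$thresholds[[1]]$fraction
#' @export
placementReport <- function(report, null, thresholdsUm = c(4, 1),
                            denominator = c("all-generated", "paired")) {
  denominator <- match.arg(denominator)
  stopifnot(is(report, "MatchingReport"), is(null, "PlacementNull"))
  p0 <- null@p
  out <- lapply(thresholdsUm, function(thr) {
    mf <- matchedFraction(report, thr, denominator)
    cis <- lapply(c("clopper_pearson", "wilson_score", "normal"),
                  function(m) proportionCI(mf$k, mf$n, method = m))
    names(cis) <- c("clopper_pearson", "wilson_score", "normal")
    list(threshold_um = thr, k = mf$k, n = mf$n, fraction = mf$fraction,
         ci = cis,
         log10_pvalue = list(
           exact_log = binomialTailLog10(mf$n, mf$k, p0, "exact_log"),
           normal = binomialTailLog10(mf$n, mf$k, p0, "normal")))
  })
  list(null = list(kind = null@kind, r_um = null@rUm,
                   L_um = null@LUm, p = p0),
       n_gt = report@nGT, n_gen = report@nGen,
       count_error_pct = report@countErrorPct,
       denominator = denominator,
       thresholds = out)
}
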