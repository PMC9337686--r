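# Random-placement null models, confidence intervals and binomial
# tails.

test_that("image-level null probability is the area ratio", {
  p <- pRandomImage(4, 159.41)
  expect_equal(p, pi * 16 / 159.41^2)
  expect_equal(signif(1 / p, 1), 500)   # 'one out of 500'
  expect_equal(pRandomImage(1, 100), pi * 1e-4)
  # monotonicity: increasing r, decreasing L
  expect_gt(pRandomImage(5, 159.41), pRandomImage(4, 159.41))
  expect_gt(pRandomImage(4, 100), pRandomImage(4, 159.41))
  expect_error(pRandomImage(60, 100), "2 \\* rUm")
  expect_error(pRandomImage(-1, 100), "positive")
})

test_that("cell-level null matches the closed form for a circular cell", {
  n <- 201
  ctr <- c(100, 100)
  R <- 80
  d <- sqrt(outer(((0:(n - 1)) - ctr[1])^2, ((0:(n - 1)) - ctr[2])^2, "+"))
  mask <- (d <= R) + 0
  r <- 20
  pn <- placementNullCell(mask, 1, r, ctr)
  # continuum limit: r^2 / (R - r)^2
  expect_equal(nullProbability(pn), r^2 / (R - r)^2, tolerance = 0.05)
  expect_error(placementNullCell(mask, 1, r, c(5, 5)), "allowed")
  tiny <- matrix(0, 40, 40)
  tiny[18:22, 18:22] <- 1
  expect_error(placementNullCell(tiny, 1, 10, c(19, 19)), "empty|allowed")
})

test_that("cell-level null agrees with Monte-Carlo placement", {
  set.seed(17)
  # random blob: union of discs
  n <- 120
  mask <- matrix(0, n, n)
  for (k in 1:4) {
    c0 <- runif(2, 30, 90)
    R0 <- runif(1, 18, 30)
    d <- sqrt(outer(((0:(n - 1)) - c0[1])^2, ((0:(n - 1)) - c0[2])^2, "+"))
    mask[d <= R0] <- 1
  }
  rUm <- 8
  ctrIdx <- which(mask == 1, arr.ind = TRUE)
  ctr <- as.numeric(ctrIdx[which.min(rowSums((ctrIdx -
    matrix(colMeans(ctrIdx), nrow(ctrIdx), 2, byrow = TRUE))^2)), ]) - 1
  pn <- placementNullCell(mask, 1, rUm, ctr)
  # Monte-Carlo oracle: uniform draws over the eroded region
  allowed <- NucleoGAN:::.withSeed(1, "mc", {
    brush <- EBImage::makeBrush(2L * rUm + 1L, shape = "disc")
    er <- EBImage::erode(mask, brush)
    pts <- which(er == 1, arr.ind = TRUE) - 1
    draws <- pts[sample.int(nrow(pts), 1e5, replace = TRUE), ] +
      matrix(runif(2e5, -0.5, 0.5), 1e5, 2)
    mean(sqrt(rowSums((draws - matrix(ctr, 1e5, 2, byrow = TRUE))^2)) < rUm)
  })
  expect_lt(abs(nullProbability(pn) - allowed) / allowed, 0.05)
})

test_that("confidence intervals reproduce the quoted score intervals", {
  w4 <- proportionCI(5785, 8151, method = "wilson_score")
  expect_equal(round(100 * w4$pHat, 1), 71.0)
  expect_equal(round(100 * (w4$upper - w4$lower) / 2, 1), 1.0)
  w1 <- proportionCI(2328, 8151, method = "wilson_score")
  expect_equal(round(100 * w1$pHat, 1), 28.6)
  expect_equal(round(100 * (w1$upper - w1$lower) / 2, 1), 1.0)
  # detection ratios quoted alongside
  expect_equal(round(100 * 8151 / 9659), 84)
  expect_equal(round(100 * 1069 / 1359), 79)
  expect_equal(round(100 * 2328 / 5785), 40)
})

test_that("Clopper-Pearson boundaries and containment of the score center", {
  expect_equal(proportionCI(0, 50)$lower, 0)
  expect_equal(proportionCI(50, 50)$upper, 1)
  for (kk in c(3, 10, 17)) {
    cp <- proportionCI(kk, 20, method = "clopper_pearson")
    ws <- proportionCI(kk, 20, method = "wilson_score")
    center <- (ws$lower + ws$upper) / 2
    expect_gte(center, cp$lower)
    expect_lte(center, cp$upper)
    expect_gte((cp$upper - cp$lower) - (ws$upper - ws$lower), -1e-9)
    expect_true(cp$lower <= cp$pHat && cp$pHat <= cp$upper)
  }
  expect_error(proportionCI(5, 3), "k <= n")
})

test_that("interval coverage over simulated binomial draws", {
  set.seed(314)
  n <- 500
  p <- 0.7
  ks <- rbinom(2000, n, p)
  covCP <- mean(vapply(ks, function(k) {
    ci <- proportionCI(k, n, method = "clopper_pearson")
    ci$lower <= p && p <= ci$upper
  }, logical(1)))
  covW <- mean(vapply(ks, function(k) {
    ci <- proportionCI(k, n, method = "wilson_score")
    ci$lower <= p && p <= ci$upper
  }, logical(1)))
  expect_gte(covCP, 0.95 - 0.011)  # exact interval: conservative
  expect_gte(covW, 0.93)
  expect_lte(covW, 0.97)
})

test_that("binomial log tails: closed forms, oracle, monotonicity", {
  expect_equal(binomialTailLog10(10, 10, 0.5), log10(2^-10))
  expect_equal(binomialTailLog10(10, 8, 0.5), log10(56 / 1024))
  expect_equal(binomialTailLog10(5, 0, 0.3), 0)
  # cross-check the log-sum-exp against R's log-space tail
  for (cs in list(c(100, 70, 0.5), c(8151, 5785, 0.002),
                  c(1000, 10, 0.002))) {
    mine <- binomialTailLog10(cs[1], cs[2], cs[3])
    ref <- pbinom(cs[2] - 1, cs[1], cs[3], lower.tail = FALSE,
                  log.p = TRUE) / log(10)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
  # decreasing in k
  tails <- vapply(c(10, 100, 500, 1000), function(k)
    binomialTailLog10(8151, k, 0.002), numeric(1))
  expect_true(all(diff(tails) < 0))
  # normal approximation with continuity correction tracks the exact
  # tail within 5% in log10 for moderate z
  for (k in c(540, 590, 650)) {           # z up to ~9.5
    ex <- binomialTailLog10(1000, k, 0.5, "exact_log")
    no <- binomialTailLog10(1000, k, 0.5, "normal")
    expect_lt(abs(ex - no) / abs(ex), 0.05)
  }
})

test_that("the full-scale matched count is overwhelmingly non-random", {
  p0 <- pRandomImage(4, 159.41)
  lt <- binomialTailLog10(8151, 5785, p0, "exact_log")
  expect_true(is.finite(lt))
  expect_lt(lt, -1000)
  ln <- binomialTailLog10(8151, 5785, p0, "normal")
  expect_true(is.finite(ln))
  expect_lt(ln, -1000)
})

test_that("random generated centroids recover the image-level null rate", {
  # feed the matcher uniformly random 'generated' nuclei: the matched
  # fraction at 4 um must approach pi r^2 / L^2
  set.seed(2718)
  L <- 200
  r <- 4
  side <- 9                     # 9x9 boxes around each centroid
  nImg <- 600
  reps <- vector("list", nImg)
  for (i in seq_len(nImg)) {
    gtC <- floor(runif(2, 30, L - 30))
    genC <- floor(runif(2, 0, L - side))
    gt <- recordsFromBoxes(list(c(gtC[1] - 4, gtC[2] - 4, side, side)))
    gen <- recordsFromBoxes(list(c(genC[1], genC[2], side, side)))
    reps[[i]] <- matchNuclei(gt, gen, pixelSizeUm = 1)
  }
  mf <- matchedFraction(combineMatchingReports(reps), r, "all-generated")
  # generated box top-left is uniform over (L - side)^2 positions;
  # a match requires the centroid within r of the true centroid
  p0 <- pRandomImage(r, L - side)
  se <- sqrt(p0 * (1 - p0) / mf$n)
  expect_lt(abs(mf$fraction - p0), 3 * se + 1e-6)
})

test_that("placementReport assembles fractions, CIs and tails", {
  recs <- recordsFromBoxes(lapply(1:4, function(k)
    c(k * 12, k * 12, 8, 8)))
  rep <- matchNuclei(recs, recs, pixelSizeUm = 1)
  pr <- placementReport(rep, placementNullImage(4, 100),
                        thresholdsUm = c(4, 1))
  t4 <- pr$thresholds[[1]]
  expect_equal(t4$fraction, 1)
  expect_equal(t4$ci$clopper_pearson$upper, 1)
  expect_lt(t4$log10_pvalue$exact_log, -5)
  expect_equal(pr$count_error_pct, 0)
  # injected full-scale counts produce a finite, hugely negative tail
  inj <- proportionCI(5785, 8151, method = "wilson_score")
  expect_equal(round(inj$pHat, 4), 0.7097)
})
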