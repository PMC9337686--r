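# Segmentation: thresholding, component labeling (vs a flood-fill
# oracle), region properties and the generator round trip.

test_that("fixed-threshold binarization is exact and rejects bad input", {
  img <- matrix(0, 8, 8)
  img[3:5, 3:5] <- 1
  cfg <- detectionConfig("fixed", 0.5)
  m <- binarizeNucleus(img, cfg)
  expect_equal(attr(m, "threshold"), 0.5)
  attr(m, "threshold") <- NULL
  expect_identical(unname(m), unname(img == 1))
  expect_equal(sum(binarizeNucleus(matrix(0, 8, 8), cfg)), 0)
  expect_error(binarizeNucleus(matrix(2, 4, 4), cfg), "\\[0,1\\]")
})

test_that("otsu threshold lands between two well-separated modes", {
  set.seed(7)
  img <- matrix(pmin(pmax(c(rnorm(2000, 0.1, 0.05), rnorm(2000, 0.9, 0.05)),
                          0), 1), 40, 100)
  mask <- binarizeNucleus(img, detectionConfig("otsu"))
  # brute-force between-class-variance sweep over 256 bins as oracle
  br <- seq(0, 1, length.out = 257)
  h <- hist(img, breaks = br, plot = FALSE)$counts
  mids <- (br[-1] + br[-257]) / 2
  bcv <- vapply(1:255, function(t) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) return(0)
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):256] * mids[(t + 1):256]) / w1
    w0 * w1 * (m0 - m1)^2
  }, numeric(1))
  thrOracle <- mids[which.max(bcv)]
  # any threshold in the empty gap between the modes maximizes the
  # between-class variance; the masks must agree exactly, and the
  # implementation's threshold must separate the two modes
  attr(mask, "threshold") -> thrImplSaved
  attr(mask, "threshold") <- NULL
  expect_identical(unname(mask), unname(img > thrOracle))
  expect_gt(thrImplSaved, 0.3)
  expect_lt(thrImplSaved, 0.7)
  expect_error(binarizeNucleus(matrix(0.4, 16, 16), detectionConfig("otsu")),
               "degenerate")
})

test_that("connectivity semantics: diagonal pixels, empty masks, checkerboard", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1
  m[2, 2] <- 1
  expect_equal(labelComponents(m, 8)$nLabels, 1L)
  expect_equal(labelComponents(m, 4)$nLabels, 2L)
  expect_equal(labelComponents(matrix(0, 5, 5))$nLabels, 0L)
  chk <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(labelComponents(chk, 4)$nLabels, 8L)
  expect_equal(labelComponents(chk, 8)$nLabels, 1L)
})

test_that("union-find labeling agrees with the flood-fill oracle", {
  set.seed(42)
  for (rep in 1:12) {
    m <- matrix(rbinom(900, 1, runif(1, 0.2, 0.7)), 30, 30)
    for (conn in c(4L, 8L)) {
      got <- labelComponents(m, conn)
      oracle <- floodFillLabels(m, conn)
      expect_equal(got$nLabels, max(oracle))
      # identical partition AND identical label numbering (both are
      # defined by raster-scan first appearance)
      expect_identical(unname(got$labels), unname(oracle))
    }
  }
})

test_that("labeling is deterministic", {
  set.seed(1)
  m <- matrix(rbinom(400, 1, 0.5), 20, 20)
  expect_identical(labelComponents(m, 8), labelComponents(m, 8))
})

test_that("record extraction: centroid, bbox, area filter, um scaling", {
  m <- matrix(0, 30, 40)
  m[11:15, 21:25] <- 1    # 5x5 square, 0-based top-left (10, 20)
  rec <- extractRecords(labelComponents(m), 0.5,
                        detectionConfig(minAreaPx = 1))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$centroid_row, 12)
  expect_equal(rec$centroid_col, 22)
  expect_equal(c(rec$bbox_min_row, rec$bbox_min_col, rec$bbox_height,
                 rec$bbox_width), c(10, 20, 5, 5))
  expect_equal(rec$area_px, 25)
  expect_equal(c(rec$centroid_um_y, rec$centroid_um_x), c(6, 11))

  # the 50-px floor: 49 px removed, 50 px kept
  m2 <- matrix(0, 30, 30)
  m2[4:10, 4:10] <- 1
  m2[10, 10] <- 0          # 48 px
  m2[20:24, 20:29] <- 1    # 50 px
  rec2 <- extractRecords(labelComponents(m2), 1, detectionConfig())
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$area_px, 50)
  m2[10, 10] <- 1          # now 49 px: still below the floor
  rec3 <- extractRecords(labelComponents(m2), 1, detectionConfig())
  expect_equal(nrow(rec3), 1L)
  m2[9, 11] <- 1           # 50 px: kept
  rec4 <- extractRecords(labelComponents(m2), 1, detectionConfig())
  expect_equal(nrow(rec4), 2L)
  expect_equal(countNuclei(rec4), 2L)
  expect_equal(countNuclei(NucleoGAN:::.emptyRecords()), 0L)
})

test_that("noise-free synthetic tiles are recovered exactly", {
  for (seed in c(101, 202)) {
    sc <- sampleScene(2, 128, 0.8203, seed = seed, meanCellRadiusUm = 10)
    rp <- renderPair(sc, renderConfig(), seed = seed)
    rec <- detectNuclei(rp$pair)
    expect_equal(nrow(rec), nCells(sc))
    # each detected centroid within 1 px of the true center
    truth <- t(vapply(cells(sc), function(c) c$nucleus_center, numeric(2)))
    for (k in seq_len(nrow(rec))) {
      d <- sqrt(rowSums((truth - matrix(as.numeric(rec[k, c("centroid_row",
        "centroid_col")]), nrow(truth), 2, byrow = TRUE))^2))
      expect_lt(min(d), 1)
    }
  }
})

test_that("nuclei partially outside the image are still counted", {
  # half-off-canvas nucleus: segmentation counts it (the automatic
  # counting bias at image edges)
  img <- matrix(0, 64, 64)
  rr <- outer((0:63) - 0, rep(1, 64))       # nucleus centered at row 0
  cc <- outer(rep(1, 64), (0:63) - 31.5)
  img[rr^2 + cc^2 <= 49] <- 0.9
  rec <- detectNuclei(img, 1, detectionConfig("fixed", 0.5))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$bbox_min_row, 0)
  expect_lt(rec$centroid_row, 3)   # hugs the edge
})
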