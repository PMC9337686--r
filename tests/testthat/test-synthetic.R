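# Synthetic paired-image generator: determinism, geometric invariants,
# and the deterministic fiber-to-nucleus linkage.

test_that("deriveNucleusCenter is the intensity-weighted midpoint centroid", {
  f2 <- list(list(endpoints = rbind(c(5, 5), c(15, 15)), intensity = 1),
             list(endpoints = rbind(c(25, 25), c(35, 35)), intensity = 1))
  expect_equal(deriveNucleusCenter(f2), c(20, 20))
  f1 <- list(list(endpoints = rbind(c(4, 8), c(6, 10)), intensity = 0.7))
  expect_equal(deriveNucleusCenter(f1), c(5, 9))
  fw <- list(list(endpoints = rbind(c(0, -5), c(0, 5)), intensity = 1),
             list(endpoints = rbind(c(0, 5), c(0, 15)), intensity = 3))
  expect_equal(deriveNucleusCenter(fw), c(0, 7.5))
  expect_error(deriveNucleusCenter(list()), "at least one fiber")
})

test_that("sampleScene is a pure function of its arguments", {
  a <- sampleScene(1, 256, 0.625, seed = 7)
  b <- sampleScene(1, 256, 0.625, seed = 7)
  expect_identical(a, b)
  expect_equal(nCells(a), 1L)
  c1 <- sampleScene(2, 128, 0.8203, seed = 9, meanCellRadiusUm = 10)
  c2 <- sampleScene(2, 128, 0.8203, seed = 10, meanCellRadiusUm = 10)
  expect_false(identical(c1, c2))
})

test_that("scenes hold disjoint cells with nuclei inside and exact linkage", {
  sc <- sampleScene(20, 512, 0.41, seed = 1)
  expect_equal(nCells(sc), 20L)
  cl <- cells(sc)
  # pairwise disjoint via the conservative circle bound
  ctrs <- t(vapply(cl, function(c) c$center, numeric(2)))
  maxR <- vapply(cl, function(c) max(c$radii_px), numeric(1))
  for (i in seq_len(19)) for (j in (i + 1):20) {
    d <- sqrt(sum((ctrs[i, ] - ctrs[j, ])^2))
    expect_gt(d, maxR[i] + maxR[j])
  }
  for (cell in cl) {
    # nucleus ellipse sampled densely along its boundary stays inside
    th <- seq(0, 2 * pi, length.out = 64)
    a <- cell$nucleus_radii[1]
    b <- cell$nucleus_radii[2]
    phi <- cell$nucleus_orientation
    br <- cell$nucleus_center[1] + a * cos(th) * cos(phi) -
      b * sin(th) * sin(phi)
    bc <- cell$nucleus_center[2] + a * cos(th) * sin(phi) +
      b * sin(th) * cos(phi)
    inside <- NucleoGAN:::.cellContains(cell, cbind(br, bc), margin = 0)
    expect_true(all(inside))
    # deterministic linkage: stored raw center equals the functional
    expect_equal(cell$nucleus_center_raw, deriveNucleusCenter(cell$fibers))
    # mean nuclear radius close to 4 um
    expect_lt(abs(mean(cell$nucleus_radii) * 0.41 - 4), 1.8)
  }
})

test_that("overcrowded placement fails with a clear error", {
  expect_error(sampleScene(1e6, 64, 0.5, seed = 0), "overcrowded|fit")
})

test_that("rendering separates channels and reproduces exact mask geometry", {
  sc <- sampleScene(2, 128, 0.8203, seed = 21, meanCellRadiusUm = 10)
  cfg <- renderConfig()   # noise-free, no blur
  rp <- renderPair(sc, cfg, seed = 21)
  nuc <- nucleus(rp$pair)
  act <- actin(rp$pair)
  # noise-free nucleus channel is exactly two-valued
  expect_setequal(unique(as.vector(nuc)),
                  c(cfg@backgroundLevel, cfg@nucleusIntensity))
  expect_identical(unname(nuc == cfg@nucleusIntensity),
                   unname(rp$nucleusMask == 1))
  # no nucleus intensity leaks into the actin channel
  fibMax <- max(act)
  expect_lte(max(act[rp$nucleusMask == 1]), fibMax)
  # foreground sparsity: the class imbalance the weighted loss targets
  expect_lt(mean(rp$nucleusMask), 0.10)
  # seeded determinism
  rp2 <- renderPair(sc, cfg, seed = 21)
  expect_identical(rp$pair@nucleus, rp2$pair@nucleus)
  expect_identical(rp$pair@actin, rp2$pair@actin)
})

test_that("zero-intensity fibers render a flat background actin channel", {
  sc <- sampleScene(1, 64, 0.8203, seed = 3)
  for (i in seq_along(cells(sc)[[1]]$fibers))
    sc@cells[[1]]$fibers[[i]]$intensity <- 0
  rp <- renderPair(sc, renderConfig(backgroundLevel = 0.05), seed = 3)
  expect_true(all(actin(rp$pair) == 0.05))
})

test_that("rasterized nucleus area matches the ellipse area", {
  # single circular nucleus of radius 8 px; pixel-center rasterization
  # has O(perimeter) lattice wobble per instance, and is unbiased over
  # sub-pixel placements of the center
  sc <- sampleScene(1, 128, 1, seed = 5, meanCellRadiusUm = 30,
                    meanNucleusRadiusUm = 8)
  areas <- vapply(c(0, 0.2, 0.4, 0.5, 0.7), function(off) {
    sc@cells[[1]]$nucleus_center <- c(63 + off, 63 + off)
    sc@cells[[1]]$nucleus_radii <- c(8, 8)
    sum(renderPair(sc, renderConfig(), seed = 5)$nucleusMask)
  }, numeric(1))
  expect_lt(abs(mean(areas) - pi * 64) / (pi * 64), 0.02)
  expect_true(all(abs(areas - pi * 64) / (pi * 64) < 0.05))
})

test_that("noise models are seeded and respect the [0,1] range", {
  sc <- sampleScene(1, 64, 0.8203, seed = 13)
  cfgN <- renderConfig(psfSigmaPx = 1, noiseModel = "gaussian",
                       noiseParam = 0.03)
  a <- renderPair(sc, cfgN, seed = 4)
  b <- renderPair(sc, cfgN, seed = 4)
  c <- renderPair(sc, cfgN, seed = 5)
  expect_identical(a$pair@actin, b$pair@actin)
  expect_false(identical(a$pair@actin, c$pair@actin))
  expect_true(all(a$pair@actin >= 0 & a$pair@actin <= 1))
  # the mask is the pre-noise footprint: unchanged across noise seeds
  expect_identical(a$nucleusMask, c$nucleusMask)
  pois <- renderPair(sc, renderConfig(noiseModel = "poisson",
                                      noiseParam = 100), seed = 6)
  expect_true(all(pois$pair@nucleus >= 0 & pois$pair@nucleus <= 1))
})

test_that("dataset split is disjoint, sized by rounding, and reproducible", {
  s <- splitIndices(4900, 0.8, seed = 1)
  expect_length(s$train, 3920)
  expect_length(s$test, 980)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(s, splitIndices(4900, 0.8, seed = 1))
  s2 <- splitIndices(10, 0.8, seed = 3)
  expect_length(s2$train, 8)
  expect_length(s2$test, 2)
  expect_error(makeDataset(1, seed = 1), "at least 2")
})

test_that("makeDataset ties images, masks and scenes together", {
  ds <- makeDataset(6, seed = 31, cellsPerTile = 1)
  expect_length(ds$train, 5)
  expect_length(ds$test, 1)
  for (i in seq_along(ds$train)) {
    sc <- ds$trainScenes[[i]]
    # per-tile linkage invariant
    for (cell in cells(sc))
      expect_equal(cell$nucleus_center_raw, deriveNucleusCenter(cell$fibers))
  }
  ds2 <- makeDataset(6, seed = 31, cellsPerTile = 1)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$train[[1]]@actin, ds2$train[[1]]@actin)
})
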