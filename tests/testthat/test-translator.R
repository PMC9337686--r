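# Translator architecture and loss properties (no long training here;
# end-to-end learning behavior is exercised in the acceptance suite).

tinyConfig <- function(...) {
  modelConfig("desk", imageSizePx = 32L, encoderBlocks = 2L,
              transformerBlocks = 2L, attentionHeads = 2L,
              tokenChannels = 16L, baseChannels = 4L, batchSize = 2L,
              seed = 5L, ...)
}

test_that("encoder geometry: token count follows the downsampling", {
  st <- initTranslator(modelConfig("desk", seed = 1))
  enc <- encodeActin(st, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(enc$featureMap), c(16, 16, 32))
  expect_equal(dim(enc$tokens), c(256, 32))
  st2 <- initTranslator(tinyConfig())
  enc2 <- encodeActin(st2, matrix(0, 32, 32))
  expect_equal(dim(enc2$tokens), c(64, 16))
  expect_error(encodeActin(st, matrix(0, 100, 100)), "64 x 64")
  expect_error(modelConfig("desk", imageSizePx = 100L, encoderBlocks = 3L),
               "divisible")
})

test_that("zeroed projections reduce each transformer block to identity", {
  st <- initTranslator(tinyConfig())
  p <- modelParameters(st)
  for (l in seq_along(p$G$trf)) {
    p$G$trf[[l]]$msa$Wo[] <- 0
    p$G$trf[[l]]$msa$bo[] <- 0
    p$G$trf[[l]]$mlp$W2[] <- 0
    p$G$trf[[l]]$mlp$b2[] <- 0
  }
  modelParameters(st) <- p
  z <- matrix(rnorm(64 * 16), 64, 16)
  expect_equal(applyTransformer(st, z), z)
})

test_that("transformer output preserves shape and is token-permutation-equivariant", {
  cfg <- modelConfig("desk", imageSizePx = 8L, encoderBlocks = 2L,
                     transformerBlocks = 2L, attentionHeads = 2L,
                     tokenChannels = 8L, baseChannels = 4L, seed = 11L)
  st <- initTranslator(cfg)
  z <- matrix(rnorm(4 * 8), 4, 8)     # 4-token toy sequence
  out <- applyTransformer(st, z)
  expect_equal(dim(out), dim(z))
  perm <- c(3, 1, 4, 2)
  outP <- applyTransformer(st, z[perm, ])
  expect_equal(outP, out[perm, ], tolerance = 1e-10)
})

test_that("decoder emits doubling resolutions with finite values", {
  st <- initTranslator(modelConfig("desk", seed = 2))
  outs <- decodeTokens(st, matrix(rnorm(256 * 32), 256, 32))
  expect_equal(vapply(outs, nrow, 1L), c(32L, 64L))
  expect_equal(vapply(outs, ncol, 1L), c(32L, 64L))
  expect_true(all(vapply(outs, function(o) all(is.finite(o)), logical(1))))
  # final output matches the configured image size
  expect_equal(dim(outs[[length(outs)]]), c(64L, 64L))
})

test_that("discriminator scores are per-image, bounded and deterministic", {
  st <- initTranslator(tinyConfig())
  imgs <- lapply(1:3, function(i) matrix(runif(1024), 32, 32))
  s <- discriminate(st, imgs)
  expect_length(s, 3L)
  expect_true(all(s > 0 & s < 1))
  expect_identical(s, discriminate(st, imgs))
})

test_that("backpropagation matches central finite differences", {
  ng <- asNamespace("NucleoGAN")
  cfg <- modelConfig("desk", imageSizePx = 16L, encoderBlocks = 2L,
                     transformerBlocks = 1L, attentionHeads = 2L,
                     tokenChannels = 8L, baseChannels = 4L, batchSize = 2L,
                     seed = 99L)
  st <- initTranslator(cfg)
  Gp <- modelParameters(st)$G
  set.seed(64)
  X <- matrix(runif(16 * 16 * 2), ncol = 1)
  gt1 <- matrix(runif(8 * 8 * 2), ncol = 1)
  gt2 <- matrix(runif(16 * 16 * 2), ncol = 1)
  lossOf <- function(p) {
    fwd <- ng$.genFwd(p, X, cfg, 2L)
    sum((fwd$outs[[1]] - gt1)^2) + sum((fwd$outs[[2]] - gt2)^2)
  }
  fwd <- ng$.genFwd(Gp, X, cfg, 2L)
  g <- ng$.genBwd(Gp, cfg, 2L, fwd,
                  list(2 * (fwd$outs[[1]] - gt1), 2 * (fwd$outs[[2]] - gt2)))
  # probe one weight in every layer family
  probes <- list(list("enc", 1L, "c1", "W", 5L), list("enc", 2L, "skip"),
                 list("enc", 2L, "down", "W", 1L), list("epos"),
                 list("trf", 1L, "msa", "Wq"), list("trf", 1L, "msa", "Wo"),
                 list("trf", 1L, "ln1", "g"), list("trf", 1L, "mlp", "W1"),
                 list("dec", 1L, "c2", "W", 9L), list("dec", 2L, "head", "W"))
  for (pp in probes) {
    arr <- Gp
    for (nm in pp) arr <- arr[[nm]]
    ga <- g
    for (nm in pp) ga <- ga[[nm]]
    i <- ((length(arr) * 7) %/% 10) + 1L   # deterministic probe index
    eps <- 1e-6
    mod <- function(v) {
      p2 <- Gp
      path <- paste0(vapply(pp, function(x)
        if (is.character(x)) sprintf("[['%s']]", x)
        else sprintf("[[%d]]", x), character(1)), collapse = "")
      eval(parse(text = paste0("p2", path, "[i] <- v")))
      p2
    }
    num <- (lossOf(mod(arr[i] + eps)) - lossOf(mod(arr[i] - eps))) / (2 * eps)
    expect_equal(ga[i], num, tolerance = 1e-5,
                 label = paste(unlist(pp), collapse = "$"))
  }
})

test_that("weighted reconstruction loss follows the printed decomposition", {
  Igt <- rbind(c(1, 0), c(0, 0))
  Iout <- rbind(c(0.5, 0.2), c(0, 0))
  M <- rbind(c(1, 0), c(0, 0))
  lb <- weightedReconLoss(Iout, Igt, M, alpha = 10)
  expect_equal(lb$recForeground, 0.5)
  expect_equal(lb$recBackground, 0.2)
  expect_equal(lb$recTotal, 5.2)
  # alpha = 1 collapses to the plain l1 sum
  lb1 <- weightedReconLoss(Iout, Igt, M, alpha = 1)
  expect_equal(lb1$recTotal, sum(abs(Iout - Igt)))
  # identity
  expect_equal(weightedReconLoss(Igt, Igt, M, 10)$recTotal, 0)
  expect_error(weightedReconLoss(Iout, Igt, M * 0.5, 10), "binary")
  expect_error(weightedReconLoss(Iout, matrix(0, 3, 3), M, 10), "shape")
})

test_that("loss decomposition holds for random batches", {
  set.seed(31)
  for (i in 1:10) {
    a <- array(runif(16 * 16 * 3), c(16, 16, 3))
    b <- array(runif(16 * 16 * 3), c(16, 16, 3))
    M <- array(rbinom(16 * 16 * 3, 1, 0.2), c(16, 16, 3))
    al <- runif(1, 1, 20)
    lb <- weightedReconLoss(a, b, M, al)
    expect_equal(lb$recTotal, al * lb$recForeground + lb$recBackground,
                 tolerance = 1e-6)
  }
})

test_that("adversarial losses: closed forms and gradient direction", {
  l <- adversarialLosses(0.5, 0.5)
  expect_equal(l$ganDiscriminator, -2 * log(0.5))
  expect_equal(l$ganGenerator, -log(0.5))
  # perfect discriminator: its objective is maxed, generator suffers
  lp <- adversarialLosses(1 - 1e-9, 1e-9)
  expect_lt(lp$ganDiscriminator, 1e-6)
  expect_gt(lp$ganGenerator, 15)
  # improving fakes reduces the generator loss (finite difference)
  f <- function(s) adversarialLosses(0.8, s)$ganGenerator
  eps <- 1e-6
  expect_lt((f(0.3 + eps) - f(0.3 - eps)) / (2 * eps), 0)
  expect_error(adversarialLosses(numeric(0), 0.5), "non-empty")
})

test_that("short training runs are reproducible and well-formed", {
  ds <- makeDataset(8, seed = 41, cellsPerTile = 1, imageSizePx = 32L,
                    meanCellRadiusUm = 6)
  cfg <- tinyConfig(maxIterations = 8L)
  st1 <- trainTranslator(ds$train, ds$trainMasks, cfg)
  st2 <- trainTranslator(ds$train, ds$trainMasks, cfg)
  expect_identical(lossHistory(st1), lossHistory(st2))
  expect_equal(nrow(lossHistory(st1)), 8L)
  lh <- lossHistory(st1)
  expect_equal(lh$rec_total, 10 * lh$rec_fg + lh$rec_bg, tolerance = 1e-9)
  expect_true(all(is.finite(as.matrix(lh))))
  expect_error(trainTranslator(ds$train[1], ds$trainMasks[1], cfg),
               "at least 2")
  expect_error(trainTranslator(ds$train, ds$trainMasks[-1], cfg), "align")
})

test_that("prediction returns a clipped image of the input shape", {
  ds <- makeDataset(4, seed = 43, cellsPerTile = 1, imageSizePx = 32L,
                    meanCellRadiusUm = 6)
  st <- trainTranslator(ds$train, ds$trainMasks, tinyConfig(maxIterations = 3L))
  out <- predictNucleus(st, ds$test[[1]])
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, predictNucleus(st, ds$test[[1]]))
  # checkpoint round trip preserves the prediction exactly
  ck <- file.path(tempdir(), "ck.rds")
  saveTranslator(st, ck)
  expect_identical(predictNucleus(loadTranslator(ck), ds$test[[1]]), out)
  unlink(ck)
})
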