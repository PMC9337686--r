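#' @include AllClasses.R nn-core.R
NULL

# ---- configuration ------------------------------------------------------

#' Construct a translator model configuration
#'
#' Two presets are provided. `"paper"` mirrors the full-scale
#' architecture (256 px tiles, four residual encoder blocks, twelve
#' transformer blocks); it is defined for completeness but is far too
#' heavy for routine runs. `"desk"` is the scaled-down configuration
#' used throughout the tests and examples: 64 px tiles, two encoder and
#' two transformer blocks, 32 token channels. Any field can be
#' overridden by name.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... named overrides of any [ModelConfig-class] slot, e.g.
#'   `alpha = 1`, `maxIterations = 500`, `seed = 7`.
#' @return a [ModelConfig-class].
#' @examples
#' modelConfig("desk", maxIterations = 200, seed = 3)
#' @export
modelConfig <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(imageSizePx = 64L, encoderBlocks = 2L, transformerBlocks = 2L,
         attentionHeads = 4L, tokenChannels = 32L, baseChannels = 8L,
         batchSize = 8L, maxIterations = 1500L)
  } else {
    list(imageSizePx = 256L, encoderBlocks = 4L, transformerBlocks = 12L,
         attentionHeads = 8L, tokenChannels = 256L, baseChannels = 32L,
         batchSize = 8L, maxIterations = 100000L)
  }
  args <- utils::modifyList(c(base, list(
    leakySlope = 0.2, alpha = 10, ganWeight = 1, lrG = 2e-4, lrD = 2e-4,
    adamBeta1 = 0.5, seed = 1L, preset = preset)), list(...))
  ints <- c("imageSizePx", "encoderBlocks", "transformerBlocks",
            "attentionHeads", "tokenChannels", "baseChannels", "batchSize",
            "maxIterations", "seed")
  for (f in ints) args[[f]] <- as.integer(args[[f]])
  do.call(new, c(list("ModelConfig"), args))
}

# encoder output channels per block (last equals tokenChannels)
.encChannels <- function(cfg) {
  nb <- cfg@encoderBlocks
  ch <- pmin(cfg@baseChannels * 2L^(seq_len(nb) - 1L), cfg@tokenChannels)
  ch[nb] <- cfg@tokenChannels
  ch
}

.decChannels <- function(cfg) {
  nb <- cfg@encoderBlocks
  pmax(cfg@tokenChannels %/% 2L^seq_len(nb), cfg@baseChannels)
}

# ---- parameter initialization -------------------------------------------

.mkConv3 <- function(cin, cout, gain = 2) {
  list(W = lapply(1:9, function(k)
         matrix(rnorm(cin * cout, 0, sqrt(gain / (9 * cin))), cin, cout)),
       b = rep(0, cout))
}

.mkLinear <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / cin)
  list(W = matrix(rnorm(cin * cout, 0, sd), cin, cout), b = rep(0, cout))
}

.mkSkip <- function(cin, cout) {
  W <- matrix(0, cin, cout)
  d <- seq_len(min(cin, cout))
  W[cbind(d, d)] <- 1
  W + matrix(rnorm(cin * cout, 0, 0.02), cin, cout)
}

.initGenParams <- function(cfg) {
  nb <- cfg@encoderBlocks
  C <- cfg@tokenChannels
  encCh <- .encChannels(cfg)
  decCh <- .decChannels(cfg)
  Hf <- cfg@imageSizePx %/% 2L^nb
  N <- Hf * Hf
  enc <- vector("list", nb)
  cin <- 1L
  for (b in seq_len(nb)) {
    co <- encCh[b]
    enc[[b]] <- list(c1 = .mkConv3(cin, co), c2 = .mkConv3(co, co),
                     skip = .mkSkip(cin, co), down = .mkConv3(co, co))
    cin <- co
  }
  trf <- lapply(seq_len(cfg@transformerBlocks), function(l) {
    list(ln1 = list(g = rep(1, C), b = rep(0, C)),
         msa = list(Wq = matrix(rnorm(C * C, 0, sqrt(1 / C)), C, C),
                    bq = rep(0, C),
                    Wk = matrix(rnorm(C * C, 0, sqrt(1 / C)), C, C),
                    bk = rep(0, C),
                    Wv = matrix(rnorm(C * C, 0, sqrt(1 / C)), C, C),
                    bv = rep(0, C),
                    Wo = matrix(rnorm(C * C, 0, sqrt(1 / C)), C, C),
                    bo = rep(0, C)),
         ln2 = list(g = rep(1, C), b = rep(0, C)),
         mlp = list(W1 = matrix(rnorm(C * 4 * C, 0, sqrt(2 / C)), C, 4L * C),
                    b1 = rep(0, 4L * C),
                    W2 = matrix(rnorm(4 * C * C, 0, sqrt(1 / (2 * C))),
                                4L * C, C),
                    b2 = rep(0, C)))
  })
  dec <- vector("list", nb)
  cin <- C
  for (b in seq_len(nb)) {
    co <- decCh[b]
    # output heads start dark (sigmoid(-2) ~ 0.12): matches the mostly
    # black nucleus channel and avoids a bright initial bias
    dec[[b]] <- list(c1 = .mkConv3(cin, co), c2 = .mkConv3(co, co),
                     skip = .mkSkip(cin, co),
                     head = list(W = matrix(rnorm(co, 0, 0.1), co, 1),
                                 b = -2))
    cin <- co
  }
  list(enc = enc, epos = matrix(rnorm(N * C, 0, 0.02), N, C),
       trf = trf, dec = dec)
}

.disChannels <- function(cfg) {
  nDown <- as.integer(round(log2(cfg@imageSizePx / 4)))
  pmin(cfg@baseChannels * 2L^(seq_len(nDown) - 1L), 64L)
}

.initDisParams <- function(cfg) {
  ch <- .disChannels(cfg)
  blocks <- vector("list", length(ch))
  cin <- 1L
  for (b in seq_along(ch)) {
    blocks[[b]] <- .mkConv3(cin, ch[b])
    cin <- ch[b]
  }
  feat <- 16L * cin
  list(blocks = blocks, fc1 = .mkLinear(feat, 128L),
       fc2 = .mkLinear(128L, 1L, sd = 0.05))
}

#' Initialize an untrained translator
#'
#' Builds seeded generator and discriminator weights for a
#' configuration without running any training. Useful for probing
#' architecture properties (shapes, residual identities, equivariances)
#' and as the starting point of [trainTranslator()].
#'
#' @param cfg a [ModelConfig-class].
#' @return a [TrainState-class] at iteration 0.
#' @examples
#' st <- initTranslator(modelConfig("desk", seed = 1))
#' st
#' @export
initTranslator <- function(cfg) {
  params <- .withSeed(cfg@seed, "init",
                      list(G = .initGenParams(cfg), D = .initDisParams(cfg)))
  new("TrainState", params = params, config = cfg,
      lossHistory = .emptyLossHistory(), iteration = 0L)
}

.emptyLossHistory <- function() {
  data.frame(iteration = integer(0), rec_fg = numeric(0),
             rec_bg = numeric(0), rec_total = numeric(0),
             gan_g = numeric(0), gan_d = numeric(0))
}

# ---- generator forward / backward ---------------------------------------

.genFwd <- function(params, X, cfg, B) {
  slope <- cfg@leakySlope
  nb <- cfg@encoderBlocks
  cur <- X
  curH <- cfg@imageSizePx
  encC <- vector("list", nb)
  for (b in seq_len(nb)) {
    shp <- list(H = curH, W = curH, B = B)
    pb <- params$enc[[b]]
    y1 <- .conv3Fwd(cur, shp, pb$c1)
    a1 <- .lreluFwd(y1, slope)
    n1 <- .pixnormFwd(a1$Y)
    y2 <- .conv3Fwd(n1$Y, shp, pb$c2)
    a2 <- .lreluFwd(y2, slope)
    n2 <- .pixnormFwd(a2$Y)
    r <- n2$Y + cur %*% pb$skip
    y3 <- .conv3Fwd(r, shp, pb$down, stride = 2L)
    a3 <- .lreluFwd(y3, slope)
    n3 <- .pixnormFwd(a3$Y)
    encC[[b]] <- list(shp = shp, X = cur, a1 = a1, n1 = n1, a2 = a2,
                      n2 = n2, r = r, a3 = a3, n3 = n3)
    cur <- n3$Y
    curH <- curH %/% 2L
  }
  Hf <- curH
  N <- Hf * Hf
  ti <- .tokIdx(Hf, Hf, B)
  Z <- cur[ti$fwd, , drop = FALSE] +
    params$epos[rep(seq_len(N), times = B), , drop = FALSE]
  trfC <- vector("list", cfg@transformerBlocks)
  for (l in seq_len(cfg@transformerBlocks)) {
    pl <- params$trf[[l]]
    ln1 <- .lnFwd(Z, pl$ln1)
    msa <- .msaFwd(ln1$Y, N, B, cfg@attentionHeads, pl$msa)
    Z1 <- msa$Y + Z
    ln2 <- .lnFwd(Z1, pl$ln2)
    h <- .addBias(ln2$Y %*% pl$mlp$W1, pl$mlp$b1)
    g <- .geluFwd(h)
    M <- .addBias(g$Y %*% pl$mlp$W2, pl$mlp$b2)
    trfC[[l]] <- list(Zin = Z, ln1 = ln1, msa = msa, Z1 = Z1, ln2 = ln2,
                      g = g)
    Z <- M + Z1
  }
  cur <- Z[ti$inv, , drop = FALSE]
  decC <- vector("list", nb)
  outs <- vector("list", nb)
  for (b in seq_len(nb)) {
    ui <- .upIdx(curH, curH, B)
    u <- cur[ui, , drop = FALSE]
    curH <- curH * 2L
    shp <- list(H = curH, W = curH, B = B)
    pb <- params$dec[[b]]
    y1 <- .conv3Fwd(u, shp, pb$c1)
    a1 <- .lreluFwd(y1, slope)
    n1 <- .pixnormFwd(a1$Y)
    y2 <- .conv3Fwd(n1$Y, shp, pb$c2)
    a2 <- .lreluFwd(y2, slope)
    n2 <- .pixnormFwd(a2$Y)
    r <- n2$Y + u %*% pb$skip
    out <- .sigmoid(.addBias(r %*% pb$head$W, pb$head$b))
    decC[[b]] <- list(shp = shp, u = u, a1 = a1, n1 = n1, a2 = a2,
                      n2 = n2, r = r, out = out)
    outs[[b]] <- out
    cur <- r
  }
  list(outs = outs, encC = encC, trfC = trfC, decC = decC, Hf = Hf, N = N)
}

# dOuts: list of gradients w.r.t. each sigmoid output (same shapes)
.genBwd <- function(params, cfg, B, fwd, dOuts) {
  slope <- cfg@leakySlope
  nb <- cfg@encoderBlocks
  gEnc <- vector("list", nb)
  gDec <- vector("list", nb)
  gTrf <- vector("list", cfg@transformerBlocks)
  dcur <- NULL
  for (b in rev(seq_len(nb))) {
    cc <- fwd$decC[[b]]
    pb <- params$dec[[b]]
    out <- cc$out
    dr <- if (is.null(dcur)) NULL else dcur
    dlog <- dOuts[[b]] * out * (1 - out)
    dHeadW <- crossprod(cc$r, dlog)
    dHeadB <- sum(dlog)
    drHead <- dlog %*% t(pb$head$W)
    dr <- if (is.null(dr)) drHead else dr + drHead
    dn2 <- dr
    da2 <- .pixnormBwd(dn2, cc$n2)
    dy2 <- .lreluBwd(da2, cc$a2)
    b2 <- .conv3Bwd(dy2, cc$n1$Y, cc$shp, pb$c2)
    da1 <- .pixnormBwd(b2$dX, cc$n1)
    dy1 <- .lreluBwd(da1, cc$a1)
    b1 <- .conv3Bwd(dy1, cc$u, cc$shp, pb$c1)
    du <- b1$dX + dr %*% t(pb$skip)
    dskip <- crossprod(cc$u, dr)
    # undo nearest-neighbour upsampling: sum gradients over children
    Hin <- cc$shp$H %/% 2L
    ui <- .upIdx(Hin, Hin, B)
    dcur <- rowsum(du, group = ui)
    dimnames(dcur) <- NULL
    gDec[[b]] <- list(c1 = b1$grad, c2 = b2$grad, skip = dskip,
                      head = list(W = dHeadW, b = dHeadB))
  }
  ti <- .tokIdx(fwd$Hf, fwd$Hf, B)
  dZ <- dcur[ti$fwd, , drop = FALSE]
  for (l in rev(seq_len(cfg@transformerBlocks))) {
    cc <- fwd$trfC[[l]]
    pl <- params$trf[[l]]
    dM <- dZ
    dG <- dM %*% t(pl$mlp$W2)
    gW2 <- crossprod(cc$g$Y, dM)
    gB2 <- colSums(dM)
    dh <- .geluBwd(dG, cc$g)
    gW1 <- crossprod(cc$ln2$Y, dh)
    gB1 <- colSums(dh)
    dln2out <- dh %*% t(pl$mlp$W1)
    l2 <- .lnBwd(dln2out, cc$Z1, pl$ln2, cc$ln2)
    dZ1 <- dZ + l2$dX
    dmsa <- dZ1
    mb <- .msaBwd(dmsa, cc$ln1$Y, fwd$N, B, cfg@attentionHeads, pl$msa,
                  cc$msa)
    l1 <- .lnBwd(mb$dX, cc$Zin, pl$ln1, cc$ln1)
    dZ <- dZ1 + l1$dX
    gTrf[[l]] <- list(ln1 = l1$grad, msa = mb$grad, ln2 = l2$grad,
                      mlp = list(W1 = gW1, b1 = gB1, W2 = gW2, b2 = gB2))
  }
  dEpos <- rowsum(dZ, group = rep(seq_len(fwd$N), times = B))
  dimnames(dEpos) <- NULL
  dcur <- dZ[ti$inv, , drop = FALSE]
  for (b in rev(seq_len(nb))) {
    cc <- fwd$encC[[b]]
    pb <- params$enc[[b]]
    dn3 <- dcur
    da3 <- .pixnormBwd(dn3, cc$n3)
    dy3 <- .lreluBwd(da3, cc$a3)
    b3 <- .conv3Bwd(dy3, cc$r, cc$shp, pb$down, stride = 2L)
    dr <- b3$dX
    dn2 <- dr
    da2 <- .pixnormBwd(dn2, cc$n2)
    dy2 <- .lreluBwd(da2, cc$a2)
    b2 <- .conv3Bwd(dy2, cc$n1$Y, cc$shp, pb$c2)
    da1 <- .pixnormBwd(b2$dX, cc$n1)
    dy1 <- .lreluBwd(da1, cc$a1)
    b1 <- .conv3Bwd(dy1, cc$X, cc$shp, pb$c1)
    dskip <- crossprod(cc$X, dr)
    dcur <- b1$dX + dr %*% t(pb$skip)
    gEnc[[b]] <- list(c1 = b1$grad, c2 = b2$grad, skip = dskip,
                      down = b3$grad)
  }
  list(enc = gEnc, epos = dEpos, trf = gTrf, dec = gDec)
}

# ---- discriminator forward / backward -----------------------------------

.disFwd <- function(params, X, cfg, B) {
  slope <- cfg@leakySlope
  cur <- X
  curH <- cfg@imageSizePx
  caches <- vector("list", length(params$blocks))
  for (b in seq_along(params$blocks)) {
    shp <- list(H = curH, W = curH, B = B)
    y <- .conv3Fwd(cur, shp, params$blocks[[b]], stride = 2L)
    a <- .lreluFwd(y, slope)
    caches[[b]] <- list(shp = shp, X = cur, a = a)
    cur <- a$Y
    curH <- curH %/% 2L
  }
  npx <- curH * curH
  C <- ncol(cur)
  Fm <- matrix(0, B, npx * C)
  for (b in seq_len(B))
    Fm[b, ] <- as.vector(cur[((b - 1L) * npx + 1L):(b * npx), ])
  h1 <- .addBias(Fm %*% params$fc1$W, params$fc1$b)
  a1 <- .lreluFwd(h1, slope)
  logits <- .addBias(a1$Y %*% params$fc2$W, params$fc2$b)
  list(logits = as.vector(logits), Fm = Fm, a1 = a1, caches = caches,
       npx = npx, C = C)
}

.disBwd <- function(params, cfg, B, fwd, dlogits, needInputGrad = FALSE) {
  slope <- cfg@leakySlope
  dlog <- matrix(dlogits, B, 1)
  gFc2 <- list(W = crossprod(fwd$a1$Y, dlog), b = sum(dlog))
  da1 <- dlog %*% t(params$fc2$W)
  dh1 <- .lreluBwd(da1, fwd$a1)
  gFc1 <- list(W = crossprod(fwd$Fm, dh1), b = colSums(dh1))
  dFm <- dh1 %*% t(params$fc1$W)
  npx <- fwd$npx
  C <- fwd$C
  dcur <- matrix(0, npx * B, C)
  for (b in seq_len(B))
    dcur[((b - 1L) * npx + 1L):(b * npx), ] <- matrix(dFm[b, ], npx, C)
  gBlocks <- vector("list", length(params$blocks))
  for (b in rev(seq_along(params$blocks))) {
    cc <- fwd$caches[[b]]
    dy <- .lreluBwd(dcur, cc$a)
    bb <- .conv3Bwd(dy, cc$X, cc$shp, params$blocks[[b]], stride = 2L)
    dcur <- bb$dX
    gBlocks[[b]] <- bb$grad
  }
  out <- list(grad = list(blocks = gBlocks, fc1 = gFc1, fc2 = gFc2))
  if (needInputGrad) out$dX <- dcur
  out
}

# ---- exported model operations ------------------------------------------

.imageToX <- function(image, cfg) {
  if (!is.matrix(image) || nrow(image) != cfg@imageSizePx ||
      ncol(image) != cfg@imageSizePx)
    stop("image must be a ", cfg@imageSizePx, " x ", cfg@imageSizePx,
         " matrix for this configuration (side divisible by 2^encoderBlocks)")
  matrix(as.vector(image), ncol = 1L)
}

#' Encode an actin image into transformer tokens
#'
#' Runs the convolutional encoder: each residual block halves the
#' resolution, so an `S` px image becomes an `S / 2^encoderBlocks`
#' feature map whose `N = (S / 2^encoderBlocks)^2` spatial positions are
#' flattened row-major into tokens and offset by the learned position
#' embedding.
#'
#' @param state a [TrainState-class].
#' @param image single-channel matrix at the configured size.
#' @return list with `featureMap` (array Hf x Hf x C) and `tokens`
#'   (N x C matrix, position embedding added).
#' @examples
#' st <- initTranslator(modelConfig("desk", seed = 1))
#' enc <- encodeActin(st, matrix(0, 64, 64))
#' dim(enc$tokens)  # 256 x 32
#' @export
encodeActin <- function(state, image) {
  cfg <- state@config
  X <- .imageToX(image, cfg)
  fwd <- .genFwd(state@params$G, X, cfg, 1L)
  Hf <- fwd$Hf
  # recover the encoder output (pre-token) feature map
  cur <- fwd$encC[[cfg@encoderBlocks]]$n3$Y
  ti <- .tokIdx(Hf, Hf, 1L)
  tokens <- cur[ti$fwd, , drop = FALSE] + state@params$G$epos
  list(featureMap = array(cur, dim = c(Hf, Hf, ncol(cur))), tokens = tokens)
}

#' Apply the transformer stack to a token sequence
#'
#' Each block computes pre-norm residual self-attention and MLP
#' updates: `z' = MSA(LN(z)) + z` followed by `z = MLP(LN(z')) + z'`.
#' Output shape equals input shape.
#'
#' @param state a [TrainState-class].
#' @param tokens N x C token matrix (C = `tokenChannels`).
#' @return N x C matrix.
#' @examples
#' st <- initTranslator(modelConfig("desk", seed = 1))
#' z <- matrix(rnorm(256 * 32), 256, 32)
#' dim(applyTransformer(st, z))
#' @export
applyTransformer <- function(state, tokens) {
  cfg <- state@config
  if (!is.matrix(tokens) || ncol(tokens) != cfg@tokenChannels)
    stop("tokens must be an N x ", cfg@tokenChannels, " matrix")
  N <- nrow(tokens)
  Z <- tokens
  for (l in seq_len(cfg@transformerBlocks)) {
    pl <- state@params$G$trf[[l]]
    ln1 <- .lnFwd(Z, pl$ln1)
    msa <- .msaFwd(ln1$Y, N, 1L, cfg@attentionHeads, pl$msa)
    Z1 <- msa$Y + Z
    ln2 <- .lnFwd(Z1, pl$ln2)
    h <- .geluFwd(.addBias(ln2$Y %*% pl$mlp$W1, pl$mlp$b1))
    Z <- .addBias(h$Y %*% pl$mlp$W2, pl$mlp$b2) + Z1
  }
  Z
}

#' Decode tokens into multi-resolution images
#'
#' The decoder mirrors the encoder: each block doubles the resolution
#' with nearest-neighbour upsampling plus a residual convolution block,
#' and an output head after every block yields a progressively
#' higher-resolution image — the final one at the configured size.
#' The multi-level outputs let reconstruction errors reach the deep
#' layers directly during training.
#'
#' @param state a [TrainState-class].
#' @param tokens N x C token matrix (N must equal the configured token
#'   count).
#' @return list of image matrices, coarsest first.
#' @examples
#' st <- initTranslator(modelConfig("desk", seed = 1))
#' outs <- decodeTokens(st, matrix(0, 256, 32))
#' vapply(outs, nrow, 1L)  # 32, 64
#' @export
decodeTokens <- function(state, tokens) {
  cfg <- state@config
  Hf <- cfg@imageSizePx %/% 2L^cfg@encoderBlocks
  if (!is.matrix(tokens) || nrow(tokens) != Hf * Hf ||
      ncol(tokens) != cfg@tokenChannels)
    stop("tokens must be ", Hf * Hf, " x ", cfg@tokenChannels)
  slope <- cfg@leakySlope
  ti <- .tokIdx(Hf, Hf, 1L)
  cur <- tokens[ti$inv, , drop = FALSE]
  curH <- Hf
  outs <- vector("list", cfg@encoderBlocks)
  for (b in seq_len(cfg@encoderBlocks)) {
    ui <- .upIdx(curH, curH, 1L)
    u <- cur[ui, , drop = FALSE]
    curH <- curH * 2L
    shp <- list(H = curH, W = curH, B = 1L)
    pb <- state@params$G$dec[[b]]
    n1 <- .pixnormFwd(.lreluFwd(.conv3Fwd(u, shp, pb$c1), slope)$Y)
    n2 <- .pixnormFwd(.lreluFwd(.conv3Fwd(n1$Y, shp, pb$c2), slope)$Y)
    r <- n2$Y + u %*% pb$skip
    outs[[b]] <- matrix(.sigmoid(.addBias(r %*% pb$head$W, pb$head$b)),
                        curH, curH)
    cur <- r
  }
  outs
}

#' Score images as real or generated
#'
#' The discriminator downsamples its input to 4 x 4 resolution with
#' strided convolutions and applies fully connected layers; the output
#' is squashed to a realness probability (1 = real, 0 = fake).
#'
#' @param state a [TrainState-class].
#' @param images a single image matrix or a list of image matrices at
#'   the configured size.
#' @return numeric vector of realness scores in (0, 1), one per image.
#' @examples
#' st <- initTranslator(modelConfig("desk", seed = 1))
#' discriminate(st, matrix(0.5, 64, 64))
#' @export
discriminate <- function(state, images) {
  cfg <- state@config
  if (is.matrix(images)) images <- list(images)
  B <- length(images)
  X <- matrix(unlist(lapply(images, function(m) .imageToX(m, cfg))),
              ncol = 1L)
  fwd <- .disFwd(state@params$D, X, cfg, B)
  .sigmoid(fwd$logits)
}

#' Generate a nucleus image from an actin image
#'
#' Full generator forward pass: encoder, transformer, decoder. The
#' finest-resolution output is returned, clipped to \[0,1\].
#'
#' @param state a trained [TrainState-class].
#' @param actinImage single-channel matrix at the configured size, or an
#'   [ImagePair-class] (its actin channel is used).
#' @return matrix of the generated nucleus channel in \[0,1\], same
#'   shape as the input.
#' @examples
#' st <- initTranslator(modelConfig("desk", seed = 1))
#' dim(predictNucleus(st, matrix(0, 64, 64)))
#' @export
predictNucleus <- function(state, actinImage) {
  if (is(actinImage, "ImagePair")) actinImage <- actinImage@actin
  cfg <- state@config
  X <- .imageToX(actinImage, cfg)
  fwd <- .genFwd(state@params$G, X, cfg, 1L)
  out <- fwd$outs[[cfg@encoderBlocks]]
  .clamp01(matrix(out, cfg@imageSizePx, cfg@imageSizePx))
}
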