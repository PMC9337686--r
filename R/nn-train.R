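#' @include nn-model.R nn-losses.R
NULL

# average-pool a (H, W) matrix by an integer factor
.avgPool <- function(M, f) {
  if (f == 1L) return(M)
  H <- nrow(M)
  W <- ncol(M)
  A <- array(M, c(f, H %/% f, f, W %/% f))
  colMeans(aperm(A, c(1, 3, 2, 4)), dims = 2L)
}

#' Train the translator under weighted reconstruction + adversarial loss
#'
#' Alternates one discriminator and one generator Adam step per
#' iteration. The generator objective is the multi-level weighted L1
#' reconstruction loss (finest level at full weight, coarser heads at
#' half weight, each against the average-pooled ground truth and mask)
#' plus `ganWeight` times the non-saturating adversarial term. The
#' discriminator minimizes the standard minimax objective on real
#' versus generated nucleus images.
#'
#' Fully seeded: weight initialization, batch order and every other
#' random draw derive from `cfg@seed`, so identical inputs yield an
#' identical `lossHistory`. Training aborts with a diagnostic if any
#' loss becomes non-finite.
#'
#' @param trainPairs list of [ImagePair-class] objects.
#' @param masks list of binary nucleus masks aligned with `trainPairs`
#'   (the pre-noise footprints from [renderPair()] for synthetic data;
#'   for real data, a thresholded ground-truth nucleus channel).
#' @param cfg a [ModelConfig-class]; `cfg@maxIterations` iterations are
#'   run (override with `iterations`).
#' @param iterations optional iteration count overriding the config.
#' @param state optional [TrainState-class] to continue training from.
#' @param verbose print a progress line every 100 iterations.
#' @return a [TrainState-class].
#' @examples
#' \donttest{
#' ds <- makeDataset(12, seed = 1, cellsPerTile = 1)
#' cfg <- modelConfig("desk", maxIterations = 5, batchSize = 4, seed = 1)
#' st <- trainTranslator(ds$train, ds$trainMasks, cfg)
#' lossHistory(st)
#' }
#' @export
trainTranslator <- function(trainPairs, masks, cfg, iterations = NULL,
                            state = NULL, verbose = FALSE) {
  n <- length(trainPairs)
  if (n < 2L) stop("trainTranslator: need at least 2 training pairs")
  if (length(masks) != n)
    stop("trainTranslator: masks must align with trainPairs")
  S <- cfg@imageSizePx
  for (i in seq_len(n)) {
    if (!identical(dim(trainPairs[[i]]@actin), c(S, S)))
      stop("trainTranslator: pair ", i, " is not ", S, " x ", S)
    if (!identical(dim(masks[[i]]), c(S, S)) || !.isBinary(masks[[i]]))
      stop("trainTranslator: mask ", i, " must be a binary ", S, " x ", S,
           " matrix")
  }
  iters <- if (is.null(iterations)) cfg@maxIterations else as.integer(iterations)
  B <- cfg@batchSize
  nb <- cfg@encoderBlocks
  alpha <- cfg@alpha

  Xall <- vapply(trainPairs, function(p) as.vector(p@actin), numeric(S * S))
  # per-level pooled targets and masks (mask: any nucleus coverage)
  gtL <- vector("list", nb)
  mkL <- vector("list", nb)
  lvlW <- c(rep(0.5, nb - 1L), 1)
  for (l in seq_len(nb)) {
    f <- 2L^(nb - l)
    Sl <- S %/% f
    gtL[[l]] <- vapply(trainPairs,
                       function(p) as.vector(.avgPool(p@nucleus, f)),
                       numeric(Sl * Sl))
    mkL[[l]] <- vapply(masks,
                       function(m) as.vector((.avgPool(m + 0, f) > 0) + 0),
                       numeric(Sl * Sl))
  }

  if (is.null(state)) state <- initTranslator(cfg)
  Gp <- state@params$G
  Dp <- state@params$D
  adG <- .adamInit(Gp)
  adD <- .adamInit(Dp)
  idxMat <- .withSeed(cfg@seed, "batches",
                      matrix(sample.int(n, B * iters, replace = TRUE), B,
                             iters))
  hist <- matrix(NA_real_, iters, 5L)
  for (it in seq_len(iters)) {
    idx <- idxMat[, it]
    X <- matrix(as.vector(Xall[, idx]), ncol = 1L)
    fwd <- .genFwd(Gp, X, cfg, B)
    fake <- fwd$outs[[nb]]

    # --- discriminator step ---
    Yreal <- matrix(as.vector(gtL[[nb]][, idx]), ncol = 1L)
    dfR <- .disFwd(Dp, Yreal, cfg, B)
    dfF <- .disFwd(Dp, fake, cfg, B)
    lossD <- mean(.softplus(-dfR$logits)) + mean(.softplus(dfF$logits))
    gR <- .disBwd(Dp, cfg, B, dfR, -.sigmoid(-dfR$logits) / B)$grad
    gF <- .disBwd(Dp, cfg, B, dfF, .sigmoid(dfF$logits) / B)$grad
    up <- .adamUpdate(Dp, .gradAdd(gR, gF), adD, cfg@lrD, cfg@adamBeta1)
    Dp <- up$params
    adD <- up$state

    # --- generator step (reconstruction + adversarial) ---
    dOuts <- vector("list", nb)
    fg <- 0
    bg <- 0
    for (l in seq_len(nb)) {
      out <- fwd$outs[[l]]
      gt <- matrix(as.vector(gtL[[l]][, idx]), ncol = 1L)
      mk <- matrix(as.vector(mkL[[l]][, idx]), ncol = 1L)
      diff <- out - gt
      fg <- fg + lvlW[l] * sum(mk * abs(diff)) / B
      bg <- bg + lvlW[l] * sum((1 - mk) * abs(diff)) / B
      w <- alpha * mk + (1 - mk)
      dOuts[[l]] <- lvlW[l] * w * sign(diff) / B
    }
    dfF2 <- .disFwd(Dp, fake, cfg, B)
    lossGadv <- mean(.softplus(-dfF2$logits))
    bbF <- .disBwd(Dp, cfg, B, dfF2,
                   cfg@ganWeight * (-.sigmoid(-dfF2$logits)) / B,
                   needInputGrad = TRUE)
    dOuts[[nb]] <- dOuts[[nb]] + bbF$dX
    gG <- .genBwd(Gp, cfg, B, fwd, dOuts)
    up <- .adamUpdate(Gp, gG, adG, cfg@lrG, cfg@adamBeta1)
    Gp <- up$params
    adG <- up$state

    hist[it, ] <- c(fg, bg, alpha * fg + bg, lossGadv, lossD)
    if (any(!is.finite(hist[it, ])))
      stop("trainTranslator: training diverged at iteration ",
           state@iteration + it, " (non-finite loss)")
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %d: rec %.2f (fg %.2f bg %.2f) G %.3f D %.3f",
                      it, hist[it, 3], hist[it, 1], hist[it, 2],
                      hist[it, 4], hist[it, 5]))
  }
  lh <- data.frame(iteration = state@iteration + seq_len(iters),
                   rec_fg = hist[, 1], rec_bg = hist[, 2],
                   rec_total = hist[, 3], gan_g = hist[, 4],
                   gan_d = hist[, 5])
  new("TrainState", params = list(G = Gp, D = Dp), config = cfg,
      lossHistory = rbind(state@lossHistory, lh),
      iteration = state@iteration + iters)
}

#' Save / load a translator checkpoint
#'
#' A checkpoint is a single serialized file holding the full
#' [TrainState-class]: weights, the embedded [ModelConfig-class] and
#' the loss history.
#'
#' @param state a [TrainState-class].
#' @param path checkpoint file path.
#' @return `saveTranslator` invisibly returns `path`; `loadTranslator`
#'   returns the restored [TrainState-class].
#' @export
saveTranslator <- function(state, path) {
  stopifnot(is(state, "TrainState"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname saveTranslator
#' @export
loadTranslator <- function(path) {
  state <- readRDS(path)
  if (!is(state, "TrainState"))
    stop("loadTranslator: ", path, " does not hold a TrainState")
  validObject(state)
  state
}
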