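#' @include nn-core.R
NULL

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Pixel-weighted L1 reconstruction loss
#'
#' The nucleus channel is mostly black background, so a plain L1 loss
#' drives a generator toward all-black output. The weighted loss
#' up-weights nucleus pixels by `alpha`:
#' \deqn{L_{rec} = \sum_x \alpha \, M(x)\,|I_{out}(x)-I_{gt}(x)| +
#'       (1-M(x))\,|I_{out}(x)-I_{gt}(x)|}
#' where `M` is the binary nucleus mask (1 inside nuclei). The sum runs
#' over pixels; with batched inputs (3D arrays, batch along the third
#' dimension) the per-image sums are averaged over the batch.
#'
#' @param Iout generated image, matrix or 3D array.
#' @param Igt ground-truth image, same shape.
#' @param M binary mask, same shape, values 0/1.
#' @param alpha foreground weight (>= 1; 10 by default — one order of
#'   magnitude, matching the foreground/background imbalance).
#' @return list with `recForeground`, `recBackground`, `recTotal`
#'   (`recTotal = alpha * recForeground + recBackground`) and `alpha`.
#' @examples
#' Igt <- rbind(c(1, 0), c(0, 0))
#' Iout <- rbind(c(0.5, 0.2), c(0, 0))
#' M <- rbind(c(1, 0), c(0, 0))
#' weightedReconLoss(Iout, Igt, M, alpha = 10)  # fg 0.5, bg 0.2, total 5.2
#' @export
weightedReconLoss <- function(Iout, Igt, M, alpha = 10) {
  if (!identical(dim(Iout), dim(Igt)) || !identical(dim(Iout), dim(M)))
    stop("weightedReconLoss: Iout, Igt and M must have identical shape")
  if (!.isBinary(M)) stop("weightedReconLoss: mask M must be binary (0/1)")
  if (alpha < 1) stop("weightedReconLoss: alpha must be >= 1")
  nBatch <- if (length(dim(Iout)) == 3L) dim(Iout)[3L] else 1L
  ad <- abs(Iout - Igt)
  fg <- sum(M * ad) / nBatch
  bg <- sum((1 - M) * ad) / nBatch
  list(recForeground = fg, recBackground = bg,
       recTotal = alpha * fg + bg, alpha = alpha)
}

#' Adversarial losses of the minimax game
#'
#' The discriminator is trained to score real nucleus images as 1 and
#' generated ones as 0 by maximizing
#' `E[log D(real)] + E[log(1 - D(fake))]`; its loss here is the
#' negative of that objective. The generator minimizes the
#' non-saturating counterpart `-E[log D(fake)]`, which plays the same
#' game but keeps gradients alive when the discriminator wins early.
#'
#' @param realScores discriminator probabilities on real images (0,1).
#' @param fakeScores discriminator probabilities on generated images.
#' @return list with `ganGenerator` and `ganDiscriminator`.
#' @examples
#' adversarialLosses(0.5, 0.5)$ganDiscriminator  # -2 * log(0.5)
#' @export
adversarialLosses <- function(realScores, fakeScores) {
  if (length(realScores) == 0L || length(fakeScores) == 0L)
    stop("adversarialLosses: batches must be non-empty")
  eps <- 1e-12
  r <- pmin(pmax(realScores, eps), 1 - eps)
  f <- pmin(pmax(fakeScores, eps), 1 - eps)
  list(ganGenerator = -mean(log(f)),
       ganDiscriminator = -mean(log(r)) - mean(log(1 - f)))
}
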