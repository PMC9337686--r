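# Low-level neural-network primitives with hand-written backpropagation.
#
# Feature maps are stored as dense matrices of shape (H*W*B) x C: pixels
# in column-major order within each image, images stacked along rows.
# 3x3 convolutions are computed as nine shifted gathers followed by
# (HWB x Cin) %*% (Cin x Cout) matrix products, so all heavy lifting is
# done by BLAS. Shift/stride/upsample index vectors are cached per
# (H, W, B) shape.
#
# Gradients are exact (no autodiff): each .xxxFwd returns the values
# plus the cache its .xxxBwd needs.

.nnIdxCache <- new.env(parent = emptyenv())

# nine gather index vectors for a 3x3 neighborhood; out-of-bounds pixels
# map to a zero row appended at position H*W*B + 1. Offsets are ordered
# so that the transposed (flipped) offset of entry k is entry 10 - k.
.shiftIdx <- function(H, W, B) {
  key <- sprintf("s%d_%d_%d", H, W, B)
  hit <- .nnIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  HW <- H * W
  zero <- HW * B + 1L
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  offs <- cbind(di = rep(-1:1, 3), dj = rep(-1:1, each = 3))
  idx <- matrix(0L, HW * B, 9L)
  for (k in 1:9) {
    ii <- i + offs[k, 1]
    jj <- j + offs[k, 2]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    base <- (jj - 1L) * H + ii
    full <- integer(HW * B)
    for (b in seq_len(B)) {
      fb <- base + (b - 1L) * HW
      fb[!ok] <- zero
      full[((b - 1L) * HW + 1L):(b * HW)] <- fb
    }
    idx[, k] <- full
  }
  res <- list(idx = idx, zero = zero)
  assign(key, res, envir = .nnIdxCache)
  res
}

# gather indices for a stride-2 3x3 convolution: one row per
# low-resolution output pixel, indexing the full-resolution input
.shiftIdx2 <- function(H, W, B) {
  key <- sprintf("s2_%d_%d_%d", H, W, B)
  hit <- .nnIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  HW <- H * W
  zero <- HW * B + 1L
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  i2 <- rep(seq_len(H2), W2)
  j2 <- rep(seq_len(W2), each = H2)
  offs <- cbind(di = rep(-1:1, 3), dj = rep(-1:1, each = 3))
  idx <- matrix(0L, H2 * W2 * B, 9L)
  for (k in 1:9) {
    ii <- 2L * i2 - 1L + offs[k, 1]
    jj <- 2L * j2 - 1L + offs[k, 2]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    base <- (jj - 1L) * H + ii
    full <- integer(H2 * W2 * B)
    for (b in seq_len(B)) {
      fb <- base + (b - 1L) * HW
      fb[!ok] <- zero
      full[((b - 1L) * H2 * W2 + 1L):(b * H2 * W2)] <- fb
    }
    idx[, k] <- full
  }
  assign(key, idx, envir = .nnIdxCache)
  idx
}

.downIdx <- function(H, W, B) {
  key <- sprintf("d%d_%d_%d", H, W, B)
  hit <- .nnIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  i2 <- rep(seq_len(H2), W2)
  j2 <- rep(seq_len(W2), each = H2)
  base <- (2L * j2 - 2L) * H + (2L * i2 - 1L)
  full <- unlist(lapply(seq_len(B) - 1L, function(b) base + b * H * W))
  assign(key, full, envir = .nnIdxCache)
  full
}

# nearest-neighbour x2 upsampling: child row -> parent row in the input
.upIdx <- function(H, W, B) {
  key <- sprintf("u%d_%d_%d", H, W, B)
  hit <- .nnIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- 2L * H
  W2 <- 2L * W
  I <- rep(seq_len(H2), W2)
  J <- rep(seq_len(W2), each = H2)
  base <- ((J + 1L) %/% 2L - 1L) * H + (I + 1L) %/% 2L
  full <- unlist(lapply(seq_len(B) - 1L, function(b) base + b * H * W))
  assign(key, full, envir = .nnIdxCache)
  full
}

# token order permutation: row-major token t -> column-major pixel row
.tokIdx <- function(H, W, B) {
  key <- sprintf("t%d_%d_%d", H, W, B)
  hit <- .nnIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  t <- seq_len(H * W)
  i <- (t - 1L) %/% W + 1L
  j <- (t - 1L) %% W + 1L
  base <- (j - 1L) * H + i
  full <- unlist(lapply(seq_len(B) - 1L, function(b) base + b * H * W))
  inv <- integer(length(full))
  inv[full] <- seq_along(full)
  res <- list(fwd = full, inv = inv)
  assign(key, res, envir = .nnIdxCache)
  res
}

.addBias <- function(Y, b) Y + rep(b, each = nrow(Y))

# ---- 3x3 convolution ----------------------------------------------------

.conv3Fwd <- function(X, shp, p, stride = 1L) {
  if (stride == 2L) {
    idx <- .shiftIdx2(shp$H, shp$W, shp$B)
    return(.conv3FwdCpp(X, idx, p$W, p$b))
  }
  si <- .shiftIdx(shp$H, shp$W, shp$B)
  .conv3FwdCpp(X, si$idx, p$W, p$b)
}

.conv3Bwd <- function(dY, X, shp, p, stride = 1L) {
  out <- if (stride == 2L) {
    .conv3BwdStrideCpp(dY, X, .shiftIdx2(shp$H, shp$W, shp$B), p$W)
  } else {
    .conv3BwdCpp(dY, X, .shiftIdx(shp$H, shp$W, shp$B)$idx, p$W)
  }
  list(dX = out$dX, grad = list(W = out$dW, b = as.vector(out$db)))
}

# ---- pointwise layers ---------------------------------------------------

.lreluFwd <- function(X, slope) {
  f <- (X > 0) + slope * (X <= 0)
  list(Y = X * f, f = f)
}
.lreluBwd <- function(dY, cache) dY * cache$f

.pixnormFwd <- function(X) {
  s <- sqrt(rowMeans(X * X) + 1e-8)
  list(Y = X / s, X = X, s = s)
}
.pixnormBwd <- function(dY, cache) {
  X <- cache$X
  s <- cache$s
  C <- ncol(X)
  dY / s - X * (rowSums(dY * X) / (C * s^3))
}

.lnFwd <- function(X, p) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + 1e-6)
  xhat <- xc * inv
  Y <- .addBias(xhat * rep(p$g, each = nrow(X)), p$b)
  list(Y = Y, xhat = xhat, inv = inv)
}
.lnBwd <- function(dY, X, p, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxh <- dY * rep(p$g, each = nrow(dY))
  dX <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
  list(dX = dX, grad = list(g = dg, b = db))
}

.geluFwd <- function(X) {
  ph <- pnorm(X)
  list(Y = X * ph, X = X, ph = ph)
}
.geluBwd <- function(dY, cache) dY * (cache$ph + cache$X * dnorm(cache$X))

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- multi-head self-attention ------------------------------------------

.msaFwd <- function(Z, N, B, nHeads, p) {
  C <- ncol(Z)
  dh <- C %/% nHeads
  Q <- .addBias(Z %*% p$Wq, p$bq)
  K <- .addBias(Z %*% p$Wk, p$bk)
  V <- .addBias(Z %*% p$Wv, p$bv)
  O <- matrix(0, nrow(Z), C)
  A <- vector("list", B * nHeads)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    for (h in seq_len(nHeads)) {
      cls <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q[rows, cls, drop = FALSE]
      Kh <- K[rows, cls, drop = FALSE]
      S <- tcrossprod(Qh, Kh) / sqrt(dh)
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      Ah <- E / rowSums(E)
      O[rows, cls] <- Ah %*% V[rows, cls, drop = FALSE]
      A[[(b - 1L) * nHeads + h]] <- Ah
    }
  }
  Y <- .addBias(O %*% p$Wo, p$bo)
  list(Y = Y, Q = Q, K = K, V = V, O = O, A = A)
}

.msaBwd <- function(dY, Z, N, B, nHeads, p, cache) {
  C <- ncol(Z)
  dh <- C %/% nHeads
  dO <- dY %*% t(p$Wo)
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dQ <- matrix(0, nrow(Z), C)
  dK <- matrix(0, nrow(Z), C)
  dV <- matrix(0, nrow(Z), C)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    for (h in seq_len(nHeads)) {
      cls <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- cache$A[[(b - 1L) * nHeads + h]]
      dOh <- dO[rows, cls, drop = FALSE]
      Vh <- cache$V[rows, cls, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cls] <- crossprod(Ah, dOh)
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQ[rows, cls] <- dS %*% cache$K[rows, cls, drop = FALSE] / sqrt(dh)
      dK[rows, cls] <- crossprod(dS, cache$Q[rows, cls, drop = FALSE]) / sqrt(dh)
    }
  }
  dZ <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dZ,
       grad = list(Wq = crossprod(Z, dQ), bq = colSums(dQ),
                   Wk = crossprod(Z, dK), bk = colSums(dK),
                   Wv = crossprod(Z, dV), bv = colSums(dV),
                   Wo = dWo, bo = dbo))
}

# ---- Adam ---------------------------------------------------------------

.zerosLike <- function(p) {
  if (is.list(p)) lapply(p, .zerosLike) else p * 0
}

.adamInit <- function(params) {
  list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)
}

.adamUpdate <- function(params, grads, st, lr, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, st$m, st$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = st$t))
}

# accumulate two parallel grad structures
.gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) Map(.gradAdd, a, b) else a + b
}
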