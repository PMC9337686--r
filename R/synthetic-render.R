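#' @include synthetic-scene.R
NULL

#' Construct a render configuration
#'
#' @param psfSigmaPx Gaussian point-spread sigma in pixels (0 disables).
#' @param backgroundLevel constant background intensity in \[0,1).
#' @param noiseModel `"none"`, `"gaussian"` or `"poisson"`.
#' @param noiseParam Gaussian sd, or Poisson photon scale (expected
#'   counts at unit intensity).
#' @param nucleusIntensity peak intensity of rendered nuclei.
#' @param bitDepth 8 or 16 (file output only).
#' @return a [RenderConfig-class].
#' @examples
#' renderConfig()                       # clean render
#' renderConfig(psfSigmaPx = 1, noiseModel = "poisson", noiseParam = 200)
#' @export
renderConfig <- function(psfSigmaPx = 0, backgroundLevel = 0.02,
                         noiseModel = c("none", "gaussian", "poisson"),
                         noiseParam = 0.01, nucleusIntensity = 0.9,
                         bitDepth = 16L) {
  new("RenderConfig", psfSigmaPx = psfSigmaPx,
      backgroundLevel = backgroundLevel,
      noiseModel = match.arg(noiseModel), noiseParam = noiseParam,
      nucleusIntensity = nucleusIntensity, bitDepth = as.integer(bitDepth))
}

# anti-aliased thick segment rendering, accumulated with pmax
.rasterFibers <- function(scene) {
  n <- scene@imageSizePx
  field <- matrix(0, n, n)
  rowc <- seq_len(n) - 1
  colc <- seq_len(n) - 1
  for (cell in scene@cells) {
    for (f in cell$fibers) {
      if (f$intensity <= 0) next
      p1 <- f$endpoints[1, ]
      p2 <- f$endpoints[2, ]
      half <- f$width_px / 2
      pad <- ceiling(half + 1.5)
      r0 <- max(1L, floor(min(p1[1], p2[1])) - pad + 1L)
      r1 <- min(n, ceiling(max(p1[1], p2[1])) + pad + 1L)
      c0 <- max(1L, floor(min(p1[2], p2[2])) - pad + 1L)
      c1 <- min(n, ceiling(max(p1[2], p2[2])) + pad + 1L)
      rr <- rowc[r0:r1]
      cc <- colc[c0:c1]
      v <- p2 - p1
      len2 <- sum(v^2)
      dr <- outer(rr - p1[1], rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - p1[2])
      t <- if (len2 > 0) .clamp01((dr * v[1] + dc * v[2]) / len2) else 0 * dr
      dist <- sqrt((dr - t * v[1])^2 + (dc - t * v[2])^2)
      a <- f$intensity * .clamp01(half + 0.5 - dist)
      field[r0:r1, c0:c1] <- pmax(field[r0:r1, c0:c1], a)
    }
  }
  field
}

.rasterNuclei <- function(scene) {
  n <- scene@imageSizePx
  mask <- matrix(0L, n, n)
  rowc <- seq_len(n) - 1
  for (cell in scene@cells) {
    ctr <- cell$nucleus_center
    a <- cell$nucleus_radii[1]
    b <- cell$nucleus_radii[2]
    phi <- cell$nucleus_orientation
    pad <- ceiling(a) + 1L
    r0 <- max(1L, floor(ctr[1]) - pad + 1L)
    r1 <- min(n, ceiling(ctr[1]) + pad + 1L)
    c0 <- max(1L, floor(ctr[2]) - pad + 1L)
    c1 <- min(n, ceiling(ctr[2]) + pad + 1L)
    if (r0 > r1 || c0 > c1) next
    dr <- outer(rowc[r0:r1] - ctr[1], rep(1, c1 - c0 + 1L))
    dc <- outer(rep(1, r1 - r0 + 1L), rowc[c0:c1] - ctr[2])
    u <- dr * cos(phi) + dc * sin(phi)
    v <- -dr * sin(phi) + dc * cos(phi)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    mask[r0:r1, c0:c1] <- pmax(mask[r0:r1, c0:c1], inside * 1L)
  }
  mask
}

.applyOptics <- function(field, cfg, seed, tag) {
  if (cfg@psfSigmaPx > 0)
    field <- EBImage::gblur(field, sigma = cfg@psfSigmaPx)
  img <- pmax(field, cfg@backgroundLevel)
  if (cfg@noiseModel != "none") {
    img <- .withSeed(seed, tag, {
      if (cfg@noiseModel == "gaussian") {
        img + matrix(rnorm(length(img), 0, cfg@noiseParam), nrow(img))
      } else {
        s <- cfg@noiseParam
        matrix(rpois(length(img), as.vector(img) * s) / s, nrow(img))
      }
    })
  }
  .clamp01(img)
}

#' Render a scene into a registered actin/nucleus image pair
#'
#' The actin channel rasterizes fiber segments only (anti-aliased thick
#' lines); the nucleus channel rasterizes nucleus ellipses only — there
#' is no cross-channel leakage. Both channels then receive the same
#' optics: Gaussian PSF blur, constant background, and optional shot or
#' read noise. The returned `nucleusMask` is the exact pre-noise,
#' pre-blur binary footprint of all nuclei: the mask M of the weighted
#' reconstruction loss.
#'
#' With `noiseModel = "none"` and `psfSigmaPx = 0` the nucleus channel
#' takes exactly two values, the background level and the nucleus
#' intensity.
#'
#' @param scene a [SceneSpec-class].
#' @param cfg a [RenderConfig-class].
#' @param seed integer seed for the noise stream (defaults to the scene
#'   seed).
#' @param id identifier stored in the resulting [ImagePair-class].
#' @return list with elements `pair` ([ImagePair-class]) and
#'   `nucleusMask` (integer 0/1 matrix).
#' @examples
#' sc <- sampleScene(1, 64, 0.8203, seed = 3)
#' rp <- renderPair(sc, renderConfig(), seed = 3)
#' range(nucleus(rp$pair))
#' @export
renderPair <- function(scene, cfg = renderConfig(), seed = scene@seed,
                       id = sprintf("scene%06d", scene@seed)) {
  stopifnot(is(scene, "SceneSpec"), is(cfg, "RenderConfig"))
  fib <- .rasterFibers(scene)
  mask <- .rasterNuclei(scene)
  actinImg <- .applyOptics(fib, cfg, seed, "noise-actin")
  nucImg <- .applyOptics(mask * cfg@nucleusIntensity, cfg, seed, "noise-nucleus")
  pair <- new("ImagePair", actin = actinImg, nucleus = nucImg,
              pixelSizeUm = scene@pixelSizeUm, id = id)
  list(pair = pair, nucleusMask = mask)
}

#' Reproducible train/test split indices
#'
#' @param nTiles total number of tiles (>= 2).
#' @param splitFraction fraction assigned to training (0 < f < 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`;
#'   `length(train) == round(splitFraction * nTiles)`.
#' @examples
#' s <- splitIndices(4900, 0.8, seed = 1)
#' lengths(s)  # 3920 train / 980 test
#' @export
splitIndices <- function(nTiles, splitFraction = 0.8, seed) {
  stopifnot(nTiles >= 2, splitFraction > 0, splitFraction < 1)
  nTrain <- min(max(round(splitFraction * nTiles), 1L), nTiles - 1L)
  perm <- .withSeed(seed, "split", sample.int(nTiles))
  list(train = sort(perm[seq_len(nTrain)]),
       test = sort(perm[seq.int(nTrain + 1L, nTiles)]))
}

#' Generate a full synthetic paired dataset with train/test split
#'
#' Samples `nTiles` scenes, renders each into an [ImagePair-class] plus
#' its nucleus mask, and splits tiles into training and testing subsets
#' (default 80/20, the conventional split for this kind of dataset).
#' Everything is a pure function of `seed`.
#'
#' @param nTiles number of tiles (>= 2).
#' @param splitFraction training fraction.
#' @param seed integer seed.
#' @param cellsPerTile expected number of cells per tile (Poisson draw,
#'   at least 1).
#' @param imageSizePx,pixelSizeUm tile geometry. The defaults render a
#'   52.5-um field at the same 0.8203 um/px sampling as the full-size
#'   210-um tile.
#' @param cfg a [RenderConfig-class].
#' @param ... further arguments passed to [sampleScene()].
#' @return list with `train`, `test` (lists of [ImagePair-class]),
#'   `trainMasks`, `testMasks`, `trainScenes`, `testScenes`, and
#'   `manifest` (data.frame id/split/pixel_size_um).
#' @examples
#' ds <- makeDataset(4, seed = 1, cellsPerTile = 1, imageSizePx = 48)
#' length(ds$train)
#' @export
makeDataset <- function(nTiles, splitFraction = 0.8, seed,
                        cellsPerTile = 2, imageSizePx = 64L,
                        pixelSizeUm = 0.8203, cfg = renderConfig(), ...) {
  if (nTiles < 2) stop("makeDataset: need at least 2 tiles to split")
  nC <- .withSeed(seed, "ncells",
                  pmax(1L, rpois(nTiles, cellsPerTile)))
  pairs <- vector("list", nTiles)
  masks <- vector("list", nTiles)
  scenes <- vector("list", nTiles)
  for (i in seq_len(nTiles)) {
    tileSeed <- .deriveSeed(seed, sprintf("tile%06d", i))
    # a Poisson draw can occasionally exceed what the tile holds:
    # fall back deterministically to the largest count that places
    k <- nC[i]
    sc <- NULL
    while (is.null(sc)) {
      sc <- tryCatch(
        sampleScene(k, imageSizePx, pixelSizeUm, seed = tileSeed, ...),
        error = function(e) NULL)
      if (is.null(sc)) {
        k <- k - 1L
        if (k < 1L)
          stop("makeDataset: tile geometry cannot hold a single cell")
      }
    }
    rp <- renderPair(sc, cfg, seed = tileSeed,
                     id = sprintf("tile%06d", i))
    pairs[[i]] <- rp$pair
    masks[[i]] <- rp$nucleusMask
    scenes[[i]] <- sc
  }
  sp <- splitIndices(nTiles, splitFraction, seed)
  ids <- vapply(pairs, function(p) p@id, character(1))
  manifest <- data.frame(
    id = ids,
    split = ifelse(seq_len(nTiles) %in% sp$train, "train", "test"),
    pixel_size_um = pixelSizeUm, stringsAsFactors = FALSE)
  list(train = pairs[sp$train], test = pairs[sp$test],
       trainMasks = masks[sp$train], testMasks = masks[sp$test],
       trainScenes = scenes[sp$train], testScenes = scenes[sp$test],
       manifest = manifest)
}
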