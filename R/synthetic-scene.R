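#' @include AllClasses.R
NULL

# --- star-convex cell geometry -------------------------------------------
#
# A cell outline is a star-convex polygon: vertex radii are a smooth
# random modulation of a base radius at fixed angles. The interior is
# defined by the circularly interpolated radial function, which gives an
# exact point-in-cell test without general polygon arithmetic.

.radialAt <- function(cell, theta) {
  ang <- cell$angles
  rad <- cell$radii_px
  th <- theta %% (2 * pi)
  i <- findInterval(th, ang)
  i0 <- ifelse(i == 0L, length(ang), i)
  i1 <- ifelse(i0 == length(ang), 1L, i0 + 1L)
  a0 <- ang[i0]
  a1 <- ifelse(i1 == 1L, ang[1L] + 2 * pi, ang[i1])
  th2 <- ifelse(th < a0, th + 2 * pi, th)
  w <- (th2 - a0) / (a1 - a0)
  rad[i0] * (1 - w) + rad[i1] * w
}

# point-in-cell test for 0-based (row, col) points, with a safety margin
.cellContains <- function(cell, pts, margin = 1) {
  dr <- pts[, 1] - cell$center[1]
  dc <- pts[, 2] - cell$center[2]
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  rho <= .radialAt(cell, theta) - margin
}

.sampleCellShape <- function(centerRC, baseRadiusPx, nVertices = 16L) {
  ang <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  # smooth low-order modulation keeps the outline star-convex and cell-like
  mod <- rep(0, nVertices)
  for (h in 2:4) {
    a <- runif(1, 0, 0.12)
    phi <- runif(1, 0, 2 * pi)
    mod <- mod + a * cos(h * ang + phi)
  }
  radii <- baseRadiusPx * pmax(0.55, 1 + mod)
  outline <- cbind(centerRC[1] + radii * cos(ang),
                   centerRC[2] + radii * sin(ang))
  list(center = centerRC, angles = ang, radii_px = radii, outline = outline)
}

.sampleFibers <- function(cell, nFibers) {
  fibers <- vector("list", nFibers)
  for (k in seq_len(nFibers)) {
    th <- runif(2, 0, 2 * pi)
    f <- runif(2, 0.15, 0.85)
    rmax <- 0.9 * .radialAt(cell, th)
    p <- cbind(cell$center[1] + f * rmax * cos(th),
               cell$center[2] + f * rmax * sin(th))
    fibers[[k]] <- list(endpoints = p,
                        intensity = runif(1, 0.4, 1),
                        width_px = runif(1, 1.0, 2.2))
  }
  fibers
}

# --- exported operations -------------------------------------------------

#' Deterministic actin-to-nucleus positional functional
#'
#' The synthetic generator realizes the positional relationship the
#' analysis is designed to detect: the nucleus centroid of each cell is
#' the intensity-weighted centroid of its fiber midpoints. Any method
#' that recovers nucleus positions from the rendered fibers can
#' therefore be scored against an exactly known ground truth.
#'
#' @param fibers list of fiber segments, each a list with `endpoints`
#'   (2 x 2 matrix of 0-based (row, col) points) and `intensity`.
#' @return numeric length-2 vector, the (row, col) centroid in pixels.
#' @examples
#' f <- list(list(endpoints = rbind(c(0, 0), c(20, 20)), intensity = 1),
#'           list(endpoints = rbind(c(20, 20), c(40, 40)), intensity = 1))
#' deriveNucleusCenter(f)  # (20, 20)
#' @export
deriveNucleusCenter <- function(fibers) {
  if (length(fibers) == 0L)
    stop("deriveNucleusCenter: need at least one fiber")
  mids <- t(vapply(fibers, function(f) colMeans(f$endpoints), numeric(2)))
  w <- vapply(fibers, function(f) f$intensity, numeric(1))
  if (sum(w) <= 0) stop("deriveNucleusCenter: total fiber intensity is zero")
  colSums(mids * w) / sum(w)
}

#' Sample a synthetic multi-cell scene
#'
#' Places `nCells` pairwise-disjoint star-convex cells in a square tile
#' by rejection sampling, fills each with fiber segments, and positions
#' each nucleus at the fiber functional of [deriveNucleusCenter()]
#' (clamped, if necessary, so the whole nucleus stays inside its cell).
#' Nuclear radii average `meanNucleusRadiusUm` (4 um, the mean nuclear
#' radius of confluent NIH3T3 fibroblasts).
#'
#' The operation is a pure function of its arguments: the same call
#' yields a bit-identical scene.
#'
#' @param nCells number of cells (>= 1).
#' @param imageSizePx side of the square tile in pixels.
#' @param pixelSizeUm physical pixel size (um/px).
#' @param seed integer seed.
#' @param meanNucleusRadiusUm mean of the nuclear major/minor radii.
#' @param nucleusRadiusSpread relative sd of the per-nucleus mean radius.
#' @param meanCellRadiusUm average cell base radius.
#' @param fibersPerCell range (min, max) of fibers per cell.
#' @param centerJitterPx sd of optional Gaussian jitter added to the
#'   rendered nucleus center (default 0: strictly deterministic linkage;
#'   the raw fiber-derived centroid is stored either way).
#' @param maxAttempts placement attempts per cell before giving up.
#' @return a [SceneSpec-class].
#' @examples
#' sc <- sampleScene(2, 64, 0.8203, seed = 1)
#' nCells(sc)
#' @export
sampleScene <- function(nCells, imageSizePx, pixelSizeUm, seed,
                        meanNucleusRadiusUm = 4,
                        nucleusRadiusSpread = 0.1,
                        meanCellRadiusUm = 13,
                        fibersPerCell = c(6L, 12L),
                        centerJitterPx = 0,
                        maxAttempts = 500L) {
  stopifnot(nCells >= 1, imageSizePx >= 8, pixelSizeUm > 0)
  .withSeed(seed, "scene", {
    cellsOut <- vector("list", nCells)
    centers <- matrix(numeric(0), 0, 2)
    maxR <- numeric(0)
    for (i in seq_len(nCells)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        baseR <- runif(1, 0.8, 1.25) * meanCellRadiusUm / pixelSizeUm
        lim <- 1.4 * baseR    # upper bound on any vertex radius
        if (2 * lim + 2 >= imageSizePx)
          stop("sampleScene: cells do not fit the tile at this pixel size")
        ctr <- runif(2, lim + 1, imageSizePx - 1 - (lim + 1))
        if (nrow(centers) == 0 ||
            all(sqrt(rowSums((centers - rep(ctr, each = nrow(centers)))^2)) >
                maxR + lim + 2)) {
          cell <- .sampleCellShape(ctr, baseR)
          centers <- rbind(centers, ctr)
          maxR <- c(maxR, max(cell$radii_px))
          cellsOut[[i]] <- cell
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("sampleScene: could not place ", nCells, " disjoint cells in ",
             imageSizePx, " px within the attempt budget (overcrowded)")
    }
    for (i in seq_len(nCells)) {
      cell <- cellsOut[[i]]
      nF <- sample(fibersPerCell[1]:fibersPerCell[2], 1L)
      cell$fibers <- .sampleFibers(cell, nF)
      raw <- deriveNucleusCenter(cell$fibers)
      m <- meanNucleusRadiusUm *
        max(0.6, 1 + rnorm(1, 0, nucleusRadiusSpread)) / pixelSizeUm
      ecc <- runif(1, 0, 0.25)
      radii <- c(m * (1 + ecc), m * (1 - ecc))
      ctrN <- raw
      if (centerJitterPx > 0) ctrN <- ctrN + rnorm(2, 0, centerJitterPx)
      # clamp: whole nucleus (major radius) must stay inside the cell;
      # in a cell barely larger than the nucleus, shrink the nucleus too
      rmin <- 0.9 * min(cell$radii_px)
      if (radii[1] > 0.85 * rmin) radii <- radii * (0.85 * rmin / radii[1])
      allowed <- rmin - radii[1]
      off <- ctrN - cell$center
      d <- sqrt(sum(off^2))
      if (d > allowed) {
        ctrN <- cell$center + if (d > 0) off * (allowed / d) else 0
      }
      cell$nucleus_center_raw <- raw
      cell$nucleus_center <- ctrN
      cell$nucleus_radii <- radii
      cell$nucleus_orientation <- runif(1, 0, pi)
      cellsOut[[i]] <- cell
    }
    new("SceneSpec", cells = cellsOut, imageSizePx = as.integer(imageSizePx),
        pixelSizeUm = pixelSizeUm, seed = as.integer(seed))
  })
}
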