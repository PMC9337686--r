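# Shared fixtures. Heavy artifacts (trained models, datasets) are
# built once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

# desk-scale synthetic dataset used by the training/recovery tests
deskDataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- makeDataset(320, seed = 11, cellsPerTile = 1)
  .fixtures$ds
}

# the main trained desk model (shared across acceptance checks)
deskModel <- function() {
  if (is.null(.fixtures$model)) {
    ds <- deskDataset()
    cfg <- modelConfig("desk", maxIterations = 700L, seed = 11)
    .fixtures$model <- trainTranslator(ds$train, ds$trainMasks, cfg)
  }
  .fixtures$model
}

# a smaller dataset for the foreground-weighting comparison
alphaDataset <- function() {
  if (is.null(.fixtures$alphaDs))
    .fixtures$alphaDs <- makeDataset(120, seed = 11, cellsPerTile = 1)
  .fixtures$alphaDs
}

# matching reports of the trained model over the synthetic test split
deskMatching <- function() {
  if (is.null(.fixtures$matching)) {
    ds <- deskDataset()
    st <- deskModel()
    dc <- detectionConfig()
    reps <- lapply(ds$test, function(p) {
      gen <- predictNucleus(st, p)
      rgt <- tryCatch(detectNuclei(p@nucleus, p@pixelSizeUm, dc),
                      error = function(e) NucleoGAN:::.emptyRecords())
      rgen <- tryCatch(detectNuclei(gen, p@pixelSizeUm, dc),
                       error = function(e) NucleoGAN:::.emptyRecords())
      matchNuclei(rgt, rgen, p@pixelSizeUm)
    })
    .fixtures$matching <- combineMatchingReports(reps)
  }
  .fixtures$matching
}

# independent flood-fill labeling oracle (breadth-first, queue-based;
# the implementation under test uses two-pass union-find instead)
floodFillLabels <- function(mask, connectivity = 8L) {
  m <- mask != 0
  H <- nrow(m)
  W <- ncol(m)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  offs <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  for (ii in seq_len(H)) for (jj in seq_len(W)) {
    if (!m[ii, jj] || lab[ii, jj] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(ii, jj), 1, 2)
    lab[ii, jj] <- nxt
    while (nrow(queue) > 0L) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        ni <- cur[1] + offs[k, 1]
        nj <- cur[2] + offs[k, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

# build a record data.frame from explicit half-open boxes (for
# matcher tests); centroids at box centers
recordsFromBoxes <- function(boxes) {
  if (length(boxes) == 0L) return(NucleoGAN:::.emptyRecords())
  do.call(rbind, lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    data.frame(label = i, area_px = b[3] * b[4],
               centroid_row = b[1] + (b[3] - 1) / 2,
               centroid_col = b[2] + (b[4] - 1) / 2,
               bbox_min_row = b[1], bbox_min_col = b[2],
               bbox_height = b[3], bbox_width = b[4],
               centroid_um_y = NA_real_, centroid_um_x = NA_real_)
  }))
}
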