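#' @include AllClasses.R
NULL

#' Detection configuration
#'
#' @param thresholdMethod `"otsu"` (between-class-variance maximizing
#'   threshold on the intensity histogram) or `"fixed"`.
#' @param fixedThreshold threshold in \[0,1\] when `thresholdMethod`
#'   is `"fixed"`.
#' @param minAreaPx components smaller than this many pixels are
#'   discarded as segmentation noise (default 50).
#' @param connectivity 4 or 8 neighbourhood for component labeling.
#' @return a plain list used by the detection functions.
#' @examples
#' detectionConfig(minAreaPx = 50)
#' @export
detectionConfig <- function(thresholdMethod = c("otsu", "fixed"),
                            fixedThreshold = 0.5, minAreaPx = 50L,
                            connectivity = 8L) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(minAreaPx >= 1, connectivity %in% c(4L, 8L),
            fixedThreshold >= 0, fixedThreshold <= 1)
  list(thresholdMethod = thresholdMethod,
       fixedThreshold = fixedThreshold,
       minAreaPx = as.integer(minAreaPx),
       connectivity = as.integer(connectivity))
}

#' Binarize a nucleus-channel image
#'
#' Pixels strictly above the threshold become foreground. With the
#' Otsu method the threshold maximizes the between-class variance of
#' the 256-bin intensity histogram; a constant image has no histogram
#' structure to threshold and raises an error.
#'
#' @param image single-channel matrix with values in \[0,1\].
#' @param cfg a [detectionConfig()].
#' @return logical matrix (the foreground mask) with the threshold used
#'   attached as attribute `"threshold"`.
#' @examples
#' img <- matrix(0, 8, 8); img[3:5, 3:5] <- 1
#' sum(binarizeNucleus(img, detectionConfig("fixed", 0.5)))
#' @export
binarizeNucleus <- function(image, cfg = detectionConfig()) {
  stopifnot(is.matrix(image))
  if (min(image) < 0 || max(image) > 1)
    stop("binarizeNucleus: image values must lie in [0,1]")
  thr <- if (cfg$thresholdMethod == "fixed") {
    cfg$fixedThreshold
  } else {
    if (diff(range(image)) == 0)
      stop("binarizeNucleus: constant image has a degenerate histogram ",
           "(all-background tile?)")
    EBImage::otsu(image, range = c(0, 1), levels = 256)
  }
  structure(image > thr, threshold = thr)
}

#' Label connected foreground components
#'
#' Two-pass union-find labeling. Components are maximal sets of
#' foreground pixels connected under the chosen neighbourhood; labels
#' are assigned in raster-scan order (row-major order of each
#' component's first pixel), so identical input always yields identical
#' labels.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `nLabels`.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
#' labelComponents(m, 8)$nLabels  # diagonal pixels touch under 8-conn
#' labelComponents(m, 4)$nLabels
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- mask != 0
  H <- nrow(m)
  W <- ncol(m)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nextLab <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!m[i, j]) next
      # neighbours already visited in raster (row-major) order
      nb <- integer(0)
      if (j > 1L && m[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
      if (i > 1L && m[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
      if (connectivity == 8L) {
        if (i > 1L && j > 1L && m[i - 1L, j - 1L])
          nb <- c(nb, lab[i - 1L, j - 1L])
        if (i > 1L && j < W && m[i - 1L, j + 1L])
          nb <- c(nb, lab[i - 1L, j + 1L])
      }
      if (length(nb) == 0L) {
        nextLab <- nextLab + 1L
        parent[nextLab] <- nextLab
        lab[i, j] <- nextLab
      } else {
        roots <- vapply(unique(nb), findRoot, integer(1))
        r <- min(roots)
        lab[i, j] <- r
        for (x in roots) parent[x] <- r
      }
    }
  }
  if (nextLab == 0L) return(list(labels = lab, nLabels = 0L))
  roots <- vapply(seq_len(nextLab), findRoot, integer(1))
  # relabel components 1..n in order of first raster-scan appearance
  fg <- which(t(lab) != 0)                 # row-major order
  labsRM <- t(lab)[fg]
  rootsRM <- roots[labsRM]
  remap <- integer(nextLab)
  nFinal <- 0L
  for (r in rootsRM) {
    if (remap[r] == 0L) {
      nFinal <- nFinal + 1L
      remap[r] <- nFinal
    }
  }
  lab[lab != 0] <- remap[roots[lab[lab != 0]]]
  list(labels = lab, nLabels = nFinal)
}

#' Extract per-nucleus records from a label map
#'
#' One record per surviving component: area, unweighted centroid of
#' member pixel coordinates, and the tight axis-aligned bounding box in
#' half-open `(min_row, min_col, height, width)` convention. All
#' coordinates are 0-based; `centroid_um_*` are the centroid
#' coordinates scaled by the pixel size. Components smaller than
#' `cfg$minAreaPx` are removed (a 50-px floor eliminates thresholding
#' noise); surviving records keep their label-map labels.
#'
#' @param labelMap result of [labelComponents()] (or an integer matrix).
#' @param pixelSizeUm physical pixel size.
#' @param cfg a [detectionConfig()].
#' @return data.frame with columns label, area_px, centroid_row,
#'   centroid_col, bbox_min_row, bbox_min_col, bbox_height, bbox_width,
#'   centroid_um_y, centroid_um_x.
#' @examples
#' m <- matrix(0, 20, 30); m[11:15, 21:25] <- 1
#' extractRecords(labelComponents(m), 0.5, detectionConfig(minAreaPx = 1))
#' @export
extractRecords <- function(labelMap, pixelSizeUm = 1,
                           cfg = detectionConfig()) {
  lab <- if (is.list(labelMap)) labelMap$labels else labelMap
  fg <- which(lab != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(.emptyRecords())
  l <- lab[lab != 0]
  area <- as.vector(table(factor(l, levels = sort(unique(l)))))
  ids <- sort(unique(l))
  rows0 <- fg[, 1] - 1
  cols0 <- fg[, 2] - 1
  f <- factor(l, levels = ids)
  cr <- tapply(rows0, f, mean)
  cc <- tapply(cols0, f, mean)
  rmin <- tapply(rows0, f, min)
  rmax <- tapply(rows0, f, max)
  cmin <- tapply(cols0, f, min)
  cmax <- tapply(cols0, f, max)
  rec <- data.frame(label = ids, area_px = area,
                    centroid_row = as.numeric(cr),
                    centroid_col = as.numeric(cc),
                    bbox_min_row = as.numeric(rmin),
                    bbox_min_col = as.numeric(cmin),
                    bbox_height = as.numeric(rmax - rmin + 1),
                    bbox_width = as.numeric(cmax - cmin + 1))
  rec <- rec[rec$area_px >= cfg$minAreaPx, , drop = FALSE]
  rec$centroid_um_y <- rec$centroid_row * pixelSizeUm
  rec$centroid_um_x <- rec$centroid_col * pixelSizeUm
  rownames(rec) <- NULL
  rec
}

.emptyRecords <- function() {
  data.frame(label = integer(0), area_px = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             bbox_min_row = numeric(0), bbox_min_col = numeric(0),
             bbox_height = numeric(0), bbox_width = numeric(0),
             centroid_um_y = numeric(0), centroid_um_x = numeric(0))
}

#' Count detected nuclei
#'
#' @param records a record data.frame from [extractRecords()].
#' @return integer count.
#' @export
countNuclei <- function(records) nrow(records)

#' Detect nuclei in a nucleus-channel image
#'
#' Convenience wrapper: binarize, label, extract records.
#'
#' @param image single-channel matrix in \[0,1\], or an
#'   [ImagePair-class] (its nucleus channel is used).
#' @param pixelSizeUm physical pixel size (taken from the pair when one
#'   is given).
#' @param cfg a [detectionConfig()].
#' @return record data.frame (see [extractRecords()]).
#' @examples
#' sc <- sampleScene(1, 64, 0.8203, seed = 5)
#' rp <- renderPair(sc, renderConfig(), seed = 5)
#' detectNuclei(rp$pair)
#' @export
detectNuclei <- function(image, pixelSizeUm = 1, cfg = detectionConfig()) {
  if (is(image, "ImagePair")) {
    pixelSizeUm <- image@pixelSizeUm
    image <- image@nucleus
  }
  mask <- binarizeNucleus(image, cfg)
  lm <- labelComponents(mask, cfg$connectivity)
  extractRecords(lm, pixelSizeUm, cfg)
}
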