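#' @include AllClasses.R
NULL

#' Bounding-box overlap ratio (intersection over union)
#'
#' Boxes use the half-open `(min_row, min_col, height, width)`
#' convention, so areas and intersections are plain products and the
#' ratio is `|A intersect B| / |A union B|`; disjoint boxes score 0.
#'
#' @param boxA,boxB numeric length-4 vectors
#'   `(min_row, min_col, height, width)`.
#' @return overlap ratio in \[0,1\].
#' @examples
#' overlapRatio(c(0, 0, 2, 2), c(1, 1, 2, 2))  # 1/7
#' @export
overlapRatio <- function(boxA, boxB) {
  stopifnot(length(boxA) == 4L, length(boxB) == 4L)
  if (boxA[3] <= 0 || boxA[4] <= 0 || boxB[3] <= 0 || boxB[4] <= 0)
    stop("overlapRatio: zero-area box")
  ih <- min(boxA[1] + boxA[3], boxB[1] + boxB[3]) - max(boxA[1], boxB[1])
  iw <- min(boxA[2] + boxA[4], boxB[2] + boxB[4]) - max(boxA[2], boxB[2])
  if (ih <= 0 || iw <= 0) return(0)
  inter <- ih * iw
  inter / (boxA[3] * boxA[4] + boxB[3] * boxB[4] - inter)
}

#' Euclidean centroid distance
#'
#' @param c1,c2 numeric length-2 `(row, col)` coordinates.
#' @return distance in pixels.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
#' @export
euclideanDistance <- function(c1, c2) {
  stopifnot(all(is.finite(c1)), all(is.finite(c2)))
  sqrt(sum((c1 - c2)^2))
}

#' Nuclei count error percentage
#'
#' @param nGT number of ground-truth nuclei (>= 1).
#' @param nGen number of generated nuclei.
#' @return `|nGT - nGen| / nGT * 100`.
#' @examples
#' countErrorPct(10, 8)  # 20
#' @export
countErrorPct <- function(nGT, nGen) {
  if (nGT < 1) stop("countErrorPct: nGT must be >= 1")
  abs(nGT - nGen) / nGT * 100
}

# all candidate pairs with OR > 0, with centroid distances
.candidatePairs <- function(gt, gen) {
  if (nrow(gt) == 0L || nrow(gen) == 0L)
    return(data.frame(gi = integer(0), gj = integer(0),
                      or = numeric(0), dist = numeric(0)))
  cand <- expand.grid(gi = seq_len(nrow(gt)), gj = seq_len(nrow(gen)))
  cand$or <- mapply(function(i, j) {
    overlapRatio(as.numeric(gt[i, c("bbox_min_row", "bbox_min_col",
                                    "bbox_height", "bbox_width")]),
                 as.numeric(gen[j, c("bbox_min_row", "bbox_min_col",
                                     "bbox_height", "bbox_width")]))
  }, cand$gi, cand$gj)
  cand$dist <- mapply(function(i, j) {
    euclideanDistance(c(gt$centroid_row[i], gt$centroid_col[i]),
                      c(gen$centroid_row[j], gen$centroid_col[j]))
  }, cand$gi, cand$gj)
  cand[cand$or > 0, , drop = FALSE]
}

.greedyAssign <- function(cand, nGT, nGen) {
  ord <- order(-cand$or, cand$dist, cand$gi, cand$gj)
  cand <- cand[ord, , drop = FALSE]
  usedGT <- logical(nGT)
  usedGen <- logical(nGen)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$gi[k]
    j <- cand$gj[k]
    if (!usedGT[i] && !usedGen[j]) {
      usedGT[i] <- TRUE
      usedGen[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

# exhaustive maximum-total-OR one-to-one assignment (small n only)
.exhaustiveAssign <- function(cand, nGT, nGen) {
  if (nrow(cand) == 0L) return(cand)
  if (max(nGT, nGen) > 8L)
    stop("exhaustive matching is limited to 8 records per side")
  byGT <- split(seq_len(nrow(cand)), cand$gi)
  best <- list(score = -1, rows = integer(0))
  rec <- function(gtIds, usedGen, rows, score) {
    if (length(gtIds) == 0L) {
      if (score > best$score + 1e-12) best <<- list(score = score, rows = rows)
      return(invisible())
    }
    i <- gtIds[1L]
    rest <- gtIds[-1L]
    rec(rest, usedGen, rows, score)     # leave gt i unmatched
    for (k in byGT[[as.character(i)]]) {
      j <- cand$gj[k]
      if (!usedGen[j])
        rec(rest, `[<-`(usedGen, j, TRUE), c(rows, k), score + cand$or[k])
    }
  }
  rec(as.integer(names(byGT)), logical(nGen), integer(0), 0)
  cand[sort(best$rows), , drop = FALSE]
}

#' Pair generated nuclei with ground-truth nuclei by maximizing overlap
#'
#' Candidate (real, generated) pairs are all pairs whose bounding boxes
#' overlap (OR > 0). The default `"greedy"` method walks the candidates
#' in strictly descending OR — ties broken by smaller centroid distance,
#' then by (gt label, gen label) — and keeps each record in at most one
#' pair. `"exhaustive"` finds the assignment maximizing total OR by
#' brute force (small inputs only; used to validate the greedy result).
#'
#' @param gtRecords,genRecords record data.frames from
#'   [extractRecords()] for the same image geometry.
#' @param pixelSizeUm pixel size for distance conversion.
#' @param method `"greedy"` or `"exhaustive"`.
#' @return a [MatchingReport-class].
#' @examples
#' img <- matrix(0, 64, 64); img[10:20, 10:20] <- 1
#' rec <- detectNuclei(img, 1, detectionConfig("fixed", 0.5, minAreaPx = 1))
#' matchNuclei(rec, rec)   # self-match: OR 1, distance 0
#' @export
matchNuclei <- function(gtRecords, genRecords, pixelSizeUm = 1,
                        method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  nGT <- nrow(gtRecords)
  nGen <- nrow(genRecords)
  cand <- .candidatePairs(gtRecords, genRecords)
  sel <- if (method == "greedy") .greedyAssign(cand, nGT, nGen)
         else .exhaustiveAssign(cand, nGT, nGen)
  pairs <- data.frame(gt_label = gtRecords$label[sel$gi],
                      gen_label = genRecords$label[sel$gj],
                      overlap_ratio = sel$or,
                      distance_px = sel$dist,
                      distance_um = sel$dist * pixelSizeUm)
  rownames(pairs) <- NULL
  new("MatchingReport",
      nGT = as.integer(nGT), nGen = as.integer(nGen), pairs = pairs,
      unmatchedGT = gtRecords[!seq_len(nGT) %in% sel$gi, , drop = FALSE],
      unmatchedGen = genRecords[!seq_len(nGen) %in% sel$gj, , drop = FALSE],
      countErrorPct = if (nGT >= 1) countErrorPct(nGT, nGen) else NA_real_,
      pixelSizeUm = pixelSizeUm)
}

#' Combine matching reports from several images
#'
#' Concatenates pair tables and recomputes the aggregate count error.
#'
#' @param reports list of [MatchingReport-class] objects.
#' @return a [MatchingReport-class] covering all images.
#' @export
combineMatchingReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  nGT <- sum(vapply(reports, function(r) r@nGT, integer(1)))
  nGen <- sum(vapply(reports, function(r) r@nGen, integer(1)))
  pairs <- do.call(rbind, lapply(reports, function(r) r@pairs))
  ugt <- do.call(rbind, lapply(reports, function(r) r@unmatchedGT))
  ugen <- do.call(rbind, lapply(reports, function(r) r@unmatchedGen))
  rownames(pairs) <- rownames(ugt) <- rownames(ugen) <- NULL
  new("MatchingReport", nGT = nGT, nGen = nGen, pairs = pairs,
      unmatchedGT = ugt, unmatchedGen = ugen,
      countErrorPct = if (nGT >= 1) countErrorPct(nGT, nGen) else NA_real_,
      pixelSizeUm = reports[[1L]]@pixelSizeUm)
}

#' Fraction of generated nuclei matched within a distance threshold
#'
#' A generated nucleus counts as matched when its centroid lies
#' strictly closer than `thresholdUm` to its paired real nucleus. The
#' denominator convention matters: `"all-generated"` (default) divides
#' by every generated nucleus, counting unpaired ones as misses;
#' `"paired"` divides by the paired nuclei only.
#'
#' @param report a [MatchingReport-class].
#' @param thresholdUm distance threshold in micrometers (> 0); the mean
#'   nuclear radius, 4 um, is the canonical choice.
#' @param denominator `"all-generated"` or `"paired"`.
#' @return list with `k` (matches under threshold), `n` (denominator)
#'   and `fraction`.
#' @examples
#' img <- matrix(0, 64, 64); img[10:20, 10:20] <- 1
#' rec <- detectNuclei(img, 1, detectionConfig("fixed", 0.5, minAreaPx = 1))
#' matchedFraction(matchNuclei(rec, rec), 4)
#' @export
matchedFraction <- function(report, thresholdUm = 4,
                            denominator = c("all-generated", "paired")) {
  denominator <- match.arg(denominator)
  if (thresholdUm <= 0) stop("matchedFraction: thresholdUm must be > 0")
  k <- sum(report@pairs$distance_um < thresholdUm)
  n <- if (denominator == "all-generated") report@nGen
       else nrow(report@pairs)
  if (n == 0L) stop("matchedFraction: no generated nuclei in denominator")
  list(k = as.integer(k), n = as.integer(n), fraction = k / n)
}
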