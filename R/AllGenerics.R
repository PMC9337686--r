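#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' `actin()` and `nucleus()` return the two channels of an
#' [ImagePair-class]; `pixelSizeUm()` the physical pixel size of a pair
#' or scene; `cells()` the per-cell ground truth of a
#' [SceneSpec-class]; `nCells()` its cell count; `tileSizeUm()` the
#' physical side length of the tile; `modelParameters()` the weight
#' list of a [TrainState-class] (with a replacement form used to probe
#' the network, e.g. zeroing projections); `lossHistory()` its
#' per-iteration loss table; `matchedPairs()` the pair table of a
#' [MatchingReport-class]; `nullProbability()` the per-trial success
#' probability of a [PlacementNull-class].
#'
#' @param x an object of the documented class.
#' @param value replacement value (parameter list).
#' @return the slot content described above.
#' @name accessors
#' @examples
#' sc <- sampleScene(nCells = 2, imageSizePx = 64, pixelSizeUm = 0.8203,
#'                   seed = 1)
#' nCells(sc)
#' tileSizeUm(sc)
NULL

#' @rdname accessors
#' @export
setGeneric("actin", function(x) standardGeneric("actin"))
#' @rdname accessors
#' @export
setGeneric("nucleus", function(x) standardGeneric("nucleus"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("tileSizeUm", function(x) standardGeneric("tileSizeUm"))
#' @rdname accessors
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))
#' @rdname accessors
#' @export
setGeneric("modelParameters<-",
           function(x, value) standardGeneric("modelParameters<-"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setGeneric("nullProbability", function(x) standardGeneric("nullProbability"))

#' @rdname accessors
setMethod("actin", "ImagePair", function(x) x@actin)
#' @rdname accessors
setMethod("nucleus", "ImagePair", function(x) x@nucleus)
#' @rdname accessors
setMethod("pixelSizeUm", "ImagePair", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSizeUm", "SceneSpec", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("cells", "SceneSpec", function(x) x@cells)
#' @rdname accessors
setMethod("nCells", "SceneSpec", function(x) length(x@cells))
#' @rdname accessors
setMethod("tileSizeUm", "SceneSpec",
          function(x) as.numeric(x@imageSizePx) * x@pixelSizeUm)
#' @rdname accessors
setMethod("modelParameters", "TrainState", function(x) x@params)
#' @rdname accessors
setMethod("modelParameters<-", "TrainState", function(x, value) {
  x@params <- value
  x
})
#' @rdname accessors
setMethod("lossHistory", "TrainState", function(x) x@lossHistory)
#' @rdname accessors
setMethod("matchedPairs", "MatchingReport", function(x) x@pairs)
#' @rdname accessors
setMethod("nullProbability", "PlacementNull", function(x) x@p)

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d cell(s), %d x %d px (%.1f x %.1f um), seed %d\n",
              length(object@cells), object@imageSizePx, object@imageSizePx,
              tileSizeUm(object), tileSizeUm(object), object@seed))
})

setMethod("show", "ImagePair", function(object) {
  d <- dim(object@actin)
  cat(sprintf("ImagePair '%s': %d x %d px, %.4f um/px\n",
              object@id, d[1], d[2], object@pixelSizeUm))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig (%s): %d px, %d encoder + %d transformer blocks, C = %d\n",
    object@preset, object@imageSizePx, object@encoderBlocks,
    object@transformerBlocks, object@tokenChannels))
  cat(sprintf("  alpha = %g, batch = %d, iterations = %d, seed = %d\n",
              object@alpha, object@batchSize, object@maxIterations,
              object@seed))
})

setMethod("show", "TrainState", function(object) {
  cat(sprintf("TrainState: %d iteration(s) on %s preset\n",
              object@iteration, object@config@preset))
  if (object@iteration > 0L) {
    last <- object@lossHistory[object@iteration, ]
    cat(sprintf("  last losses: rec = %.4g (fg %.4g / bg %.4g), G = %.4g, D = %.4g\n",
                last$rec_total, last$rec_fg, last$rec_bg, last$gan_g,
                last$gan_d))
  }
})

setMethod("show", "MatchingReport", function(object) {
  cat(sprintf(
    "MatchingReport: %d real vs %d generated nuclei, %d pair(s), count error %.1f%%\n",
    object@nGT, object@nGen, nrow(object@pairs), object@countErrorPct))
})

setMethod("show", "PlacementNull", function(object) {
  cat(sprintf("PlacementNull (%s-level): r = %g um, p = %.4g (1 in %.0f)\n",
              object@kind, object@rUm, object@p, 1 / object@p))
})
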