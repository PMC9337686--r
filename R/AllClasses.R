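#' @include utils.R
NULL

#' SceneSpec: ground truth for one synthetic tile
#'
#' Holds the full generative description of a synthetic image tile:
#' the cell outlines, the fiber segments rendered into the actin
#' channel, and the true nucleus geometry. Each element of `cells` is a
#' list with entries `outline` (closed polygon, n x 2 matrix of 0-based
#' (row, col) pixel coordinates), `fibers` (list of lists with
#' `endpoints` 2 x 2 matrix, `intensity` in \[0,1\], `width_px`),
#' `nucleus_center_raw` (the fiber-derived centroid before any
#' clamping), `nucleus_center` (the rendered centroid), `nucleus_radii`
#' (major, minor in px), and `nucleus_orientation` (radians).
#'
#' All coordinates are 0-based (row, col) at pixel centers; physical
#' distances are pixel distances times `pixelSizeUm`.
#'
#' @slot cells list of per-cell ground-truth descriptions (see above).
#' @slot imageSizePx integer side length of the square tile in pixels.
#' @slot pixelSizeUm physical pixel size in micrometers per pixel.
#' @slot seed integer seed the scene was sampled under.
#' @seealso [sampleScene()], [renderPair()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(cells = "list", imageSizePx = "integer",
                 pixelSizeUm = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@imageSizePx) != 1L || object@imageSizePx < 8L)
      msg <- c(msg, "imageSizePx must be a single integer >= 8")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    for (cell in object@cells) {
      need <- c("outline", "fibers", "nucleus_center", "nucleus_center_raw",
                "nucleus_radii", "nucleus_orientation")
      if (!all(need %in% names(cell)))
        msg <- c(msg, "each cell must carry outline, fibers and nucleus geometry")
    }
    if (is.null(msg)) TRUE else msg
  })

#' ImagePair: one registered actin/nucleus image pair
#'
#' The unit flowing through the pipeline: two single-channel images of
#' identical shape with intensities in \[0,1\] plus the physical pixel
#' size. The actin channel is the translator input; the nucleus channel
#' is its target (real data) or output (generated data).
#'
#' @slot actin numeric matrix, actin-filament channel, values in \[0,1\].
#' @slot nucleus numeric matrix, nucleus channel, values in \[0,1\].
#' @slot pixelSizeUm physical pixel size (um/px).
#' @slot id character identifier used in file names and reports.
#' @seealso [renderPair()], [predictNucleus()]
#' @exportClass ImagePair
setClass("ImagePair",
  representation(actin = "matrix", nucleus = "matrix",
                 pixelSizeUm = "numeric", id = "character"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@actin), dim(object@nucleus)))
      msg <- c(msg, "actin and nucleus channels must have identical shape")
    rng <- range(object@actin, object@nucleus)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "channel intensities must lie in [0,1]")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' RenderConfig: rasterization and noise settings
#'
#' @slot psfSigmaPx Gaussian point-spread sigma in pixels (0 = none).
#' @slot backgroundLevel constant background intensity in \[0,1); must
#'   stay below the rendered nucleus peak so thresholding is possible.
#' @slot noiseModel one of `"none"`, `"gaussian"`, `"poisson"`.
#' @slot noiseParam sd of the additive Gaussian noise, or the photon
#'   scale (expected counts at intensity 1) of the Poisson shot noise.
#' @slot nucleusIntensity peak intensity of rendered nuclei.
#' @slot bitDepth 8 or 16; only affects file output quantization.
#' @seealso [renderConfig()], [renderPair()]
#' @exportClass RenderConfig
setClass("RenderConfig",
  representation(psfSigmaPx = "numeric", backgroundLevel = "numeric",
                 noiseModel = "character", noiseParam = "numeric",
                 nucleusIntensity = "numeric", bitDepth = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@noiseModel %in% c("none", "gaussian", "poisson"))
      msg <- c(msg, "noiseModel must be one of none/gaussian/poisson")
    if (object@backgroundLevel < 0 || object@backgroundLevel >= 1)
      msg <- c(msg, "backgroundLevel must lie in [0,1)")
    if (object@backgroundLevel >= object@nucleusIntensity)
      msg <- c(msg, "backgroundLevel must be below nucleusIntensity")
    if (!object@bitDepth %in% c(8L, 16L))
      msg <- c(msg, "bitDepth must be 8 or 16")
    if (object@psfSigmaPx < 0) msg <- c(msg, "psfSigmaPx must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' ModelConfig: translator architecture and training hyperparameters
#'
#' @slot imageSizePx input/output image side; must be divisible by
#'   `2^encoderBlocks`.
#' @slot encoderBlocks number of residual downsampling blocks.
#' @slot transformerBlocks number of transformer encoder layers.
#' @slot attentionHeads heads of the multi-head self-attention.
#' @slot tokenChannels channel width C of the token sequence.
#' @slot baseChannels channel width of the first encoder block.
#' @slot leakySlope leak factor of the leaky rectifier.
#' @slot alpha foreground weight of the reconstruction loss (>= 1).
#' @slot ganWeight weight of the adversarial term in the generator loss.
#' @slot lrG,lrD Adam learning rates for generator and discriminator.
#' @slot adamBeta1 Adam first-moment decay.
#' @slot batchSize images per iteration.
#' @slot maxIterations training iterations.
#' @slot seed training seed (weight init, batch order, all noise).
#' @slot preset `"desk"` (64 px, 2+2 blocks) or `"paper"` (256 px, 4
#'   encoder and 12 transformer blocks).
#' @seealso [modelConfig()], [trainTranslator()]
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(imageSizePx = "integer", encoderBlocks = "integer",
                 transformerBlocks = "integer", attentionHeads = "integer",
                 tokenChannels = "integer", baseChannels = "integer",
                 leakySlope = "numeric", alpha = "numeric",
                 ganWeight = "numeric", lrG = "numeric", lrD = "numeric",
                 adamBeta1 = "numeric", batchSize = "integer",
                 maxIterations = "integer", seed = "integer",
                 preset = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@imageSizePx %% (2L^object@encoderBlocks) != 0L)
      msg <- c(msg, "imageSizePx must be divisible by 2^encoderBlocks")
    if (object@alpha < 1) msg <- c(msg, "alpha must be >= 1")
    if (object@tokenChannels %% object@attentionHeads != 0L)
      msg <- c(msg, "tokenChannels must be divisible by attentionHeads")
    if (is.null(msg)) TRUE else msg
  })

#' TrainState: parameters and history of a (partially) trained translator
#'
#' @slot params named list of generator and discriminator weight arrays
#'   (opaque; access through the model operations).
#' @slot config the [ModelConfig-class] the state was built under.
#' @slot lossHistory data.frame with one row per iteration: `iteration`,
#'   `rec_fg`, `rec_bg`, `rec_total`, `gan_g`, `gan_d`.
#' @slot iteration number of completed training iterations.
#' @seealso [initTranslator()], [trainTranslator()], [predictNucleus()]
#' @exportClass TrainState
setClass("TrainState",
  representation(params = "list", config = "ModelConfig",
                 lossHistory = "data.frame", iteration = "integer"),
  validity = function(object) {
    if (nrow(object@lossHistory) != object@iteration)
      "lossHistory must have one row per completed iteration" else TRUE
  })

#' MatchingReport: paired real/generated nuclei for one image or a set
#'
#' @slot nGT number of ground-truth (real) nuclei considered.
#' @slot nGen number of generated nuclei considered.
#' @slot pairs data.frame of matched pairs: gt_label, gen_label,
#'   overlap_ratio, distance_px, distance_um (one row per pair; each
#'   record appears in at most one pair).
#' @slot unmatchedGT,unmatchedGen data.frames of leftover records.
#' @slot countErrorPct percentage count error |nGT - nGen| / nGT * 100.
#' @slot pixelSizeUm pixel size used to convert distances to um.
#' @seealso [matchNuclei()], [matchedFraction()]
#' @exportClass MatchingReport
setClass("MatchingReport",
  representation(nGT = "integer", nGen = "integer", pairs = "data.frame",
                 unmatchedGT = "data.frame", unmatchedGen = "data.frame",
                 countErrorPct = "numeric", pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@pairs) + nrow(object@unmatchedGen) != object@nGen)
      msg <- c(msg, "pairs + unmatchedGen must partition the generated records")
    if (nrow(object@pairs) + nrow(object@unmatchedGT) != object@nGT)
      msg <- c(msg, "pairs + unmatchedGT must partition the ground-truth records")
    if (is.null(msg)) TRUE else msg
  })

#' PlacementNull: geometric random-placement null model
#'
#' The probability `p` that a uniformly placed nucleus centroid lands
#' within the match radius of the true position — over the whole image
#' (`kind = "image"`, p = pi r^2 / L^2) or within the erosion-restricted
#' cell mask (`kind = "cell"`).
#'
#' @slot kind `"image"` or `"cell"`.
#' @slot rUm match radius in micrometers (mean nuclear radius, 4 um).
#' @slot LUm image side in micrometers (image kind; `NA` for cell kind).
#' @slot p per-trial success probability in (0,1).
#' @seealso [placementNullImage()], [placementNullCell()], [placementReport()]
#' @exportClass PlacementNull
setClass("PlacementNull",
  representation(kind = "character", rUm = "numeric", LUm = "numeric",
                 p = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("image", "cell"))
      msg <- c(msg, "kind must be 'image' or 'cell'")
    if (object@p <= 0 || object@p >= 1)
      msg <- c(msg, "null probability must lie strictly in (0,1)")
    if (is.null(msg)) TRUE else msg
  })
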