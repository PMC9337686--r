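#' @include AllClasses.R
NULL

#' Write image pairs as single-channel TIFF files
#'
#' Each pair becomes `<id>_actin.tif` and `<id>_nucleus.tif` (8- or
#' 16-bit grayscale), alongside optional ground-truth sidecars written
#' by [runPipeline()].
#'
#' @param pairs list of [ImagePair-class] objects.
#' @param dir output directory (created if missing).
#' @param bitDepth 8 or 16.
#' @return invisibly, the vector of written file paths.
#' @export
writeImagePairs <- function(pairs, dir, bitDepth = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in pairs) {
    fa <- file.path(dir, paste0(p@id, "_actin.tif"))
    fn <- file.path(dir, paste0(p@id, "_nucleus.tif"))
    tiff::writeTIFF(p@actin, fa, bits.per.sample = as.integer(bitDepth))
    tiff::writeTIFF(p@nucleus, fn, bits.per.sample = as.integer(bitDepth))
    paths <- c(paths, fa, fn)
  }
  invisible(paths)
}

#' Read one image pair written by [writeImagePairs()]
#'
#' @param dir directory holding the TIFF files.
#' @param id pair identifier.
#' @param pixelSizeUm physical pixel size to attach.
#' @return an [ImagePair-class].
#' @export
readImagePair <- function(dir, id, pixelSizeUm) {
  fa <- file.path(dir, paste0(id, "_actin.tif"))
  fn <- file.path(dir, paste0(id, "_nucleus.tif"))
  if (!file.exists(fa) || !file.exists(fn))
    stop("readImagePair: missing TIFF files for id '", id, "' in ", dir)
  new("ImagePair", actin = .clamp01(tiff::readTIFF(fa)),
      nucleus = .clamp01(tiff::readTIFF(fn)),
      pixelSizeUm = pixelSizeUm, id = id)
}

# JSON-serializable description of a SceneSpec (documented schema:
# image_size_px, pixel_size_um, seed, cells[] with outline, fibers[],
# nucleus_center, nucleus_center_raw, nucleus_radii_px,
# nucleus_orientation)
.sceneToList <- function(scene) {
  list(image_size_px = scene@imageSizePx,
       pixel_size_um = scene@pixelSizeUm,
       seed = scene@seed,
       cells = lapply(scene@cells, function(cell) {
         list(outline = unname(cell$outline),
              nucleus_center = unname(cell$nucleus_center),
              nucleus_center_raw = unname(cell$nucleus_center_raw),
              nucleus_radii_px = unname(cell$nucleus_radii),
              nucleus_orientation = cell$nucleus_orientation,
              fibers = lapply(cell$fibers, function(f)
                list(endpoints = unname(f$endpoints),
                     intensity = f$intensity,
                     width_px = f$width_px)))
       }))
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# records.csv with an image id column prepended
.writeRecords <- function(recordsById, path) {
  rows <- lapply(names(recordsById), function(id) {
    r <- recordsById[[id]]
    if (nrow(r) == 0L) return(NULL)
    cbind(data.frame(id = id, stringsAsFactors = FALSE), r)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- cbind(data.frame(id = character(0)),
                                 .emptyRecords())
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
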