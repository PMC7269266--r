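#' Calibrated grayscale image container
#'
#' A `pellet_image` is a plain numeric matrix (rows = y, columns = x,
#' row-major 0-based pixel convention in all reported coordinates) carrying
#' the physical pixel size in micrometres as an attribute. All measurement
#' functions in the package consume this container so that calibration can
#' never be separated from the raster.
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_size_um Positive scalar, edge length of one pixel in um.
#' @return Object of class `pellet_image`.
#' @export
pellet_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive finite scalar")
  structure(pixels, pixel_size_um = as.numeric(pixel_size_um),
            class = c("pellet_image", "matrix", "array"))
}

#' @export
print.pellet_image <- function(x, ...) {
  cat(sprintf("<pellet_image> %d x %d px @ %.4g um/px, intensity [%.3g, %.3g]\n",
              nrow(x), ncol(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

#' Pixel calibration of an image
#' @param image A `pellet_image`.
#' @return Pixel edge length in um.
#' @export
pixel_size <- function(image) {
  ps <- attr(image, "pixel_size_um")
  if (is.null(ps)) stop("image carries no pixel_size_um attribute")
  ps
}

#' Write / read a calibrated image as TIFF plus sidecar JSON
#'
#' The raster goes to a 16-bit grayscale TIFF; the pixel size (and any extra
#' metadata) goes to `<path>.json` next to it, since baseline TIFF readers do
#' not reliably round-trip resolution tags.
#'
#' @param image A `pellet_image` with intensities in \[0, 1\].
#' @param path Output TIFF path.
#' @param metadata Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_pellet_tiff <- function(image, path, metadata = list()) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  px <- pmin(pmax(unclass(image), 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  side <- c(list(pixel_size_um = pixel_size(image)), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pellet_tiff
#' @param pixel_size_um Calibration override; if `NULL` the sidecar JSON is read.
#' @export
read_pellet_tiff <- function(path, pixel_size_um = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF files")
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (is.null(pixel_size_um)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("no pixel size given and no sidecar JSON found at ", side)
    pixel_size_um <- jsonlite::read_json(side)$pixel_size_um
  }
  pellet_image(px, pixel_size_um)
}

# Evaluate `expr` under a temporarily seeded RNG, restoring prior state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
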