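#' Single-channel fluorescence micrograph
#'
#' A `micrograph` couples a 2D nonnegative intensity matrix with the physical
#' pixel size and a channel label. It is the common currency of every image
#' operation in the package: the synthetic generators emit micrographs, the
#' counting and skeletonization routines consume them, and the TIFF readers
#' and writers round-trip them.
#'
#' @param pixels numeric matrix of nonnegative intensities (rows = y, columns
#'   = x, following R matrix convention).
#' @param pixel_size physical edge length of one pixel in micrometres.
#' @param channel channel label, one of `"nuclei"`, `"dead"`, `"live"`,
#'   `"neurite"`, `"calcium"`.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size,
                       channel = c("nuclei", "dead", "live", "neurite", "calcium")) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) < 1L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (any(pixels < 0)) stop("micrograph intensities must be nonnegative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/px)")
  structure(list(pixels = pixels, pixel_size = pixel_size, channel = channel),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %dx%d px, %.3g um/px, channel '%s', range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Imaged area of a micrograph in cm^2
#'
#' @param img a [micrograph()].
#' @return Physical field area in cm^2 (1 cm^2 = 1e8 um^2).
#' @export
field_area_cm2 <- function(img) {
  stopifnot(inherits(img, "micrograph"))
  prod(dim(img$pixels)) * img$pixel_size^2 / 1e8
}

#' Threshold specification for semi-automatic segmentation
#'
#' Describes how the binarization threshold of an image is resolved, plus the
#' object-area window used to discard debris and clumps. In `"absolute"` mode
#' the threshold is `value` itself. In `"relative"` mode the threshold adapts
#' to each image: it is `value` times a robust background scale,
#' `median(pixels) + k_mad * mad(pixels)`, so a single user-chosen multiplier
#' carries across images with minor illumination differences. The relative
#' threshold scales linearly with overall image intensity, which makes counts
#' invariant to global gain changes.
#'
#' @param mode `"absolute"` or `"relative"`.
#' @param value positive threshold (absolute mode, intensity units) or
#'   multiplier (relative mode).
#' @param k_mad multiplier on the median absolute deviation added to the
#'   median before scaling (relative mode only; default 5).
#' @param min_object_area,max_object_area connected-component area window in
#'   pixels; components smaller than `min_object_area` are discarded, larger
#'   than `max_object_area` are declumped (see [count_objects()]).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("relative", "absolute"), value = 1,
                           k_mad = 5, min_object_area = 5,
                           max_object_area = 45) {
  mode <- match.arg(mode)
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("'value' must be a single positive number")
  if (min_object_area <= 0 || min_object_area > max_object_area)
    stop("need 0 < min_object_area <= max_object_area")
  structure(list(mode = mode, value = value, k_mad = k_mad,
                 min_object_area = min_object_area,
                 max_object_area = max_object_area),
            class = "threshold_spec")
}

#' Resolve an absolute intensity threshold for an image
#'
#' @param image a [micrograph()].
#' @param spec a [threshold_spec()].
#' @return A single absolute intensity threshold.
#' @details In relative mode a degenerate image whose robust background scale
#'   is not positive (e.g. an all-zero frame) raises an error instead of
#'   silently returning a zero threshold.
#' @export
select_threshold <- function(image, spec) {
  stopifnot(inherits(image, "micrograph"), inherits(spec, "threshold_spec"))
  if (spec$mode == "absolute") return(spec$value)
  px <- as.numeric(image$pixels)
  scale <- stats::median(px) + spec$k_mad * stats::mad(px)
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate image: robust background scale is not positive; ",
         "use an absolute threshold")
  spec$value * scale
}

# ---- TIFF input/output -----------------------------------------------------
# Images are stored as 16-bit unsigned TIFF; intensities map linearly from
# [0, 65535] counts. Values are clipped at the 16-bit ceiling on write.

#' Write a micrograph to a 16-bit TIFF file
#'
#' @param img a [micrograph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  px <- pmin(pmax(img$pixels, 0), 65535) / 65535
  tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a micrograph from a TIFF file
#'
#' @param path TIFF file path.
#' @param pixel_size physical pixel size in um/px (TIFFs written by this
#'   package do not embed it; it travels in the experiment design table).
#' @param channel channel label for the returned micrograph.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size, channel = "nuclei") {
  px <- tiff::readTIFF(path)
  if (is.list(px)) px <- px[[1L]]
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  micrograph(round(px * 65535), pixel_size, channel)
}

#' Write a calcium movie to a multi-page 16-bit TIFF
#'
#' @param movie a [calcium_movie()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "calcium_movie"))
  fr <- movie$frames
  pages <- lapply(seq_len(dim(fr)[3L]),
                  function(t) pmin(pmax(fr[, , t], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a calcium movie from a multi-page TIFF
#'
#' @param path TIFF file path.
#' @param frame_rate acquisition rate in Hz.
#' @return A [calcium_movie()].
#' @export
read_movie <- function(path, frame_rate) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * 65535)
  calcium_movie(arr, frame_rate)
}
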