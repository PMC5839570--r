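#' Display frame images
#'
#' A `frame_image` is an H x W x 3 array of 8-bit red/green/blue intensities,
#' the unit of exchange between frame sources (webcam, file, renderer) and the
#' display decoder. Pixel coordinates are 0-based, row-major, with the origin
#' at the top-left corner of the image; all intensities lie in `[0, 255]`.
#'
#' @param pixels numeric or integer array of dimension `c(height, width, 3)`
#'   with values in `[0, 255]` (channel order red, green, blue).
#' @return An object of class `frame_image`.
#' @export
frame_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("frame must have positive height and width", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_image> %d x %d px, mean red %.1f\n",
              d[1], d[2], mean(x[, , 1])))
  invisible(x)
}

frame_height <- function(frame) dim(frame)[1]
frame_width  <- function(frame) dim(frame)[2]

#' Extract the red channel of a frame
#'
#' Seven-segment pH-meter displays of the kind this package targets emit red
#' light, so the whole decoding pipeline operates on the red plane of each
#' recorded frame; green and blue carry no signal.
#'
#' @param frame a [frame_image()].
#' @return An integer matrix (height x width) of red intensities.
#' @export
red_channel <- function(frame) {
  if (!inherits(frame, "frame_image")) frame <- frame_image(frame)
  m <- frame[, , 1L]
  dim(m) <- dim(frame)[1:2]
  m
}

#' Threshold an intensity grid
#'
#' A pixel counts as "on" iff its intensity is strictly greater than the
#' threshold. The strict inequality is a deliberate convention: a threshold of
#' 255 turns every pixel off, a threshold of 0 keeps every non-black pixel on.
#'
#' @param gray numeric matrix of intensities in `[0, 255]`.
#' @param threshold scalar in `[0, 255]`.
#' @return A logical matrix of the same shape.
#' @export
binarize <- function(gray, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 255)
    stop("'threshold' must be a single value in [0, 255]", call. = FALSE)
  gray > threshold
}

#' Write / read a frame as PNG
#'
#' @param frame a [frame_image()].
#' @param path file path.
#' @return `write_frame_png` returns `path` invisibly; `read_frame_png`
#'   returns a [frame_image()].
#' @export
write_frame_png <- function(frame, path) {
  if (!inherits(frame, "frame_image")) frame <- frame_image(frame)
  arr <- unclass(frame) / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L)            # grayscale: replicate into RGB
    arr <- array(arr, dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  frame_image(round(arr * 255))
}
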