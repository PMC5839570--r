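#' Seven-segment digit geometry
#'
#' Describes where the digits of a seven-segment display sit on a frame. The
#' display is assumed to have a fixed format: `n_digits` equally spaced digit
#' boxes with a decimal point permanently placed after the `decimal_index`-th
#' digit (counted from the left), as on a bench pH meter showing e.g.
#' `10.553`. Coordinates are 0-based with the origin at the top-left pixel.
#'
#' @param anchor_row,anchor_col 0-based pixel coordinates of the top-left
#'   corner of the first (leftmost) digit's bounding box.
#' @param digit_width,digit_height size of each digit box in pixels
#'   (`digit_width >= 3`, `digit_height >= 5`).
#' @param digit_pitch horizontal distance in pixels between the anchors of
#'   successive digits (`>= digit_width`).
#' @param n_digits number of digits on the display.
#' @param decimal_index number of digits to the left of the fixed decimal
#'   point; `0 <= decimal_index < n_digits`. The default layout (5 digits,
#'   `decimal_index = 2`) reads values like `10.553`.
#' @return An object of class `segment_geometry`.
#' @export
segment_geometry <- function(anchor_row, anchor_col, digit_width, digit_height,
                             digit_pitch = digit_width + 2L, n_digits = 5L,
                             decimal_index = 2L) {
  stopifnot(anchor_row >= 0, anchor_col >= 0)
  if (digit_width < 3L || digit_height < 5L)
    stop("digit box too small: need width >= 3 and height >= 5", call. = FALSE)
  if (digit_pitch < digit_width)
    stop("'digit_pitch' must be >= 'digit_width'", call. = FALSE)
  if (n_digits < 1L || decimal_index < 0L || decimal_index >= n_digits)
    stop("need 0 <= decimal_index < n_digits", call. = FALSE)
  structure(list(anchor_row = as.integer(anchor_row),
                 anchor_col = as.integer(anchor_col),
                 digit_width = as.integer(digit_width),
                 digit_height = as.integer(digit_height),
                 digit_pitch = as.integer(digit_pitch),
                 n_digits = as.integer(n_digits),
                 decimal_index = as.integer(decimal_index)),
            class = "segment_geometry")
}

#' OCR calibration
#'
#' Bundles the binarization threshold, the digit geometry and the probe
#' sensitivity into one calibration object used by [decode_display()].
#'
#' @param threshold red-channel intensity threshold in `[0, 255]`; pixels
#'   strictly brighter than this count as lit.
#' @param geometry a [segment_geometry()].
#' @param on_fraction fraction in `(0, 1]` of probe pixels that must be lit
#'   for a segment to count as "on". The default 0.5 is a robust midpoint.
#' @return An object of class `ocr_calibration`.
#' @export
ocr_calibration <- function(threshold, geometry, on_fraction = 0.5) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
    stop("'threshold' must lie in [0, 255]", call. = FALSE)
  stopifnot(inherits(geometry, "segment_geometry"))
  if (!(on_fraction > 0 && on_fraction <= 1))
    stop("'on_fraction' must lie in (0, 1]", call. = FALSE)
  structure(list(threshold = threshold, geometry = geometry,
                 on_fraction = on_fraction),
            class = "ocr_calibration")
}

# Canonical seven-segment encoding. Segments are labelled
#   a = top, b = top-right, c = bottom-right, d = bottom,
#   e = bottom-left, f = top-left, g = middle.
SEGMENT_LABELS <- c("a", "b", "c", "d", "e", "f", "g")

DIGIT_SEGMENTS <- list(
  "0" = c("a", "b", "c", "d", "e", "f"),
  "1" = c("b", "c"),
  "2" = c("a", "b", "d", "e", "g"),
  "3" = c("a", "b", "c", "d", "g"),
  "4" = c("b", "c", "f", "g"),
  "5" = c("a", "c", "d", "f", "g"),
  "6" = c("a", "c", "d", "e", "f", "g"),
  "7" = c("a", "b", "c"),
  "8" = c("a", "b", "c", "d", "e", "f", "g"),
  "9" = c("a", "b", "c", "d", "f", "g"),
  "blank" = character(0),
  "minus" = "g"
)

.pattern_key <- function(lit) paste(sort(unique(lit)), collapse = "")

.DECODE_MAP <- local({
  keys <- vapply(DIGIT_SEGMENTS, .pattern_key, character(1))
  stats::setNames(names(DIGIT_SEGMENTS), keys)
})

#' Decode a single segment pattern
#'
#' Pure lookup of a lit-segment set in the canonical seven-segment digit map.
#' Exactly 12 of the 128 possible patterns decode to something: the digits
#' 0-9, the empty pattern (`"blank"`) and the lone middle bar (`"minus"`).
#' Every other pattern yields `"invalid"` — a value, not an error, since
#' mid-transition frames routinely produce such patterns.
#'
#' @param lit character vector, a subset of `c("a","b","c","d","e","f","g")`.
#' @return One of `"0"`..`"9"`, `"blank"`, `"minus"`, `"invalid"`.
#' @export
decode_digit <- function(lit) {
  if (length(lit) && !all(lit %in% SEGMENT_LABELS))
    stop("unknown segment label(s): ",
         paste(setdiff(lit, SEGMENT_LABELS), collapse = ", "), call. = FALSE)
  idx <- match(.pattern_key(lit), names(.DECODE_MAP))
  if (is.na(idx)) "invalid" else unname(.DECODE_MAP[idx])
}

# Probe rectangles for the 7 segments of one digit box, in 0-based local
# coordinates (row0, row1, col0, col1; inclusive). Thin rectangles of
# thickness max(1, floor(h/10)) at the standard relative positions;
# horizontal bars are inset by the thickness so corners are unambiguous.
segment_rects <- function(digit_width, digit_height) {
  h <- digit_height; w <- digit_width
  t <- max(1L, min(h %/% 10L, (w - 1L) %/% 2L, (h - 3L) %/% 2L))
  mid <- (h - t) %/% 2L
  list(
    a = c(0L, t - 1L, t, w - 1L - t),
    g = c(mid, mid + t - 1L, t, w - 1L - t),
    d = c(h - t, h - 1L, t, w - 1L - t),
    f = c(t, mid - 1L, 0L, t - 1L),
    b = c(t, mid - 1L, w - t, w - 1L),
    e = c(mid + t, h - 1L - t, 0L, t - 1L),
    c = c(mid + t, h - 1L - t, w - t, w - 1L)
  )
}

.digit_anchor <- function(geometry, digit_index) {
  c(row = geometry$anchor_row,
    col = geometry$anchor_col + (digit_index - 1L) * geometry$digit_pitch)
}

.check_geometry_fits <- function(geometry, height, width) {
  last <- .digit_anchor(geometry, geometry$n_digits)
  if (geometry$anchor_row + geometry$digit_height > height ||
      last["col"] + geometry$digit_width > width)
    stop("digit boxes extend beyond the frame", call. = FALSE)
  invisible(TRUE)
}

#' Sample the lit-segment pattern of one digit
#'
#' For each of the seven canonical probe rectangles inside the digit box, the
#' segment counts as lit iff the fraction of on-pixels in the rectangle is at
#' least `on_fraction`.
#'
#' @param binary logical matrix from [binarize()].
#' @param geometry a [segment_geometry()].
#' @param digit_index which digit to sample, 1-based from the left.
#' @param on_fraction see [ocr_calibration()].
#' @return Character vector of lit segment labels (possibly empty).
#' @export
sample_pattern <- function(binary, geometry, digit_index, on_fraction = 0.5) {
  stopifnot(digit_index >= 1L, digit_index <= geometry$n_digits)
  .check_geometry_fits(geometry, nrow(binary), ncol(binary))
  anchor <- .digit_anchor(geometry, digit_index)
  rects <- segment_rects(geometry$digit_width, geometry$digit_height)
  lit <- vapply(rects, function(r) {
    rows <- (anchor[["row"]] + r[1]):(anchor[["row"]] + r[2]) + 1L
    cols <- (anchor[["col"]] + r[3]):(anchor[["col"]] + r[4]) + 1L
    mean(binary[rows, cols]) >= on_fraction
  }, logical(1))
  names(rects)[lit]
}

#' Timestamped decoded reading
#'
#' @param value decoded numeric value (pH).
#' @param valid logical; `FALSE` for unreadable / transition frames.
#' @param timestamp seconds on the caller's monotonic clock.
#' @return An object of class `ph_reading`.
#' @export
ph_reading <- function(value, valid, timestamp = NA_real_) {
  structure(list(value = value, valid = isTRUE(valid), timestamp = timestamp),
            class = "ph_reading")
}

#' @export
print.ph_reading <- function(x, ...) {
  cat(sprintf("<ph_reading> %s at t=%s\n",
              if (x$valid) sprintf("%.3f", x$value) else "(invalid)",
              format(x$timestamp)), ...)
  invisible(x)
}

#' Decode a full display frame into a reading
#'
#' Runs the red-channel / threshold / segment-probe pipeline over every digit
#' box and assembles the displayed number using the calibration's fixed
#' decimal position. Leading blank digits are allowed (displays suppress
#' leading zeros); a blank after a non-blank digit, a minus sign anywhere, or
#' any unrecognized segment pattern marks the reading invalid — this is what
#' rejects mid-transition frames instead of mis-reading them.
#'
#' @param frame a [frame_image()].
#' @param cal an [ocr_calibration()].
#' @param timestamp passed through to the returned reading.
#' @return A [ph_reading()].
#' @export
decode_display <- function(frame, cal, timestamp = NA_real_) {
  if (!inherits(frame, "frame_image")) frame <- frame_image(frame)
  stopifnot(inherits(cal, "ocr_calibration"))
  geom <- cal$geometry
  .check_geometry_fits(geom, frame_height(frame), frame_width(frame))
  bin <- binarize(red_channel(frame), cal$threshold)
  symbols <- vapply(seq_len(geom$n_digits), function(i) {
    decode_digit(sample_pattern(bin, geom, i, cal$on_fraction))
  }, character(1))

  if (any(symbols == "invalid") || any(symbols == "minus"))
    return(ph_reading(NA_real_, FALSE, timestamp))
  blanks <- symbols == "blank"
  if (all(blanks))                              # nothing displayed
    return(ph_reading(NA_real_, FALSE, timestamp))
  if (any(blanks & cumsum(!blanks) > 0))        # blank after a digit
    return(ph_reading(NA_real_, FALSE, timestamp))
  digits <- ifelse(blanks, "0", symbols)
  scaled <- as.numeric(paste(digits, collapse = ""))
  k <- geom$n_digits - geom$decimal_index
  ph_reading(scaled / 10^k, TRUE, timestamp)
}

#' Automatic threshold calibration from a known reading
#'
#' Scans every integer threshold 0..255, keeps those for which
#' [decode_display()] returns the known value, and returns the midpoint of
#' the widest contiguous interval of working thresholds — the most
#' light-change-tolerant choice.
#'
#' @param frame a frame showing `known_value`.
#' @param geometry a [segment_geometry()].
#' @param known_value the value currently shown on the display.
#' @param on_fraction see [ocr_calibration()].
#' @return Integer threshold.
#' @export
auto_threshold <- function(frame, geometry, known_value, on_fraction = 0.5) {
  if (!inherits(frame, "frame_image")) frame <- frame_image(frame)
  k <- geometry$n_digits - geometry$decimal_index
  ok <- vapply(0:255, function(thr) {
    r <- decode_display(frame, ocr_calibration(thr, geometry, on_fraction))
    r$valid && abs(r$value - known_value) < 0.5 / 10^k
  }, logical(1))
  if (!any(ok))
    stop("calibration failure: no threshold in 0..255 decodes the known value",
         call. = FALSE)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  lo <- starts[best] - 1L                       # back to 0-based thresholds
  hi <- ends[best] - 1L
  as.integer((lo + hi) %/% 2L)
}
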