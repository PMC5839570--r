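#' Display rendering style
#'
#' Appearance parameters for the synthetic seven-segment renderer. The
#' renderer emits red-dominant frames — the signal lives in the red channel,
#' as on the red LED display of the target pH meter — with optional Gaussian
#' pixel noise emulating sensor/lighting variation.
#'
#' @param on_intensity red intensity of lit segments (default 230).
#' @param off_intensity red intensity of unlit segments (default 30).
#' @param background red/green/blue intensity of everything else.
#' @param noise_sd standard deviation of additive Gaussian pixel noise,
#'   clipped to `[0, 255]` after addition.
#' @param segment_thickness optional drawn bar thickness in pixels; when
#'   larger than the probe thickness the bars are widened symmetrically
#'   around the same canonical positions, so decoding still works.
#' @return A list of class `display_style`.
#' @export
display_style <- function(on_intensity = 230, off_intensity = 30,
                          background = 15, noise_sd = 0,
                          segment_thickness = NULL) {
  stopifnot(on_intensity >= 0, on_intensity <= 255,
            off_intensity >= 0, off_intensity <= 255,
            background >= 0, background <= 255, noise_sd >= 0)
  structure(list(on_intensity = on_intensity, off_intensity = off_intensity,
                 background = background, noise_sd = noise_sd,
                 segment_thickness = segment_thickness),
            class = "display_style")
}

# Split a display value into per-digit symbols ("0".."9" or "blank").
# Leading zeros left of the decimal point are blanked, except the digit
# immediately before the point (a meter shows "0.500", not ".500").
display_digits <- function(value, n_digits, decimal_index) {
  k <- n_digits - decimal_index
  scaled <- round(value * 10^k)
  if (is.na(scaled) || value < 0 || scaled >= 10^n_digits)
    stop(sprintf("value %s not representable on a %d-digit display",
                 format(value), n_digits), call. = FALSE)
  s <- strsplit(sprintf(paste0("%0", n_digits, "d"), as.integer(scaled)),
                "")[[1]]
  if (decimal_index > 1L)
    for (i in seq_len(decimal_index - 1L)) {
      if (s[i] != "0") break
      s[i] <- "blank"
    }
  s
}

# Expand a probe rectangle to the drawn thickness (thin dimension only).
.expand_rect <- function(r, extra_lo, extra_hi, horizontal) {
  if (horizontal) c(r[1] - extra_lo, r[2] + extra_hi, r[3], r[4])
  else            c(r[1], r[2], r[3] - extra_lo, r[4] + extra_hi)
}

#' Render a value as a seven-segment display frame
#'
#' Synthetic stand-in for the webcam pointed at the pH meter: draws the
#' digits of `value` as lit segment bars at the canonical probe positions of
#' `geometry`, on a red-dominant background, with optional Gaussian noise.
#' `render_display` followed by [decode_display()] with a matching
#' calibration is the identity on every representable value when
#' `noise_sd = 0`.
#'
#' @param value number to display; must be representable with the geometry's
#'   digit count and fixed decimal position.
#' @param geometry a [segment_geometry()].
#' @param style a [display_style()].
#' @param symbols optional character vector of per-digit symbols (names of
#'   `DIGIT_SEGMENTS`, e.g. `"minus"`), overriding the digits of `value`;
#'   used to fabricate transition/corrupted frames.
#' @param lit_override optional list, per digit, of segment-label vectors
#'   that replace the canonical pattern (for corruption injection).
#' @return A [frame_image()].
#' @export
render_display <- function(value, geometry, style = display_style(),
                           symbols = NULL, lit_override = NULL) {
  stopifnot(inherits(geometry, "segment_geometry"))
  if (is.null(symbols))
    symbols <- display_digits(value, geometry$n_digits, geometry$decimal_index)
  stopifnot(length(symbols) == geometry$n_digits,
            all(symbols %in% names(DIGIT_SEGMENTS)))

  h <- 2L * geometry$anchor_row + geometry$digit_height
  w <- 2L * geometry$anchor_col + geometry$digit_width +
    (geometry$n_digits - 1L) * geometry$digit_pitch
  red <- matrix(style$background, h, w)

  rects <- segment_rects(geometry$digit_width, geometry$digit_height)
  probe_t <- rects$a[2] - rects$a[1] + 1L
  extra <- if (!is.null(style$segment_thickness) &&
               style$segment_thickness > probe_t)
    style$segment_thickness - probe_t else 0L
  e_lo <- extra %/% 2L
  e_hi <- extra - e_lo

  for (i in seq_len(geometry$n_digits)) {
    anchor <- .digit_anchor(geometry, i)
    lit <- if (!is.null(lit_override) && !is.null(lit_override[[i]]))
      lit_override[[i]] else DIGIT_SEGMENTS[[symbols[i]]]
    for (seg in SEGMENT_LABELS) {
      r <- .expand_rect(rects[[seg]], e_lo, e_hi, seg %in% c("a", "g", "d"))
      rows <- max(0L, r[1]):min(geometry$digit_height - 1L, r[2]) +
        anchor[["row"]] + 1L
      cols <- max(0L, r[3]):min(geometry$digit_width - 1L, r[4]) +
        anchor[["col"]] + 1L
      red[rows, cols] <- if (seg %in% lit) style$on_intensity
                         else style$off_intensity
    }
  }

  px <- array(style$background, dim = c(h, w, 3L))
  px[, , 1L] <- red
  if (style$noise_sd > 0) {
    px <- px + stats::rnorm(length(px), sd = style$noise_sd)
    px <- pmin(pmax(px, 0), 255)
  }
  frame_image(round(px))
}

#' Frame sources
#'
#' A frame source is any function returning `list(frame, timestamp)` on each
#' call, or `NULL` when exhausted — the contract behind which the webcam, a
#' directory of PNGs and the synthetic renderer are interchangeable.
#'
#' @param paths character vector of PNG paths (read in order).
#' @param timestamps optional numeric timestamps, one per path.
#' @return A function implementing the frame-source contract.
#' @export
file_frame_source <- function(paths, timestamps = seq_along(paths)) {
  stopifnot(length(paths) == length(timestamps))
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(paths)) return(NULL)
    list(frame = read_frame_png(paths[i]), timestamp = timestamps[i])
  }
}

#' @rdname file_frame_source
#' @param value_fun function of a timestamp returning the value to display.
#' @param geometry,style passed to [render_display()].
#' @param dt seconds between frames.
#' @export
renderer_frame_source <- function(value_fun, geometry,
                                  style = display_style(), dt = 1) {
  t <- 0
  function() {
    t <<- t + dt
    list(frame = render_display(value_fun(t), geometry, style), timestamp = t)
  }
}
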