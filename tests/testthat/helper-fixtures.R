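# Shared fixtures: a small display geometry/calibration and quick renders.

test_geometry <- function(...) segment_geometry(2, 2, 6, 9, 8, ...)

test_cal <- function(threshold = 128, geometry = test_geometry(), ...)
  ocr_calibration(threshold, geometry, ...)

render_and_decode <- function(value, geometry = test_geometry(),
                              style = display_style(), threshold = 128) {
  decode_display(render_display(value, geometry, style),
                 ocr_calibration(threshold, geometry))
}

# All 128 subsets of the 7 segment labels.
all_patterns <- function() {
  segs <- c("a", "b", "c", "d", "e", "f", "g")
  lapply(0:127, function(bits) segs[bitwAnd(bits, 2^(0:6)) > 0])
}
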