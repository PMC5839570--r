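test_that("red_channel extracts exactly the red plane", {
  black <- frame_image(array(0, c(4, 5, 3)))
  expect_equal(red_channel(black), matrix(0L, 4, 5))

  px <- array(0, c(4, 5, 3)); px[, , 1] <- 200
  expect_equal(red_channel(frame_image(px)), matrix(200L, 4, 5))

  f <- render_display(3.141, test_geometry())
  expect_identical(red_channel(f), unclass(f)[, , 1])
})

test_that("binarize matches per-pixel brute force and is strict", {
  g200 <- matrix(200, 3, 3)
  expect_true(all(binarize(g200, 128)))
  expect_false(any(binarize(g200, 255)))
  expect_false(any(binarize(g200, 200)))   # strict '>'

  set.seed(7)
  for (thr in c(0, 17, 128, 254)) {
    gr <- matrix(sample(0:255, 60, replace = TRUE), 6, 10)
    oracle <- matrix(vapply(as.vector(gr), function(p) p > thr, logical(1)),
                     6, 10)
    expect_identical(binarize(gr, thr), oracle)
  }
  expect_error(binarize(g200, 256), "threshold")
  expect_error(binarize(g200, -1), "threshold")
})

test_that("decode_digit implements the canonical map; 12 of 128 patterns valid", {
  expect_identical(decode_digit(c("b", "c")), "1")
  expect_identical(decode_digit(character(0)), "blank")
  expect_identical(decode_digit("g"), "minus")
  expect_identical(decode_digit(c("a", "b", "c", "d", "e", "f", "g")), "8")
  expect_identical(decode_digit(c("a", "d", "g")), "invalid")
  expect_error(decode_digit("z"), "unknown segment")

  decoded <- vapply(all_patterns(), decode_digit, character(1))
  expect_identical(sum(decoded != "invalid"), 12L)
  # each valid symbol appears exactly once
  expect_setequal(decoded[decoded != "invalid"],
                  c(as.character(0:9), "blank", "minus"))
})

test_that("sample_pattern recovers rendered patterns, also under noise", {
  g <- test_geometry()
  bin8 <- binarize(red_channel(render_display(88.888, g)), 128)
  expect_setequal(sample_pattern(bin8, g, 3),
                  c("a", "b", "c", "d", "e", "f", "g"))

  blank_frame <- render_display(0.5, g)    # digits 1-2 blank, 3 is '0'
  bin <- binarize(red_channel(blank_frame), 128)
  expect_length(sample_pattern(bin, g, 1), 0)

  # rendered "1" with 10% salt-and-pepper noise still reads {b, c}
  set.seed(11)
  f1 <- render_display(11.111, g)
  px <- unclass(f1)
  flip <- runif(length(px)) < 0.10
  px[flip] <- 255 - px[flip]
  bin_noisy <- binarize(px[, , 1], 128)
  for (d in 1:5)
    expect_setequal(sample_pattern(bin_noisy, g, d, on_fraction = 0.5),
                    c("b", "c"))

  expect_error(
    sample_pattern(matrix(FALSE, 5, 5), g, 1),
    "beyond the frame")
})

test_that("decode_display handles leading blanks, rejects corruption", {
  g <- test_geometry()
  cal <- test_cal()
  r <- decode_display(render_display(10.553, g), cal, timestamp = 3.5)
  expect_true(r$valid)
  expect_equal(r$value, 10.553)
  expect_equal(r$timestamp, 3.5)

  r2 <- decode_display(render_display(9.997, g), cal)
  expect_true(r2$valid)
  expect_equal(r2$value, 9.997)

  # mid-transition frame: one digit corrupted to {a,d,g}
  ov <- list(NULL, NULL, c("a", "d", "g"), NULL, NULL)
  rbad <- decode_display(render_display(10.553, g, lit_override = ov), cal)
  expect_false(rbad$valid)

  # minus anywhere invalidates
  rminus <- decode_display(
    render_display(NA, g, symbols = c("minus", "1", "2", "3", "4")), cal)
  expect_false(rminus$valid)

  # internal blank invalidates
  rblank <- decode_display(
    render_display(NA, g, symbols = c("1", "blank", "2", "3", "4")), cal)
  expect_false(rblank$valid)

  # an entirely blank display is not a reading
  rempty <- decode_display(
    render_display(NA, g, symbols = rep("blank", 5)), cal)
  expect_false(rempty$valid)
})

test_that("single-segment flips never silently misread a digit", {
  # Flipping one segment of a rendered digit must either keep the decode
  # identical or make the frame invalid -- matching the brute-force map:
  # a flip is dangerous only if it lands exactly on another valid pattern.
  g <- segment_geometry(1, 1, 6, 9, 8, n_digits = 1L, decimal_index = 0L)
  cal <- ocr_calibration(128, g)
  for (digit in 0:9) {
    true_pattern <- phstat:::DIGIT_SEGMENTS[[as.character(digit)]]
    for (seg in c("a", "b", "c", "d", "e", "f", "g")) {
      flipped <- if (seg %in% true_pattern) setdiff(true_pattern, seg)
                 else union(true_pattern, seg)
      oracle <- decode_digit(flipped)
      r <- decode_display(
        render_display(NA, g, symbols = "0", lit_override = list(flipped)),
        cal)
      if (oracle %in% as.character(0:9)) {
        expect_true(r$valid)
        expect_equal(r$value * 10, as.numeric(oracle))
      } else {
        expect_false(r$valid)   # blank/minus/invalid all refuse the reading
      }
    }
  }
})

test_that("round-trip holds across a grid of geometries and values", {
  geoms <- list(
    segment_geometry(0, 0, 3, 5, 3, n_digits = 4, decimal_index = 1),
    segment_geometry(2, 2, 6, 9, 8, n_digits = 5, decimal_index = 2),
    segment_geometry(5, 3, 12, 21, 15, n_digits = 3, decimal_index = 2),
    segment_geometry(1, 1, 8, 30, 10, n_digits = 5, decimal_index = 0)
  )
  for (g in geoms) {
    k <- g$n_digits - g$decimal_index
    vmax <- (10^g$n_digits - 1) / 10^k
    vals <- c(0, 10^-k, vmax, round(runif(25, 0, vmax) * 10^k) / 10^k)
    cal <- ocr_calibration(128, g)
    for (v in vals) {
      r <- decode_display(render_display(v, g), cal)
      expect_true(r$valid)
      expect_equal(r$value, v, tolerance = 1e-12)
    }
  }
})

test_that("renderer range checks and noise robustness", {
  g <- test_geometry()
  expect_error(render_display(1000, g), "not representable")
  expect_error(render_display(-0.001, g), "not representable")

  set.seed(5)
  style <- display_style(on_intensity = 230, off_intensity = 30,
                         noise_sd = 20)
  for (i in 1:20) {
    r <- decode_display(render_display(7.000, g, style), test_cal(128))
    expect_true(r$valid)
    expect_equal(r$value, 7.000)
  }

  # thicker drawn bars still decode
  fat <- display_style(segment_thickness = 3)
  r <- decode_display(render_display(12.345, g, fat), test_cal())
  expect_equal(r$value, 12.345)
})

test_that("auto_threshold finds the widest working band", {
  g <- test_geometry()
  f <- render_display(10.553, g, display_style(on_intensity = 230,
                                               off_intensity = 30))
  thr <- auto_threshold(f, g, 10.553)
  expect_gt(thr, 30); expect_lt(thr, 230)
  r <- decode_display(f, ocr_calibration(thr, g))
  expect_equal(r$value, 10.553)
  # scan oracle: the returned threshold must itself work, and sit at the
  # midpoint of the widest contiguous working interval
  works <- vapply(0:255, function(t)
    isTRUE(all.equal(decode_display(f, ocr_calibration(t, g))$value, 10.553)),
    logical(1))
  runs <- rle(works)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  widest <- which(runs$values)[which.max(runs$lengths[runs$values])]
  expect_equal(thr, ((starts[widest] - 1L) + (ends[widest] - 1L)) %/% 2L)

  expect_error(auto_threshold(frame_image(array(0, c(13, 50, 3))), g, 1.0),
               "calibration failure")
})

test_that("threshold calibrated once survives fresh noisy frames", {
  g <- test_geometry()
  style <- display_style(on_intensity = 230, off_intensity = 30, noise_sd = 12)
  set.seed(21)
  thr <- auto_threshold(render_display(10.553, g, style), g, 10.553)
  cal <- ocr_calibration(thr, g)
  ok <- 0L
  for (i in 1:100) {
    r <- decode_display(render_display(10.553, g, style), cal)
    if (r$valid && r$value == 10.553) ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})

test_that("PNG round trip preserves frames; frame sources follow the contract", {
  g <- test_geometry()
  f <- render_display(3.217, g)
  path <- withr::local_tempfile(fileext = ".png")
  write_frame_png(f, path)
  f2 <- read_frame_png(path)
  expect_identical(unclass(f2), unclass(f))

  src <- file_frame_source(c(path, path), timestamps = c(1, 2))
  first <- src()
  expect_equal(first$timestamp, 1)
  expect_equal(decode_display(first$frame, test_cal())$value, 3.217)
  expect_equal(src()$timestamp, 2)
  expect_null(src())

  rsrc <- renderer_frame_source(function(t) 7.0, g)
  out <- rsrc()
  expect_equal(decode_display(out$frame, test_cal())$value, 7.0)
})
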