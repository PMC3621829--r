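test_that("segmentation finds dark objects against the background", {
  blank <- fx_blank_strip(64, 128)
  seg <- segment_objects(blank, background_level = 230 / 255)
  expect_length(seg$areas, 0)

  disk <- fx_disk_image(radius = 16)
  seg <- segment_objects(disk$img, background_level = 230 / 255)
  expect_length(seg$areas, 1)
  # oracle: the drawn mask's own pixel count
  expect_equal(seg$areas, sum(disk$mask))
  expect_lt(abs(seg$areas - pi * 16^2), 0.05 * pi * 16^2)

  two <- fx_disk_image(radius = 8, w = 256, cx = 60)
  img2 <- two$img
  d2 <- fx_disk_image(radius = 10, w = 256, cx = 190)
  img2 <- pmin(img2, d2$img)
  seg2 <- segment_objects(img2, background_level = 230 / 255)
  expect_length(seg2$areas, 2)
})

test_that("size filter thresholds at the minimum nucleus area inclusively", {
  expect_false(size_filter(c(10, 199), min_px = 200))
  expect_true(size_filter(c(10, 200), min_px = 200))   # "at least" 200
  expect_false(size_filter(integer(), min_px = 200))
})

test_that("edge filter detects steps and rejects constant or blurred images", {
  flat <- matrix(0.5, 64, 64)
  ef <- edge_filter(flat)
  expect_false(ef$pass)
  expect_equal(ef$edge_count, 0)

  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  # oracle: the smoothed gradient at a unit step exceeds the 0.07 threshold
  g <- cytofocus:::sobel_gradients(
    cytofocus:::blur_image(step, 1.41))$mag
  expect_gt(max(g), 0.07)
  expect_true(edge_filter(step)$pass)

  sl <- fx_small_slide()
  rec <- sl$cell_records[5, ]
  strip <- make_focus_strip(sl, c(rec$x_um, rec$y_um), rec$z_um)
  n_sharp <- edge_filter(strip)$edge_count
  n_blur <- edge_filter(cytofocus:::blur_image(strip, 8))$edge_count
  expect_gt(n_sharp, n_blur)
})

test_that("color filter counts stained object pixels per class with hue wrap", {
  tab <- color_class_table()
  mk <- function(n, rgbcol, w = 40) {
    img <- fx_blank_strip(20, w)
    mask <- matrix(FALSE, 20, w)
    mask[seq_len(ceiling(n / w)), ][seq_len(n)] <- TRUE
    for (ch in 1:3) { m <- img[, , ch]; m[mask] <- rgbcol[ch]; img[, , ch] <- m }
    list(img = img, mask = mask)
  }
  blue <- grDevices::col2rgb(grDevices::hsv(0.62, 0.5, 0.45)) / 255
  nine <- mk(9, blue)
  expect_false(color_filter(nine$img, nine$mask, tab)$pass)
  ten <- mk(10, blue)
  res <- color_filter(ten$img, ten$mask, tab)
  expect_true(res$pass)
  expect_equal(unname(res$counts["nucleus"]), 10L)
  # hue wrap: Fast Red sits across the 1 -> 0 boundary
  red <- mk(25, grDevices::col2rgb(grDevices::hsv(0.98, 0.6, 0.55)) / 255)
  expect_gte(color_filter(red$img, red$mask, tab)$counts[["ki67"]], 25)
  # a big gray dust object matches no class
  gray <- mk(500, c(0.55, 0.55, 0.55), w = 60)
  resg <- color_filter(gray$img, gray$mask, tab)
  expect_false(resg$pass)
  expect_equal(resg$pooled, 0L)
  expect_error(color_filter(ten$img, matrix(TRUE, 3, 3), tab), "shape")
})

test_that("focus point verdict is the conjunction of the three filters", {
  sl <- fx_small_slide()
  rec <- sl$cell_records[5, ]
  v_in <- classify_focus_point(
    make_focus_strip(sl, c(rec$x_um, rec$y_um), rec$z_um))
  expect_true(v_in$valid)
  expect_true(v_in$size_pass && v_in$edge_pass && v_in$color_pass)

  v_blank <- classify_focus_point(fx_blank_strip())
  expect_false(v_blank$valid)
  expect_false(v_blank$size_pass || v_blank$edge_pass || v_blank$color_pass)

  # a strongly defocused strip fails, and diagnostics are still populated
  v_oof <- classify_focus_point(
    make_focus_strip(sl, c(rec$x_um, rec$y_um), rec$z_um + 12))
  expect_false(v_oof$valid)
  expect_false(v_oof$edge_pass)
  expect_true(is.finite(v_oof$diagnostics$largest_area))

  # in-focus dust artifact: bright-field object without stain color
  dusty <- make_virtual_slide(n_cells = 0, dust_density = 20, seed = 31)
  d <- dusty$dust_records[which.max(dusty$dust_records$radius_um), ]
  v_dust <- classify_focus_point(
    make_focus_strip(dusty, c(d$x_um, d$y_um), dusty$dust_z_um))
  expect_false(v_dust$valid)
  expect_false(v_dust$color_pass)
  # conjunction law over a batch of mixed strips
  for (v in list(v_in, v_blank, v_oof, v_dust))
    expect_equal(v$valid, v$size_pass && v$edge_pass && v$color_pass)
})
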