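test_that("virtual slides honor the requested geometry and z range", {
  sl <- make_virtual_slide(n_cells = 120, z_range_um = 29.5, seed = 1)
  expect_s3_class(sl, "virtual_slide")
  got <- diff(range(sl$surface$grid))
  expect_lt(abs(got - 29.5) / 29.5, 0.05)
  # every cell lies inside the cell circle
  r <- sqrt((sl$cell_records$x_um - sl$circle_center_um[1])^2 +
              (sl$cell_records$y_um - sl$circle_center_um[2])^2)
  expect_true(all(r <= sl$circle_diameter_um / 2))
  # dust plane is disjoint from (and nearer the objective than) the cells
  expect_lt(sl$dust_z_um, min(sl$cell_records$z_um))
  expect_error(make_virtual_slide(width_px = -5), "positive")
})

test_that("generation and rendering are deterministic given the seed", {
  a <- make_virtual_slide(n_cells = 500, seed = 7)
  b <- make_virtual_slide(n_cells = 500, seed = 7)
  expect_identical(a$cell_records, b$cell_records)
  expect_identical(a$dust_records, b$dust_records)
  reg <- list(x0 = 100, y0 = 100, w = 80, h = 60)
  expect_identical(render_at(a, reg, 100), render_at(b, reg, 100))
  c2 <- make_virtual_slide(n_cells = 500, seed = 8)
  expect_false(identical(a$cell_records$x_um, c2$cell_records$x_um))
})

test_that("an empty slide renders pure background", {
  sl <- make_virtual_slide(n_cells = 0, dust_density = 0, noise_sd = 0,
                           seed = 2)
  img <- render_at(sl, list(x0 = 0, y0 = 0, w = 64, h = 64), 100)
  expect_true(all(img == sl$palette$background_value / 255))
  strip <- make_focus_strip(sl, c(sl$width_um / 2, sl$height_um / 2), 100)
  expect_true(all(strip == sl$palette$background_value / 255))
})

test_that("defocus blur is linear in |dz|, capped, and zero at focus", {
  m <- defocus_model(blur_sigma_per_um = 0.5, max_sigma = 10)
  expect_equal(defocus_sigma(m, 0), 0)
  expect_equal(defocus_sigma(m, 5), 2.5)
  expect_gt(defocus_sigma(m, 10), defocus_sigma(m, 5))
  expect_equal(defocus_sigma(m, 100), 10)   # cap
  dz <- seq(0, 30, 3)
  expect_true(all(diff(defocus_sigma(m, dz)) >= 0))
})

test_that("rendering keys blur to surface distance, dust to the dust plane", {
  sl <- fx_small_slide()
  rec <- sl$cell_records[10, ]
  tile_sharp <- render_cell_tile(rec, 0, noise_sd = 0)
  tile_blur <- render_cell_tile(rec, 10, noise_sd = 0)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  vlap <- function(img) stats::var(as.vector(
    EBImage::filter2(rgb_to_gray(img), lap, boundary = "replicate")))
  expect_gt(vlap(tile_sharp), vlap(tile_blur))

  # focusing on the dust plane leaves dust sharp and cells blurred
  dusty <- make_virtual_slide(n_cells = 40, dust_density = 15,
                              dust_layer_offset_um = 40, seed = 13)
  d <- dusty$dust_records[1, ]
  reg <- list(x0 = round(d$x_um / dusty$pixel_size_um) - 32,
              y0 = round(d$y_um / dusty$pixel_size_um) - 32, w = 64, h = 64)
  on_dust <- render_at(dusty, reg, dusty$dust_z_um, noise = FALSE)
  off_dust <- render_at(dusty, reg, dusty$dust_z_um + 30, noise = FALSE)
  expect_gt(vlap(on_dust), vlap(off_dust))
  expect_error(render_at(dusty, list(x0 = 1e7, y0 = 0, w = 10, h = 10), 0),
               "outside")
})

test_that("variance of the Laplacian decays monotonically with defocus", {
  rec <- fx_small_slide()$cell_records[3, ]
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  v <- vapply(seq(0, 14, 2), function(dz) {
    img <- render_cell_tile(rec, dz, noise_sd = 0)
    stats::var(as.vector(EBImage::filter2(rgb_to_gray(img), lap,
                                          boundary = "replicate")))
  }, numeric(1))
  expect_true(all(diff(v) <= 1e-12))
})

test_that("focus strips have the linear-sensor geometry and blur out", {
  sl <- fx_small_slide()
  rec <- sl$cell_records[1, ]
  strip <- make_focus_strip(sl, c(rec$x_um, rec$y_um), rec$z_um)
  expect_equal(dim(strip), c(64, 512, 3))
  n_in <- sum(canny_edges(rgb_to_gray(strip)))
  strip15 <- make_focus_strip(sl, c(rec$x_um, rec$y_um), rec$z_um + 15)
  expect_gt(n_in, sum(canny_edges(rgb_to_gray(strip15))))
  expect_error(make_focus_strip(sl, c(-100, -100), 100), "outside")
})

test_that("training sets are balanced, labeled and reproducible", {
  ts <- make_training_set(4, seed = 9)
  expect_length(ts, 8)
  labs <- vapply(ts, function(c) c$true_label, character(1))
  expect_equal(sum(labs == "in_focus"), 4)
  expect_equal(sum(labs == "out_of_focus"), 4)
  dz <- vapply(ts, function(c) c$defocus_um, numeric(1))
  expect_true(all(dz[labs == "out_of_focus"] >= 8))
  ts2 <- make_training_set(4, seed = 9)
  expect_identical(labs, vapply(ts2, function(c) c$true_label, character(1)))
  expect_identical(ts[[1]]$pixels, ts2[[1]]$pixels)
  one <- make_training_set(1, seed = 2)
  expect_length(one, 2)
})

test_that("dust and cell layers occupy disjoint z intervals", {
  for (seed in 1:3) {
    sl <- make_virtual_slide(n_cells = 100, z_range_um = 25,
                             dust_layer_offset_um = 30, seed = seed)
    expect_lt(sl$dust_z_um, min(sl$cell_records$z_um))
  }
})
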