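test_that("the cell circle is found from the macro border marks", {
  sl <- fx_small_slide()
  sc <- virtual_scanner(sl, seed = 3)
  macro <- scanner_macro(sc, 192)
  um_per_px <- sl$width_um / 192
  circle <- detect_cell_circle(macro, um_per_px, sl$circle_diameter_um)
  expect_lt(abs(circle$center_um[1] - sl$circle_center_um[1]),
            2 * um_per_px)
  expect_lt(abs(circle$center_um[2] - sl$circle_center_um[2]),
            2 * um_per_px)
  blank <- array(0.9, dim = c(100, 100, 3))
  expect_error(detect_cell_circle(blank, 10), "circle not found")
})

test_that("focus points are placed inside the circle, honoring bad regions", {
  circle <- list(center_um = c(2000, 2000), diameter_um = 2200)
  pts <- place_focus_points(circle, 12)
  expect_equal(nrow(pts), 12)
  d <- sqrt((pts$x_um - 2000)^2 + (pts$y_um - 2000)^2)
  expect_true(all(d <= 1100))
  # escalation never duplicates prior points
  more <- place_focus_points(circle, 12, existing = pts)
  expect_equal(nrow(more), 12)
  dd <- as.matrix(stats::dist(rbind(pts, more)))
  diag(dd) <- Inf
  expect_gt(min(dd), 1)
  # new points concentrate in a named bad region
  bad <- data.frame(x0_um = 1400, y0_um = 1400, w_um = 500, h_um = 500)
  inbad <- place_focus_points(circle, 8, existing = pts, bad_regions = bad)
  expect_true(all(inbad$x_um >= 1400 & inbad$x_um <= 1900 &
                    inbad$y_um >= 1400 & inbad$y_um <= 1900))
})

test_that("focus rounds keep cell locks and reject dust and blank probes", {
  # cell-rich probes without dust are all valid
  sl <- make_virtual_slide(n_cells = 200, dust_density = 0, seed = 21)
  sc <- virtual_scanner(sl, seed = 21)
  picks <- sl$cell_records[1:8, ]
  pts <- data.frame(x_um = picks$x_um, y_um = picks$y_um)
  valid <- focus_round(sc, pts)
  expect_equal(nrow(valid), 8)
  expect_true(all(valid$lock == "cell"))
  expect_equal(valid$z_um, picks$z_um, tolerance = 1e-9)

  # blank glass yields zero valid points
  empty <- make_virtual_slide(n_cells = 0, dust_density = 0, seed = 22)
  sce <- virtual_scanner(empty, seed = 22)
  v0 <- focus_round(sce, data.frame(x_um = c(1000, 2000), y_um = c(1000, 2000)))
  expect_equal(nrow(v0), 0)

  # probes locked on the dust plane are excluded from the output
  dusty <- make_virtual_slide(n_cells = 0, dust_density = 25, seed = 23)
  scd <- virtual_scanner(dusty, dust_capture = 5, seed = 23)
  dpts <- data.frame(x_um = dusty$dust_records$x_um[1:10],
                     y_um = dusty$dust_records$y_um[1:10])
  vd <- focus_round(scd, dpts)
  allres <- attr(vd, "all")
  expect_gt(sum(allres$lock == "dust"), 0)   # dust capture happened
  expect_equal(nrow(vd), 0)                  # but nothing passed the filters
})

test_that("focus maps interpolate exactly and improve with more points", {
  pts <- data.frame(x_um = c(100, 900, 500), y_um = c(100, 100, 800))
  pts$z_um <- 50 + 0.01 * pts$x_um - 0.005 * pts$y_um
  map <- build_focus_map(pts)
  expect_equal(focus_map_z(map, pts$x_um, pts$y_um), pts$z_um,
               tolerance = 1e-6)
  # three coplanar points reproduce their plane inside the hull
  expect_equal(focus_map_z(map, 500, 300), 50 + 0.01 * 500 - 0.005 * 300,
               tolerance = 1e-6)
  # one point extrapolates as a constant
  one <- build_focus_map(data.frame(x_um = 5, y_um = 5, z_um = 42))
  expect_equal(focus_map_z(one, c(0, 1000), c(0, 1000)), c(42, 42))
  expect_error(build_focus_map(data.frame()), "at least one")

  sl <- fx_slide()
  circle <- list(center_um = sl$circle_center_um,
                 diameter_um = sl$circle_diameter_um)
  rmse <- vapply(c(5, 30), function(n) {
    p <- place_focus_points(circle, n)
    p$z_um <- surface_z(sl, p$x_um, p$y_um)
    focus_map_rmse(build_focus_map(p), sl, seed = 3)
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("the valid-point rule requires strictly more than five points", {
  # verified through the config contract rather than a full scanner run
  cfg <- workflow_config()
  expect_equal(cfg$min_valid, 6)
  expect_equal(cfg$initial_points, 12)
  expect_equal(cfg$max_focus_iters, 5)
  expect_equal(cfg$max_scan_rounds, 7)
  expect_equal(cfg$sharpness_threshold, 90)
})

test_that("the full workflow completes on a populated slide and terminates", {
  sl <- fx_small_slide()
  sc <- virtual_scanner(sl, seed = 11)
  model <- fx_model()
  ses <- run_workflow(sc, model, workflow_config(max_cells = 10, seed = 11))
  expect_s3_class(ses, "scan_session")
  expect_equal(ses$status, "completed")
  expect_gte(ses$final_score, 90)
  expect_lte(ses$scan_rounds, 7)
  expect_lte(ses$focus_iterations, 5 * 3)   # max_iters x (restarts + 1)
  expect_gte(nrow(ses$focus_points), 6)
  # refocused regions in round k+1 come from the bad set of round k
  if (nrow(ses$per_round) > 1) {
    for (k in 2:nrow(ses$per_round)) {
      ref <- as.integer(strsplit(ses$per_round$refocused[k], " ")[[1]])
      expect_lte(length(ref), ses$per_round$n_oof_regions[k - 1])
    }
  }
})

test_that("repeat scans are reproducible with a low coefficient of variation", {
  sl <- fx_small_slide()
  sc <- virtual_scanner(sl, seed = 11)
  model <- fx_model()
  cv <- repeat_scan_cv(sc, model, n_repeats = 2,
                       config = workflow_config(max_cells = 8, seed = 11))
  expect_length(cv$scores, 2)
  expect_true(all(cv$statuses == "completed"))
  expect_equal(cv$cv, coefficient_of_variation(cv$scores))
  expect_lt(cv$cv, 10)
})
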