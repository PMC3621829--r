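test_that("region partition tiles the slide exactly", {
  p <- partition_regions(4000, 4000)
  expect_equal(nrow(p), 16)
  expect_true(all(p$w == 1000) && all(p$h == 1000))
  q <- partition_regions(4001, 4000)
  expect_lte(diff(range(q$w)), 1)
  for (part in list(p, q, partition_regions(777, 531)))
    expect_equal(sum(part$w * part$h),
                 max(part$x0 + part$w) * max(part$y0 + part$h))
})

test_that("cells are detected on the overview and sampling is capped", {
  sl <- fx_small_slide()
  ov <- render_overview(sl, 384)
  det <- detect_cells(ov, max_cells = 1e6, seed = 1)
  # most of the 300 deposits are found (clusters can merge)
  expect_gt(nrow(det), 150)
  capped <- detect_cells(ov, max_cells = 20, seed = 1)
  expect_equal(nrow(capped), 20)
  expect_identical(capped, detect_cells(ov, max_cells = 20, seed = 1))
  blank <- array(0.9, dim = c(64, 64, 3))
  expect_equal(nrow(detect_cells(blank)), 0)
})

test_that("exclusion filter drops huge clusters and very small cells", {
  areas <- c(4e6 + 1, 4e6, 1000, 199, 200)
  expect_equal(exclusion_filter(areas), c(4e6, 1000, 200))
  cells <- data.frame(area_px = areas)
  expect_equal(nrow(exclusion_filter(cells)), 3)
})

test_that("sharpness features behave on degenerate and structured tiles", {
  flat <- matrix(0.5, 64, 64)
  f <- extract_features(flat)
  expect_equal(unname(f[c("edge_count", "gradient_score", "diff_blurred")]),
               c(0, 0, 0))
  expect_equal(f[["blur_metric"]], 1)

  board <- matrix(0, 64, 64)
  board[(row(board) %/% 8 + col(board) %/% 8) %% 2 == 0] <- 1
  expect_gt(extract_features(board)[["diff_blurred"]], 0)

  rec <- fx_small_slide()$cell_records[2, ]
  f_in <- extract_features(render_cell_tile(rec, 0, noise_sd = 0))
  f_out <- extract_features(render_cell_tile(rec, 12, noise_sd = 0))
  for (feat in c("edge_count", "gradient_score", "diff_blurred"))
    expect_gt(f_in[[feat]], f_out[[feat]])
  expect_lt(f_in[["blur_metric"]], f_out[["blur_metric"]])
  expect_true(all(is.finite(f_in)))
  expect_gte(f_in[["blur_metric"]], 0)
  expect_lte(f_in[["blur_metric"]], 1)
})

test_that("the SVM separates synthetic focus classes and is reproducible", {
  model <- fx_model()
  expect_gte(model$train_accuracy, 0.95)
  probe <- make_training_set(10, seed = 202)
  p1 <- predict_sharpness(model, probe)
  tr <- make_training_set(60, seed = 101)
  model2 <- train_sharpness_model(tr, seed = 1)
  expect_identical(p1, predict_sharpness(model2, probe))
  # single-class input is rejected
  onesided <- probe[vapply(probe, function(c)
    c$true_label == "in_focus", logical(1))]
  expect_error(train_sharpness_model(onesided), "both classes")
  # identical feature vectors in both classes: error or near-chance flag
  x <- matrix(rep(1:10, 4), ncol = 2)
  y <- rep(c("in_focus", "out_of_focus"), each = 10)
  res <- tryCatch(train_sharpness_model(x, y),
                  warning = function(w) "flagged",
                  error = function(e) "flagged")
  expect_true(identical(res, "flagged") || res$train_accuracy < 0.7)
})

test_that("model bundles round-trip with their feature configuration", {
  model <- fx_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_sharpness_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_sharpness_model(path)
  probe <- make_training_set(5, seed = 303)
  expect_identical(predict_sharpness(model, probe),
                   predict_sharpness(back, probe))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_sharpness_model(bad), "not a valid")
})

test_that("slide scores average region scores over cell-bearing regions", {
  sl <- fx_small_slide()
  model <- fx_model()
  rep <- score_slide(sl, function(x, y) surface_z(sl, x, y), model,
                     max_cells = 15, seed = 2)
  expect_false(rep$no_data)
  sc <- rep$region_scores
  expect_true(all(sc[!is.na(sc)] >= 0 & sc[!is.na(sc)] <= 100))
  expect_equal(rep$slide_score, mean(sc[!is.na(sc)]))
  expect_gte(rep$slide_score, 90)   # scanning at the true surface is sharp
  # strict mode divides by all 16 regions
  rep_s <- score_slide(sl, function(x, y) surface_z(sl, x, y), model,
                       max_cells = 15, strict = TRUE, seed = 2)
  expect_equal(rep_s$slide_score, sum(sc[!is.na(sc)]) / 16)
  # an empty slide reports no-data
  empty <- make_virtual_slide(n_cells = 0, dust_density = 0, seed = 3)
  rep_e <- score_slide(empty, 100, model, seed = 1)
  expect_true(rep_e$no_data)
})

test_that("a defocused scan scores lower and flags its regions", {
  sl <- fx_small_slide()
  model <- fx_model()
  good <- score_slide(sl, function(x, y) surface_z(sl, x, y), model,
                      max_cells = 10, seed = 4)
  bad <- score_slide(sl, function(x, y) surface_z(sl, x, y) + 12, model,
                     max_cells = 10, seed = 4)
  expect_lt(bad$slide_score, good$slide_score)
  expect_gt(length(bad$out_of_focus_regions),
            length(good$out_of_focus_regions))
})

test_that("the slide score stabilizes as the cell budget grows", {
  sl <- fx_small_slide()
  model <- fx_model()
  mixed <- function(x, y) surface_z(sl, x, y) +
    ifelse(x > sl$width_um / 2, 9, 0)   # half the slide mildly defocused
  stab <- cells_vs_score_stability(sl, mixed, model,
                                   cell_counts = c(4, 40), runs = 4,
                                   seed = 6)
  expect_equal(nrow(stab), 2)
  expect_lte(stab$sd_score[stab$max_cells == 40],
             stab$sd_score[stab$max_cells == 4])
})
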