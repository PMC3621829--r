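# Whole-slide sharpness quantification.
#
# The slide is divided into a 4 x 4 grid of regions. In each region cells
# are detected on a low-resolution overview (Otsu segmentation + HSV cell
# test), up to 200 are sampled, and each sampled cell tile is described by
# five sharpness features: Canny edge count, mean gradient magnitude,
# difference to an unsharp-masked copy, difference to a Gaussian-blurred
# copy, and a no-reference perceptual blur metric. An RBF-kernel SVM
# classifies each cell in-focus / out-of-focus; the per-region percentage
# of in-focus cells is the region score, and the slide score is the mean
# over cell-bearing regions.

#' Partition slide bounds into a 4 x 4 region grid
#'
#' The tiles cover the area exactly with no overlap; with indivisible
#' bounds the tile sizes differ by at most one pixel.
#'
#' @param width_px,height_px slide bounds in px.
#' @param nx,ny grid shape (default 4 x 4).
#' @return data.frame with 0-based `x0`, `y0`, `w`, `h` and `region`
#'   (0-based row-major index).
#' @export
partition_regions <- function(width_px, height_px, nx = 4, ny = 4) {
  stopifnot(width_px >= nx, height_px >= ny)
  xb <- round(seq(0, width_px, length.out = nx + 1))
  yb <- round(seq(0, height_px, length.out = ny + 1))
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(region = seq_len(nrow(g)) - 1L,
             x0 = xb[g$ix], y0 = yb[g$iy],
             w = diff(xb)[g$ix], h = diff(yb)[g$iy])
}

region_of <- function(regions, x_px, y_px) {
  idx <- rep(NA_integer_, length(x_px))
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    sel <- x_px >= r$x0 & x_px < r$x0 + r$w & y_px >= r$y0 & y_px < r$y0 + r$h
    idx[sel] <- r$region
  }
  idx
}

#' Detect cells on a low-resolution overview image
#'
#' Grayscale conversion, Otsu thresholding, connected components, then an
#' HSV test requiring a minimum fraction of each object's pixels to fall in
#' a stain class. At most `max_cells` detections are uniformly sampled.
#'
#' @param overview RGB array.
#' @param hsv_table a [color_class_table()].
#' @param max_cells sampling cap (default 200).
#' @param min_area_px minimum object area on the overview (default 2).
#' @param min_stain_frac minimum stained fraction of object pixels.
#' @param seed sampling seed.
#' @return data.frame of detections: `x_px`, `y_px` (overview pixel
#'   centroids, 0-based), `area_px`. Empty when nothing is found.
#' @export
detect_cells <- function(overview, hsv_table = color_class_table(),
                         max_cells = 200, min_area_px = 2,
                         min_stain_frac = 0.3, seed = 1) {
  gray <- rgb_to_gray(overview)
  if (max(gray) - min(gray) < 0.05)
    return(data.frame(x_px = numeric(), y_px = numeric(),
                      area_px = integer()))
  th <- EBImage::otsu(gray, range = range(gray))
  mask <- gray < th
  labels <- unclass(EBImage::bwlabel(mask))
  n <- max(labels)
  if (n == 0)
    return(data.frame(x_px = numeric(), y_px = numeric(),
                      area_px = integer()))
  hsv <- rgb_to_hsv_array(overview)
  keep <- logical(n); cx <- numeric(n); cy <- numeric(n); ar <- integer(n)
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  rows <- (idx - 1) %% nrow(labels) + 1
  cols <- (idx - 1) %/% nrow(labels) + 1
  hv <- hsv[, , 1][idx]; sv <- hsv[, , 2][idx]; vv <- hsv[, , 3][idx]
  stained <- rep(FALSE, length(idx))
  for (cls in hsv_table) {
    stained <- stained | (hue_in_range(hv, cls$h[1], cls$h[2]) &
                            sv >= cls$s[1] & sv <= cls$s[2] &
                            vv >= cls$v[1] & vv <= cls$v[2])
  }
  for (k in seq_len(n)) {
    sel <- lab_v == k
    a <- sum(sel)
    ar[k] <- a
    keep[k] <- a >= min_area_px && mean(stained[sel]) >= min_stain_frac
    cx[k] <- mean(cols[sel]) - 0.5
    cy[k] <- mean(rows[sel]) - 0.5
  }
  det <- data.frame(x_px = cx, y_px = cy, area_px = ar)[keep, , drop = FALSE]
  if (nrow(det) > max_cells) {
    det <- with_seed(seed, det[sample.int(nrow(det), max_cells), ,
                               drop = FALSE])
  }
  rownames(det) <- NULL
  det
}

#' Exclude inappropriate cells from sharpness analysis
#'
#' Drops huge cell clusters (area above `max_area_px`, 4 megapixels at
#' native resolution) and very small cells (below `min_area_px`, the
#' small-nucleus floor). Thresholds scale with the square of the
#' resolution factor when working downscaled.
#'
#' @param cells list of `cell_image` objects, or a data.frame/vector with
#'   an `area_px` field.
#' @param max_area_px upper area bound (default 4e6, native scale).
#' @param min_area_px lower area bound (default 200, native scale).
#' @return the surviving subset, same type as the input.
#' @export
exclusion_filter <- function(cells, max_area_px = 4e6, min_area_px = 200) {
  areas <- if (is.data.frame(cells)) cells$area_px
  else if (is.list(cells)) vapply(cells, function(c) c$area_px, numeric(1))
  else cells
  keep <- areas <= max_area_px & areas >= min_area_px
  if (is.data.frame(cells)) cells[keep, , drop = FALSE]
  else if (is.list(cells)) cells[keep]
  else cells[keep]
}

# Crété-Roffet-style no-reference perceptual blur, in [0, 1]
# (0 = sharp, 1 = maximally blurred). The image is strongly blurred along
# each axis; if that changes neighboring-pixel variation only a little, the
# image was already blurred.
perceptual_blur_metric <- function(gray) {
  gray <- rgb_to_gray(gray)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3 || w < 3) return(1)
  k <- matrix(1 / 9, 1, 9)
  bver <- unclass(EBImage::filter2(gray, t(k), boundary = "replicate"))
  bhor <- unclass(EBImage::filter2(gray, k, boundary = "replicate"))
  dF_v <- abs(gray[-1, ] - gray[-h, ]); dB_v <- abs(bver[-1, ] - bver[-h, ])
  dF_h <- abs(gray[, -1] - gray[, -w]); dB_h <- abs(bhor[, -1] - bhor[, -w])
  sF_v <- sum(dF_v); sF_h <- sum(dF_h)
  if (sF_v == 0 && sF_h == 0) return(1)
  b_v <- if (sF_v > 0) (sF_v - sum(pmax(0, dF_v - dB_v))) / sF_v else 1
  b_h <- if (sF_h > 0) (sF_h - sum(pmax(0, dF_h - dB_h))) / sF_h else 1
  max(b_v, b_h)
}

#' Extract the five sharpness features of a cell tile
#'
#' `edge_count`: Canny edge pixels (same constants as the focus-point edge
#' filter); `gradient_score`: mean Sobel gradient magnitude;
#' `diff_sharpened`: mean absolute difference to an unsharp-masked copy;
#' `diff_blurred`: mean absolute difference to a Gaussian-blurred copy
#' (sigma 2); `blur_metric`: no-reference perceptual blur in [0, 1]. A
#' constant tile yields zeros with `blur_metric` 1.
#'
#' @param tile RGB array or grayscale matrix.
#' @param canny_high,canny_sigma Canny constants.
#' @param unsharp_sigma,unsharp_amount unsharp-mask parameters.
#' @param blur_sigma sigma of the blurred-copy reference.
#' @return named numeric vector of the five features.
#' @export
extract_features <- function(tile, canny_high = 0.07, canny_sigma = 1.41,
                             unsharp_sigma = 1, unsharp_amount = 1,
                             blur_sigma = 2) {
  gray <- rgb_to_gray(tile)
  if (max(gray) - min(gray) < 1e-8) {
    return(c(edge_count = 0, gradient_score = 0, diff_sharpened = 0,
             diff_blurred = 0, blur_metric = 1))
  }
  edges <- canny_edges(gray, sigma = canny_sigma, high = canny_high)
  grad <- mean(sobel_gradients(gray)$mag)
  blur1 <- blur_image(gray, unsharp_sigma)
  sharpened <- gray + unsharp_amount * (gray - blur1)
  blur2 <- blur_image(gray, blur_sigma)
  c(edge_count = sum(edges),
    gradient_score = grad,
    diff_sharpened = mean(abs(gray - sharpened)),
    diff_blurred = mean(abs(gray - blur2)),
    blur_metric = perceptual_blur_metric(gray))
}

feature_matrix <- function(cells, feature_config = list()) {
  fe <- function(tile) do.call(extract_features, c(list(tile), feature_config))
  t(vapply(cells, function(c) fe(c$pixels), numeric(5)))
}

#' Train the in-focus / out-of-focus SVM
#'
#' Features are standardized with the training statistics, then a support
#' vector machine with a Gaussian RBF kernel (scaling factor `sigma`,
#' default 1) is fitted.
#'
#' @param cells labeled `cell_image` list (with `true_label` fields), or a
#'   numeric feature matrix when `labels` is given.
#' @param labels optional label vector accompanying a feature matrix.
#' @param sigma RBF kernel scaling factor (kernel
#'   `exp(-||u - v||^2 / (2 sigma^2))`).
#' @param cost SVM cost parameter.
#' @param feature_config named list of [extract_features()] overrides.
#' @param seed retained in the model metadata for provenance.
#' @return a `sharpness_model`: the fitted SVM, standardization
#'   parameters, feature configuration and training metadata (including
#'   training accuracy).
#' @export
train_sharpness_model <- function(cells, labels = NULL, sigma = 1, cost = 1,
                                  feature_config = list(), seed = 1) {
  if (is.matrix(cells)) {
    x <- cells
  } else {
    labels <- vapply(cells, function(c) c$true_label, character(1))
    x <- feature_matrix(cells, feature_config)
  }
  y <- factor(labels, levels = c("in_focus", "out_of_focus"))
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes")
  centre <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = centre, scale = scl)
  fit <- with_seed(seed, e1071::svm(xs, y, kernel = "radial",
                                    gamma = 1 / (2 * sigma^2), cost = cost,
                                    scale = FALSE))
  train_acc <- mean(stats::predict(fit, xs) == y)
  if (train_acc < 0.6)
    warning(sprintf("training accuracy %.1f%% is near chance; %s",
                    100 * train_acc,
                    "the two classes may not be separable"))
  structure(list(svm = fit, center = centre, scale = scl,
                 feature_config = feature_config, sigma = sigma,
                 n_per_class = as.vector(table(y)),
                 train_accuracy = train_acc, seed = seed,
                 version = "cytofocus-model-1"),
            class = "sharpness_model")
}

#' Classify cell tiles with a trained sharpness model
#'
#' @param model a `sharpness_model`.
#' @param cells `cell_image` list or a feature matrix.
#' @return factor of predictions (`in_focus` / `out_of_focus`).
#' @export
predict_sharpness <- function(model, cells) {
  x <- if (is.matrix(cells)) cells
  else feature_matrix(cells, model$feature_config)
  xs <- scale(x, center = model$center, scale = model$scale)
  stats::predict(model$svm, xs)
}

#' Save / load a sharpness model bundle
#'
#' The bundle is an RDS file with a JSON sidecar recording the version,
#' feature configuration and training metadata; loading verifies the
#' version and feature configuration.
#'
#' @param model a `sharpness_model`.
#' @param path bundle path (`.rds`; the sidecar adds `.json`).
#' @return `path`, invisibly (for save); the model (for load).
#' @export
save_sharpness_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(version = model$version, sigma = model$sigma,
               n_per_class = model$n_per_class,
               train_accuracy = model$train_accuracy,
               feature_config = model$feature_config, seed = model$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_sharpness_model
#' @export
load_sharpness_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sharpness_model") ||
      !identical(model$version, "cytofocus-model-1"))
    stop("not a valid sharpness model bundle")
  model
}

# sample up to max_cells detections per region from a whole-slide overview
# and map them to full-resolution um coordinates
sample_slide_cells <- function(slide, overview_px = 384, hsv_table,
                               max_cells = 200, seed = 1) {
  ov <- render_overview(slide, overview_px)
  f <- slide$width_px / overview_px          # overview px -> slide px
  det <- detect_cells(ov, hsv_table, max_cells = .Machine$integer.max,
                      seed = seed)
  if (nrow(det) == 0) return(cbind(det, region = integer()))
  det$x_slide_px <- det$x_px * f
  det$y_slide_px <- det$y_px * f
  regions <- partition_regions(slide$width_px, slide$height_px)
  det$region <- region_of(regions, det$x_slide_px, det$y_slide_px)
  with_seed(seed, {
    parts <- split(det, det$region)
    parts <- lapply(parts, function(d) {
      if (nrow(d) > max_cells) d[sample.int(nrow(d), max_cells), ,
                                 drop = FALSE] else d
    })
    det <- do.call(rbind, parts)
  })
  rownames(det) <- NULL
  det
}

#' Score the sharpness of a (virtually scanned) slide
#'
#' Per region: detect cells on the overview, apply the exclusion filter,
#' extract tiles from the scan rendered at `focus`, classify each with the
#' model, and record the percentage of in-focus cells. The slide score is
#' the arithmetic mean over regions with at least one examined cell
#' (`strict = TRUE` averages over all 16 regions instead, counting empty
#' regions as 0).
#'
#' @param slide a `virtual_slide`.
#' @param focus focus height: scalar z in um or a `function(x_um, y_um)`
#'   such as [focus_map_fun()].
#' @param model a `sharpness_model`.
#' @param max_cells per-region sampling cap (default 200).
#' @param region_threshold regions scoring below this are listed as
#'   out of focus (default 90).
#' @param tile_px extracted tile side (default 64).
#' @param overview_px overview width used for detection.
#' @param min_area_px,max_area_px exclusion-filter bounds at working scale.
#' @param strict average over all regions including empty ones.
#' @param seed sampling seed.
#' @return a `slide_sharpness_report`: `region_scores` (16 values, NA
#'   where no cells), `cells_examined`, `slide_score`,
#'   `out_of_focus_regions`, `no_data` flag.
#' @export
score_slide <- function(slide, focus, model, max_cells = 200,
                        region_threshold = 90, tile_px = 64,
                        overview_px = 384, min_area_px = 50,
                        max_area_px = 1e6, strict = FALSE, seed = 1) {
  det <- sample_slide_cells(slide, overview_px, color_class_table(),
                            max_cells, seed)
  regions <- partition_regions(slide$width_px, slide$height_px)
  scores <- rep(NA_real_, nrow(regions))
  examined <- integer(nrow(regions))
  if (nrow(det) > 0) {
    # exclusion on full-resolution object area estimated from the overview
    f <- slide$width_px / overview_px
    det$area_px <- det$area_px * f^2
    det <- exclusion_filter(det, max_area_px, min_area_px)
    fz <- if (is.function(focus)) focus else function(x, y) focus
    for (k in seq_len(nrow(regions))) {
      d <- det[det$region == regions$region[k], , drop = FALSE]
      if (nrow(d) == 0) next
      preds <- character(nrow(d))
      for (j in seq_len(nrow(d))) {
        x0 <- round(min(max(d$x_slide_px[j] - tile_px / 2, 0),
                        slide$width_px - tile_px))
        y0 <- round(min(max(d$y_slide_px[j] - tile_px / 2, 0),
                        slide$height_px - tile_px))
        tile <- render_at(slide, list(x0 = x0, y0 = y0,
                                      w = tile_px, h = tile_px), fz)
        preds[j] <- as.character(
          predict_sharpness(model, list(list(pixels = tile))))
      }
      examined[k] <- nrow(d)
      scores[k] <- 100 * mean(preds == "in_focus")
    }
  }
  scored <- !is.na(scores)
  slide_score <- if (!any(scored)) NA_real_
  else if (strict) sum(scores[scored]) / nrow(regions)
  else mean(scores[scored])
  structure(list(region_scores = scores, cells_examined = examined,
                 slide_score = slide_score,
                 out_of_focus_regions =
                   regions$region[scored & scores < region_threshold],
                 region_threshold = region_threshold,
                 no_data = !any(scored)),
            class = "slide_sharpness_report")
}

#' @export
print.slide_sharpness_report <- function(x, ...) {
  if (x$no_data) {
    cat("slide sharpness: no cells detected (no-data)\n")
    return(invisible(x))
  }
  cat(sprintf("slide sharpness score: %.1f%%  (%d/%d regions with cells)\n",
              x$slide_score, sum(!is.na(x$region_scores)),
              length(x$region_scores)))
  if (length(x$out_of_focus_regions))
    cat("out-of-focus regions:",
        paste(x$out_of_focus_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Stability of the slide score against the per-region cell budget
#'
#' Repeats [score_slide()] with different `max_cells` values and sampling
#' seeds and reports the mean and standard deviation of the slide score at
#' each budget.
#'
#' @param slide,focus,model as [score_slide()].
#' @param cell_counts vector of `max_cells` budgets.
#' @param runs repeats per budget (default 10).
#' @param seed base seed; run r uses a derived substream.
#' @param ... further arguments passed to [score_slide()].
#' @return data.frame with `max_cells`, `mean_score`, `sd_score`.
#' @export
cells_vs_score_stability <- function(slide, focus, model,
                                     cell_counts = c(10, 50, 100, 200),
                                     runs = 10, seed = 1, ...) {
  stopifnot(all(cell_counts >= 1), runs >= 1)
  out <- lapply(cell_counts, function(mc) {
    scores <- vapply(seq_len(runs), function(r) {
      rep <- score_slide(slide, focus, model, max_cells = mc,
                         seed = derive_seed(seed, paste0("stab", mc, "_", r)),
                         ...)
      rep$slide_score
    }, numeric(1))
    data.frame(max_cells = mc, mean_score = mean(scores),
               sd_score = if (runs > 1) stats::sd(scores) else 0)
  })
  do.call(rbind, out)
}
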