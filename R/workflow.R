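# Closed-loop scan-control workflow against the virtual scanner: detect the
# cell circle on the macro image, place focus points, validate them with
# the focus-point filters, build a focus map, scan, score slide sharpness,
# and iterate — refocusing out-of-focus regions — until the slide passes
# the sharpness threshold or is declared not scannable.

#' A virtual scanner over a virtual slide
#'
#' Implements the scanner contract used by [run_workflow()]: a macro image,
#' an autofocus routine, and focus-map-driven rendering. The autofocus
#' emulates a contrast-based line sensor: it locks onto objects inside the
#' central quarter of the strip footprint; a probe over dust locks onto the
#' dust plane with probability proportional to the local dust coverage
#' (times `dust_capture`), and a probe with nothing in its window fails to
#' lock and returns a far-defocused height.
#'
#' @param slide a `virtual_slide`.
#' @param strip_w,strip_h focus strip shape in px.
#' @param dust_capture multiplier on the dust lock-on probability
#'   (default 1; 0 disables dust capture).
#' @param seed scanner RNG seed (autofocus substreams derive from it).
#' @return a `virtual_scanner`.
#' @export
virtual_scanner <- function(slide, strip_w = 512, strip_h = 64,
                            dust_capture = 1, seed = 1) {
  structure(list(slide = slide, strip_w = strip_w, strip_h = strip_h,
                 dust_capture = dust_capture, seed = as.integer(seed)),
            class = "virtual_scanner")
}

#' Macro image of the loaded slide
#' @param scanner a `virtual_scanner`.
#' @param width_px macro width.
#' @return RGB array including the slide border marks.
#' @export
scanner_macro <- function(scanner, width_px = 192) {
  render_overview(scanner$slide, width_px, borders = TRUE)
}

#' Autofocus a set of probe points
#'
#' For each point the scanner sweeps z and locks onto the dominant object
#' in its contrast window, returning the measured height and the captured
#' strip image.
#'
#' @param scanner a `virtual_scanner`.
#' @param points data.frame with `x_um`, `y_um`.
#' @param key string naming the focusing round (seeds the lock-on
#'   substream).
#' @return data.frame `x_um`, `y_um`, `z_um`, `lock` (cell/dust/none) with
#'   the rendered strips attached as attribute `strips`.
#' @export
scanner_focus_at <- function(scanner, points, key = "focus") {
  slide <- scanner$slide
  ps <- slide$pixel_size_um
  roi_half_w <- scanner$strip_w / 8 * ps   # central quarter of the strip
  roi_half_h <- scanner$strip_h / 2 * ps
  roi_area <- (2 * roi_half_w) * (2 * roi_half_h)
  cells <- slide$cell_records
  dust <- slide$dust_records
  n <- nrow(points)
  z <- numeric(n); lock <- character(n)
  rng_seed <- derive_seed(scanner$seed, key)
  u <- with_seed(rng_seed, stats::runif(n))
  for (k in seq_len(n)) {
    px <- points$x_um[k]; py <- points$y_um[k]
    csel <- if (nrow(cells)) which(
      abs(cells$x_um - px) < roi_half_w + cells$radius_um &
        abs(cells$y_um - py) < roi_half_h + cells$radius_um) else integer()
    dsel <- if (nrow(dust)) which(
      abs(dust$x_um - px) < roi_half_w + dust$radius_um &
        abs(dust$y_um - py) < roi_half_h + dust$radius_um) else integer()
    p_dust <- if (length(dsel))
      min(1, scanner$dust_capture *
            sum(pi * dust$radius_um[dsel]^2) / roi_area *
            if (length(csel)) 1 else 5) else 0
    if (length(dsel) && (length(csel) == 0 || u[k] < p_dust)) {
      z[k] <- slide$dust_z_um; lock[k] <- "dust"
    } else if (length(csel)) {
      d2 <- (cells$x_um[csel] - px)^2 + (cells$y_um[csel] - py)^2
      z[k] <- cells$z_um[csel[which.min(d2)]]; lock[k] <- "cell"
    } else {
      # no contrast in the window: the sweep fails to lock
      z[k] <- surface_z(slide, px, py) - slide$dust_layer_offset_um / 2
      lock[k] <- "none"
    }
  }
  out <- data.frame(x_um = points$x_um, y_um = points$y_um,
                    z_um = z, lock = lock)
  strips <- lapply(seq_len(n), function(k)
    make_focus_strip(slide, c(out$x_um[k], out$y_um[k]), out$z_um[k],
                     scanner$strip_w, scanner$strip_h))
  attr(out, "strips") <- strips
  out
}

#' Detect the cell circle on a macro image
#'
#' Thresholds the macro at a fixed dark level to segment the slide border
#' marks; their centroid is the circle centre, and the circle diameter is
#' the known deposition diameter.
#'
#' @param macro RGB macro image.
#' @param um_per_px physical size of a macro pixel.
#' @param diameter_um cell-circle diameter (default 2200 at desk scale).
#' @param threshold dark threshold (default 0.1).
#' @return list with `center_um` (x, y) and `diameter_um`.
#' @export
detect_cell_circle <- function(macro, um_per_px, diameter_um = 2200,
                               threshold = 0.1) {
  gray <- rgb_to_gray(macro)
  mask <- gray < threshold
  if (sum(mask) < 10) stop("circle not found: no border marks detected")
  idx <- which(mask)
  rows <- (idx - 1) %% nrow(gray) + 1
  cols <- (idx - 1) %/% nrow(gray) + 1
  list(center_um = c((mean(cols) - 0.5) * um_per_px,
                     (mean(rows) - 0.5) * um_per_px),
       diameter_um = diameter_um)
}

#' Place focus points inside the cell circle
#'
#' The initial layout is a quasi-uniform sunflower spiral over the circle.
#' When `bad_regions` rectangles are given, all new points are concentrated
#' inside them (clipped to the circle). New points never duplicate
#' `existing` ones.
#'
#' @param circle list with `center_um` and `diameter_um`.
#' @param n number of new points.
#' @param existing optional data.frame of prior points (`x_um`, `y_um`).
#' @param bad_regions optional data.frame of rectangles (`x0_um`, `y0_um`,
#'   `w_um`, `h_um`) to concentrate on.
#' @return data.frame `x_um`, `y_um` of the `n` new points.
#' @export
place_focus_points <- function(circle, n, existing = NULL,
                               bad_regions = NULL) {
  stopifnot(n >= 1)
  cx <- circle$center_um[1]; cy <- circle$center_um[2]
  R <- circle$diameter_um / 2
  golden <- pi * (3 - sqrt(5))
  n_exist <- if (is.null(existing)) 0L else nrow(existing)
  too_close <- function(x, y) {
    n_exist > 0 && any((existing$x_um - x)^2 + (existing$y_um - y)^2 < 25)
  }
  pts <- matrix(numeric(0), ncol = 2)
  if (is.null(bad_regions) || nrow(bad_regions) == 0) {
    k <- 0; i <- n_exist   # continue the spiral past prior layouts
    while (k < n) {
      i <- i + 1
      r <- 0.92 * R * sqrt(((i * 89) %% 997) / 997 + 1e-3)
      th <- i * golden
      x <- cx + r * cos(th); y <- cy + r * sin(th)
      if (!too_close(x, y)) { pts <- rbind(pts, c(x, y)); k <- k + 1 }
    }
  } else {
    k <- 0; i <- n_exist; reg <- 0
    while (k < n) {
      i <- i + 1
      reg <- reg %% nrow(bad_regions) + 1
      b <- bad_regions[reg, ]
      bx <- b$x0_um + b$w_um / 2; by <- b$y0_um + b$h_um / 2
      rr <- 0.45 * min(b$w_um, b$h_um) * sqrt((i %% 97) / 97 + 0.01)
      th <- i * golden
      x <- bx + rr * cos(th); y <- by + rr * sin(th)
      # clip to the circle
      d <- sqrt((x - cx)^2 + (y - cy)^2)
      if (d > 0.95 * R) {
        x <- cx + (x - cx) * 0.95 * R / d
        y <- cy + (y - cy) * 0.95 * R / d
      }
      if (!too_close(x, y)) { pts <- rbind(pts, c(x, y)); k <- k + 1 }
    }
  }
  data.frame(x_um = pts[, 1], y_um = pts[, 2])
}

#' One focusing round: autofocus and validate focus points
#'
#' Each probe is focused by the scanner and its strip classified by the
#' focus-point filters; only valid points are returned.
#'
#' @param scanner a `virtual_scanner`.
#' @param points data.frame `x_um`, `y_um`.
#' @param config a [filter_config()].
#' @param key focusing-round key (RNG substream).
#' @return data.frame of valid points (`x_um`, `y_um`, `z_um`, `lock`),
#'   with attribute `all` carrying every probed point and its verdict.
#' @export
focus_round <- function(scanner, points, config = filter_config(),
                        key = "focus") {
  stopifnot(nrow(points) >= 1)
  res <- scanner_focus_at(scanner, points, key)
  strips <- attr(res, "strips")
  verdicts <- vapply(strips, function(s)
    classify_focus_point(s, config)$valid, logical(1))
  res$valid <- verdicts
  out <- res[res$valid, c("x_um", "y_um", "z_um", "lock"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- res
  out
}

#' Workflow configuration
#'
#' The scan-control constants: 12 initial focus points, proceed to scan
#' when more than five are valid, at most five focusing iterations per
#' attempt, at most seven scan rounds, 90% sharpness threshold.
#'
#' @param initial_points,point_increment,max_points focus-point schedule.
#' @param min_valid minimum valid points to start scanning (6 = "more
#'   than five").
#' @param max_focus_iters focusing iterations per attempt.
#' @param restart_cap full restarts after failed attempts.
#' @param max_scan_rounds scan/re-scan rounds before aborting.
#' @param sharpness_threshold slide pass threshold in percent.
#' @param oof_score,oof_regions boundaries of the "completely
#'   out-of-focus" state (score below `oof_score` with at least
#'   `oof_regions` regions under the threshold).
#' @param max_cells per-region cell budget for scoring.
#' @param overview_px,tile_px scoring render sizes.
#' @param filter a [filter_config()].
#' @param seed session seed.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(initial_points = 12, point_increment = 12,
                            max_points = 85, min_valid = 6,
                            max_focus_iters = 5, restart_cap = 2,
                            max_scan_rounds = 7, sharpness_threshold = 90,
                            oof_score = 30, oof_regions = 12,
                            max_cells = 200, overview_px = 384,
                            tile_px = 64, filter = filter_config(),
                            seed = 1) {
  stopifnot(initial_points >= 1, min_valid >= 1, max_focus_iters >= 1,
            max_scan_rounds >= 1, sharpness_threshold >= 0,
            sharpness_threshold <= 100)
  structure(list(initial_points = initial_points,
                 point_increment = point_increment,
                 max_points = max_points, min_valid = min_valid,
                 max_focus_iters = max_focus_iters,
                 restart_cap = restart_cap,
                 max_scan_rounds = max_scan_rounds,
                 sharpness_threshold = sharpness_threshold,
                 oof_score = oof_score, oof_regions = oof_regions,
                 max_cells = max_cells, overview_px = overview_px,
                 tile_px = tile_px, filter = filter,
                 seed = as.integer(seed)), class = "workflow_config")
}

#' Run the complete iterative scan workflow
#'
#' Detect the cell circle; place 12 focus points; focus and validate; once
#' more than five points are valid, scan along the interpolated focus map
#' and score slide sharpness; re-focus out-of-focus regions (or the whole
#' slide if completely out of focus) and re-scan, for at most seven scan
#' rounds. Attempts whose five focusing iterations never yield enough
#' valid points are restarted with fresh points, up to the restart cap;
#' slides that never pass are `not_scannable`.
#'
#' @param scanner a `virtual_scanner`.
#' @param model a trained `sharpness_model`.
#' @param config a [workflow_config()].
#' @return a `scan_session`: `status` (completed / not_scannable),
#'   `final_score`, `focus_iterations`, `scan_rounds`, `per_round`
#'   data.frame, the final `focus_map` and valid `focus_points`.
#' @export
run_workflow <- function(scanner, model, config = workflow_config()) {
  slide <- scanner$slide
  macro_px <- 192
  macro <- scanner_macro(scanner, macro_px)
  circle <- detect_cell_circle(macro, slide$width_um / macro_px,
                               slide$circle_diameter_um)
  regions <- partition_regions(slide$width_px, slide$height_px)
  ps <- slide$pixel_size_um

  session <- list(status = "not_scannable", final_score = NA_real_,
                  focus_iterations = 0L, scan_rounds = 0L,
                  per_round = data.frame(), focus_map = NULL,
                  focus_points = NULL)
  per_round <- list()
  seed0 <- config$seed

  for (attempt in seq_len(config$restart_cap + 1L)) {
    points <- place_focus_points(circle, config$initial_points,
                                 existing = if (attempt > 1) points else NULL)
    valid <- NULL
    for (iter in seq_len(config$max_focus_iters)) {
      session$focus_iterations <- session$focus_iterations + 1L
      key <- sprintf("s%d_a%d_f%d", seed0, attempt, iter)
      valid <- focus_round(scanner, points, config$filter, key)
      if (nrow(valid) >= config$min_valid) break
      if (nrow(points) < config$max_points) {
        add <- min(config$point_increment,
                   config$max_points - nrow(points))
        points <- rbind(points,
                        place_focus_points(circle, add, existing = points))
      }
    }
    if (is.null(valid) || nrow(valid) < config$min_valid) next  # restart

    map <- build_focus_map(valid)
    refocused <- integer()
    while (session$scan_rounds < config$max_scan_rounds) {
      session$scan_rounds <- session$scan_rounds + 1L
      rep <- score_slide(slide, focus_map_fun(map), model,
                         max_cells = config$max_cells,
                         region_threshold = config$sharpness_threshold,
                         tile_px = config$tile_px,
                         overview_px = config$overview_px,
                         seed = derive_seed(seed0,
                                            paste0("score", session$scan_rounds)))
      per_round[[length(per_round) + 1]] <- data.frame(
        round = session$scan_rounds, n_points = nrow(points),
        n_valid = nrow(valid),
        slide_score = rep$slide_score,
        n_oof_regions = length(rep$out_of_focus_regions),
        refocused = paste(refocused, collapse = " "))
      if (rep$no_data) break
      if (rep$slide_score >= config$sharpness_threshold) {
        session$status <- "completed"
        session$final_score <- rep$slide_score
        session$focus_map <- map
        session$focus_points <- valid
        session$per_round <- do.call(rbind, per_round)
        return(structure(session, class = "scan_session"))
      }
      session$final_score <- rep$slide_score
      completely_oof <- rep$slide_score < config$oof_score &&
        length(rep$out_of_focus_regions) >= config$oof_regions
      if (nrow(points) < config$max_points) {
        add <- min(config$point_increment, config$max_points - nrow(points))
        bad <- NULL
        if (!completely_oof) {
          br <- regions[regions$region %in% rep$out_of_focus_regions, ,
                        drop = FALSE]
          bad <- data.frame(x0_um = br$x0 * ps, y0_um = br$y0 * ps,
                            w_um = br$w * ps, h_um = br$h * ps)
        }
        new_pts <- place_focus_points(circle, add, existing = points,
                                      bad_regions = bad)
        key <- sprintf("s%d_rescan%d", seed0, session$scan_rounds)
        new_valid <- focus_round(scanner, new_pts, config$filter, key)
        points <- rbind(points, new_pts)
        if (nrow(new_valid) > 0) valid <- rbind(valid, new_valid)
        map <- build_focus_map(valid)
      }
      refocused <- rep$out_of_focus_regions
    }
    session$focus_map <- map
    session$focus_points <- valid
    break
  }
  session$per_round <- if (length(per_round)) do.call(rbind, per_round)
  else data.frame()
  structure(session, class = "scan_session")
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("scan session: %s after %d focus iteration(s), %d scan round(s)\n",
              x$status, x$focus_iterations, x$scan_rounds))
  if (!is.na(x$final_score))
    cat(sprintf("final slide score: %.1f%%\n", x$final_score))
  invisible(x)
}

#' Repeat-scan reproducibility
#'
#' Runs the full workflow `n_repeats` times with identical configuration
#' but distinct RNG substreams and reports the per-run final scores and
#' their coefficient of variation.
#'
#' @param scanner a `virtual_scanner`.
#' @param model a `sharpness_model`.
#' @param n_repeats number of repeats (default 5).
#' @param config a [workflow_config()].
#' @return list with `scores`, `statuses` and `cv` (percent).
#' @export
repeat_scan_cv <- function(scanner, model, n_repeats = 5,
                           config = workflow_config()) {
  stopifnot(n_repeats >= 2)
  scores <- numeric(n_repeats); statuses <- character(n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("repeat", r))
    sc <- scanner
    sc$seed <- derive_seed(scanner$seed, paste0("repeat", r))
    ses <- run_workflow(sc, model, cfg)
    scores[r] <- ses$final_score
    statuses[r] <- ses$status
  }
  list(scores = scores, statuses = statuses,
       cv = coefficient_of_variation(scores))
}
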