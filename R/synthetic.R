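# Virtual liquid-based cytology slide simulator.
#
# A VirtualSlide is a desk-scale stand-in for a ThinPrep preparation: cells
# (hematoxylin, DAB/p16-brown or Fast-Red/Ki-67 stained, some clustered)
# scattered inside a circular deposition area, sitting on a smooth
# three-dimensional focal surface, plus a disjoint dust layer nearer the
# objective. Any region can be rendered at any focus height; each object is
# drawn with a Gaussian defocus blur whose sigma grows linearly with its
# distance from the focus plane. All generators are pure functions of
# (configuration, seed).
#
# Default geometry is 1/2 of the native 0.46 um/px scanner resolution
# (pixel_size_um = 0.92), a 4096 x 4096 px slide and a 2.2 mm cell circle —
# one tenth of the physical 22 mm circle, preserving the aspect conventions
# of the real system while staying desk-sized.

#' Stain palette for synthetic slides
#'
#' Hue ranges (fractions of the hue circle) from which per-cell colors are
#' jittered: hematoxylin-blue nuclei, pale blue-gray cytoplasm, DAB brown
#' (p16) and Fast Red (Ki-67).
#'
#' @param nucleus_hue_range,cytoplasm_hue_range,dab_hue_range,fastred_hue_range
#'   length-2 hue intervals in [0, 1] (`fastred` wraps the circle).
#' @param background_value background grayscale level in [0, 255].
#' @return a `stain_palette` list.
#' @export
stain_palette <- function(nucleus_hue_range = c(0.55, 0.68),
                          cytoplasm_hue_range = c(0.52, 0.62),
                          dab_hue_range = c(0.06, 0.11),
                          fastred_hue_range = c(0.95, 0.02),
                          background_value = 235) {
  stopifnot(background_value >= 0, background_value <= 255)
  structure(list(nucleus_hue_range = nucleus_hue_range,
                 cytoplasm_hue_range = cytoplasm_hue_range,
                 dab_hue_range = dab_hue_range,
                 fastred_hue_range = fastred_hue_range,
                 background_value = background_value),
            class = "stain_palette")
}

#' Linear defocus blur model
#'
#' Defocus is modeled as Gaussian blur with sigma linear in the absolute
#' z-offset from the focal plane, capped; sigma(0) = 0 and sigma is
#' nondecreasing in |dz|.
#'
#' @param blur_sigma_per_um blur growth rate in px per um of defocus.
#' @param max_sigma cap in px.
#' @return a `defocus_model` list.
#' @export
defocus_model <- function(blur_sigma_per_um = 0.5, max_sigma = 10) {
  stopifnot(blur_sigma_per_um >= 0, max_sigma >= 0)
  structure(list(blur_sigma_per_um = blur_sigma_per_um,
                 max_sigma = max_sigma),
            class = "defocus_model")
}

#' Blur sigma for a given defocus
#' @param model a [defocus_model()].
#' @param dz_um defocus offset(s) in um (sign ignored).
#' @return sigma in px.
#' @export
defocus_sigma <- function(model, dz_um) {
  pmin(model$blur_sigma_per_um * abs(dz_um), model$max_sigma)
}

# draw per-cell appearance attributes; caller provides RNG state
sample_cell_attrs <- function(n, palette, cluster_frac) {
  cls <- sample(c("hematoxylin", "p16", "ki67"), n, replace = TRUE,
                prob = c(0.6, 0.2, 0.2))
  hue_in <- function(rng, n) {
    lo <- rng[1]; hi <- rng[2]
    span <- if (hi >= lo) hi - lo else hi + 1 - lo
    (lo + stats::runif(n) * span) %% 1
  }
  nuc_h <- numeric(n); nuc_s <- numeric(n); nuc_v <- numeric(n)
  cyt_h <- hue_in(palette$cytoplasm_hue_range, n)
  cyt_s <- stats::runif(n, 0.08, 0.20)
  cyt_v <- stats::runif(n, 0.72, 0.86)
  for (k in seq_len(n)) {
    if (cls[k] == "ki67") {
      nuc_h[k] <- hue_in(palette$fastred_hue_range, 1)
      nuc_s[k] <- stats::runif(1, 0.50, 0.80)
      nuc_v[k] <- stats::runif(1, 0.45, 0.60)
    } else if (cls[k] == "p16") {
      nuc_h[k] <- hue_in(palette$dab_hue_range, 1)
      nuc_s[k] <- stats::runif(1, 0.50, 0.75)
      nuc_v[k] <- stats::runif(1, 0.30, 0.45)
      cyt_h[k] <- hue_in(palette$dab_hue_range, 1)
      cyt_s[k] <- stats::runif(1, 0.35, 0.55)
      cyt_v[k] <- stats::runif(1, 0.58, 0.72)
    } else {
      nuc_h[k] <- hue_in(palette$nucleus_hue_range, 1)
      nuc_s[k] <- stats::runif(1, 0.35, 0.60)
      nuc_v[k] <- stats::runif(1, 0.35, 0.55)
    }
  }
  data.frame(class = cls,
             cluster = stats::runif(n) < cluster_frac,
             radius_um = stats::runif(n, 18, 28),
             angle = stats::runif(n, 0, pi),
             ecc = stats::runif(n, 0.65, 0.95),
             nuc_frac = stats::runif(n, 0.30, 0.42),
             nuc_h = nuc_h, nuc_s = nuc_s, nuc_v = nuc_v,
             cyt_h = cyt_h, cyt_s = cyt_s, cyt_v = cyt_v,
             stringsAsFactors = FALSE)
}

#' Create a virtual LBC slide
#'
#' @param n_cells number of cells/clusters deposited inside the cell circle.
#' @param z_range_um requested peak-to-peak range of the focal surface
#'   (default 21, a typical LBC within-slide height variation; observed
#'   clinical slides range roughly 12-30 um).
#' @param dust_density dust particles per mm^2 of slide area on the
#'   coverslip plane (default 2).
#' @param dust_layer_offset_um separation of the dust plane from the bottom
#'   of the cell-layer z range, toward the objective (default 40).
#' @param width_px,height_px slide raster size at working resolution.
#' @param pixel_size_um working resolution (default 0.92, half native).
#' @param circle_diameter_um cell-circle diameter (default 2200).
#' @param z_base_um offset of the cell layer from the normalized z origin.
#' @param control_grid number of focal-surface control nodes per axis.
#' @param cluster_frac fraction of deposits rendered as cell clusters.
#' @param palette a [stain_palette()].
#' @param defocus a [defocus_model()].
#' @param noise_sd additive Gaussian render noise (intensity units).
#' @param seed RNG seed; identical seeds give bit-identical slides.
#' @return a `virtual_slide` object.
#' @export
make_virtual_slide <- function(n_cells = 500, z_range_um = 21,
                               dust_density = 2, dust_layer_offset_um = 40,
                               width_px = 4096, height_px = 4096,
                               pixel_size_um = 0.92,
                               circle_diameter_um = 2200,
                               z_base_um = 100, control_grid = 4,
                               cluster_frac = 0.15,
                               palette = stain_palette(),
                               defocus = defocus_model(),
                               noise_sd = 0.005, seed = 1) {
  if (width_px <= 0 || height_px <= 0 || pixel_size_um <= 0 ||
      circle_diameter_um <= 0)
    stop("slide dimensions must be positive")
  stopifnot(n_cells >= 0, z_range_um >= 0, dust_density >= 0)

  width_um <- width_px * pixel_size_um
  height_um <- height_px * pixel_size_um
  centre <- c(width_um / 2, height_um / 2)
  radius_um <- circle_diameter_um / 2

  with_seed(seed, {
    # focal surface: smooth random control grid rescaled to the requested
    # peak-to-peak range (bilinear interpolation attains its extremes at the
    # nodes, so the rendered range matches exactly)
    g <- matrix(stats::rnorm(control_grid^2), control_grid, control_grid)
    if (diff(range(g)) > 0 && z_range_um > 0) {
      g <- (g - min(g)) / diff(range(g)) * z_range_um
    } else {
      g <- matrix(0, control_grid, control_grid)
    }
    surface <- list(grid = g + z_base_um,
                    x_nodes = seq(0, width_um, length.out = control_grid),
                    y_nodes = seq(0, height_um, length.out = control_grid))

    # cell positions: uniform in the circle
    if (n_cells > 0) {
      th <- stats::runif(n_cells, 0, 2 * pi)
      rr <- radius_um * 0.97 * sqrt(stats::runif(n_cells))
      pos <- data.frame(x_um = centre[1] + rr * cos(th),
                        y_um = centre[2] + rr * sin(th))
      cells <- cbind(id = seq_len(n_cells), pos,
                     sample_cell_attrs(n_cells, palette, cluster_frac))
    } else {
      cells <- data.frame(id = integer(), x_um = numeric(), y_um = numeric())
    }

    n_dust <- stats::rpois(1, dust_density * width_um * height_um / 1e6)
    dust <- data.frame(x_um = stats::runif(n_dust, 0, width_um),
                       y_um = stats::runif(n_dust, 0, height_um),
                       radius_um = stats::runif(n_dust, 4, 12),
                       gray = stats::runif(n_dust, 0.35, 0.70))

    slide <- structure(list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um,
      width_um = width_um, height_um = height_um,
      circle_center_um = centre, circle_diameter_um = circle_diameter_um,
      cell_records = cells, surface = surface,
      dust_records = dust,
      dust_layer_offset_um = dust_layer_offset_um,
      dust_z_um = min(surface$grid) - dust_layer_offset_um,
      palette = palette, defocus = defocus,
      noise_sd = noise_sd, seed = as.integer(seed)), class = "virtual_slide")
    if (n_cells > 0)
      slide$cell_records$z_um <- surface_z(slide, cells$x_um, cells$y_um)
    slide
  })
}

#' Evaluate the true focal surface
#'
#' Bilinear interpolation of the control grid; finite everywhere on the
#' slide.
#'
#' @param slide a `virtual_slide`.
#' @param x_um,y_um physical coordinates (vectors).
#' @return z heights in um.
#' @export
surface_z <- function(slide, x_um, y_um) {
  s <- slide$surface
  nx <- length(s$x_nodes); ny <- length(s$y_nodes)
  fx <- (pmin(pmax(x_um, 0), slide$width_um)) /
    slide$width_um * (nx - 1)
  fy <- (pmin(pmax(y_um, 0), slide$height_um)) /
    slide$height_um * (ny - 1)
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  # grid is indexed [row = y node, col = x node]
  z00 <- s$grid[cbind(j0 + 1, i0 + 1)]
  z01 <- s$grid[cbind(j0 + 1, i0 + 2)]
  z10 <- s$grid[cbind(j0 + 2, i0 + 1)]
  z11 <- s$grid[cbind(j0 + 2, i0 + 2)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}

# --- rasterization -------------------------------------------------------

# anti-aliased ellipse coverage on a local pixel grid
ellipse_coverage <- function(rows, cols, cy, cx, a, b, angle) {
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(rows - cy, length(rows), length(cols))
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  q <- sqrt((u / a)^2 + (v / b)^2)
  aa <- 1.2 / max(min(a, b), 1)          # ~1 px anti-alias band
  clamp01((1 - q) / aa)
}

# paint a stained cell (or cluster of sub-cells) onto a white patch
paint_cell <- function(patch, record, cy, cx, px_per_um) {
  r <- record$radius_um * px_per_um
  subs <- if (isTRUE(record$cluster)) {
    k <- 3L
    ang <- record$angle + (seq_len(k) - 1) * 2.39996
    data.frame(cy = cy + 0.75 * r * sin(ang), cx = cx + 0.75 * r * cos(ang),
               r = 0.70 * r)
  } else data.frame(cy = cy, cx = cx, r = r)
  rows <- seq_len(nrow(patch[, , 1])); cols <- seq_len(ncol(patch[, , 1]))
  cyt_rgb <- hsv_to_rgb(record$cyt_h, record$cyt_s, record$cyt_v)
  nuc_rgb <- hsv_to_rgb(record$nuc_h, record$nuc_s, record$nuc_v)
  for (s in seq_len(nrow(subs))) {
    cov_c <- ellipse_coverage(rows, cols, subs$cy[s], subs$cx[s],
                              subs$r[s], subs$r[s] * record$ecc,
                              record$angle)
    rn <- subs$r[s] * record$nuc_frac
    cov_n <- ellipse_coverage(rows, cols, subs$cy[s], subs$cx[s],
                              rn, rn * 0.9, record$angle + 0.5)
    for (ch in 1:3) {
      layer <- patch[, , ch]
      layer <- layer * (1 - cov_c) + cyt_rgb[ch] * cov_c
      layer <- layer * (1 - cov_n) + nuc_rgb[ch] * cov_n
      patch[, , ch] <- layer
    }
  }
  patch
}

paint_dust <- function(patch, record, cy, cx, px_per_um) {
  rows <- seq_len(nrow(patch[, , 1])); cols <- seq_len(ncol(patch[, , 1]))
  r <- record$radius_um * px_per_um
  cov <- ellipse_coverage(rows, cols, cy, cx, r, 0.7 * r, 0.8)
  for (ch in 1:3)
    patch[, , ch] <- patch[, , ch] * (1 - cov) + record$gray * cov
  patch
}

#' Render a rectangular region of a virtual slide
#'
#' Each cell is drawn with Gaussian blur of sigma given by the slide's
#' defocus model at |focus_z - surface(x, y)|; dust is blurred by its
#' distance from the dust plane instead.
#'
#' @param slide a `virtual_slide`.
#' @param region `list(x0, y0, w, h)` in 0-based slide pixel coordinates.
#' @param focus_z focus height in um — a scalar, or a `function(x_um, y_um)`
#'   (e.g. [focus_map_fun()]) evaluated at each object's position.
#' @param noise add the slide's render noise (default TRUE).
#' @return RGB array (h x w x 3) in [0, 1].
#' @export
render_at <- function(slide, region, focus_z, noise = TRUE) {
  x0 <- region$x0; y0 <- region$y0; w <- region$w; h <- region$h
  if (w <= 0 || h <= 0) stop("region must have positive size")
  if (x0 >= slide$width_px || y0 >= slide$height_px ||
      x0 + w <= 0 || y0 + h <= 0)
    stop("region lies outside the slide")
  ps <- slide$pixel_size_um
  bg <- slide$palette$background_value / 255
  canvas <- array(bg, dim = c(h, w, 3))

  fz <- if (is.function(focus_z)) focus_z else function(x, y) focus_z

  draw_objects <- function(canvas, recs, z_vals, painter) {
    if (nrow(recs) == 0) return(canvas)
    f_vals <- fz(recs$x_um, recs$y_um)
    if (length(f_vals) == 1) f_vals <- rep(f_vals, nrow(recs))
    sigma_all <- defocus_sigma(slide$defocus, abs(f_vals - z_vals))
    clf <- if ("cluster" %in% names(recs))
      ifelse(recs$cluster, 1.6, 1.0) else 1.0
    r_all <- recs$radius_um / ps * clf
    margin_all <- ceiling(r_all + 3 * sigma_all + 2)
    ccx_all <- recs$x_um / ps - x0
    ccy_all <- recs$y_um / ps - y0
    vis <- which(ccx_all >= -margin_all & ccy_all >= -margin_all &
                   ccx_all <= w + margin_all & ccy_all <= h + margin_all)
    for (k in vis) {
      rec <- recs[k, ]
      sigma <- sigma_all[k]
      margin <- margin_all[k]
      ccx <- ccx_all[k]; ccy <- ccy_all[k]
      c0 <- floor(ccx - margin); c1 <- ceiling(ccx + margin)
      r0 <- floor(ccy - margin); r1 <- ceiling(ccy + margin)
      pw <- c1 - c0 + 1L; ph <- r1 - r0 + 1L
      patch <- array(bg, dim = c(ph, pw, 3))
      patch <- painter(patch, rec, ccy - r0 + 1, ccx - c0 + 1, 1 / ps)
      if (sigma > 0.05) patch <- blur_image(patch, sigma)
      # clip patch to canvas and min-composite (stains are darker than glass)
      rr <- max(1, 1 - r0):min(ph, h - r0)
      cc <- max(1, 1 - c0):min(pw, w - c0)
      if (length(rr) == 0 || length(cc) == 0) next
      tr <- rr + r0; tc <- cc + c0
      for (ch in 1:3)
        canvas[tr, tc, ch] <- pmin(canvas[tr, tc, ch], patch[rr, cc, ch])
    }
    canvas
  }

  if (nrow(slide$cell_records))
    canvas <- draw_objects(canvas, slide$cell_records,
                           slide$cell_records$z_um, paint_cell)
  if (nrow(slide$dust_records))
    canvas <- draw_objects(canvas, slide$dust_records,
                           rep(slide$dust_z_um, nrow(slide$dust_records)),
                           paint_dust)

  if (noise && slide$noise_sd > 0) {
    nseed <- derive_seed(slide$seed,
                         sprintf("render_%d_%d_%d_%d", x0, y0, w, h))
    canvas <- with_seed(nseed, {
      clamp01(canvas + stats::rnorm(length(canvas), 0, slide$noise_sd))
    })
  }
  canvas
}

#' Render a wide-and-short focus-point strip
#'
#' Emulates the scanner's linear sensor: a strip centred on a probe point,
#' rendered through [render_at()].
#'
#' @param slide a `virtual_slide`.
#' @param point `c(x_um, y_um)` probe location (must lie on the slide).
#' @param focus_z focus height in um (scalar or function, as [render_at()]).
#' @param strip_w,strip_h strip shape in px (default 512 x 64).
#' @return RGB array (strip_h x strip_w x 3).
#' @export
make_focus_strip <- function(slide, point, focus_z,
                             strip_w = 512, strip_h = 64) {
  ps <- slide$pixel_size_um
  if (point[1] < 0 || point[2] < 0 || point[1] > slide$width_um ||
      point[2] > slide$height_um)
    stop("point lies outside the slide")
  x0 <- round(point[1] / ps - strip_w / 2)
  y0 <- round(point[2] / ps - strip_h / 2)
  x0 <- min(max(x0, 0), slide$width_px - strip_w)
  y0 <- min(max(y0, 0), slide$height_px - strip_h)
  render_at(slide, list(x0 = x0, y0 = y0, w = strip_w, h = strip_h), focus_z)
}

#' Low-resolution overview of the whole slide
#'
#' All objects are drawn in focus (macro optics have a large depth of
#' field). Optionally includes the dark border marks that flank the cell
#' circle on physical ThinPrep slides, used for circle detection.
#'
#' @param slide a `virtual_slide`.
#' @param width_px overview width (height scales proportionally).
#' @param borders draw the slide border marks (default FALSE).
#' @return RGB array.
#' @export
render_overview <- function(slide, width_px = 256, borders = FALSE) {
  f <- width_px / slide$width_px
  h <- round(slide$height_px * f)
  ps_eff <- slide$pixel_size_um / f
  bg <- slide$palette$background_value / 255
  canvas <- array(bg, dim = c(h, width_px, 3))
  recs <- slide$cell_records
  if (nrow(recs) > 0) {
    rows <- seq_len(h); cols <- seq_len(width_px)
    for (k in seq_len(nrow(recs))) {
      rec <- recs[k, ]
      r_px <- max(rec$radius_um / ps_eff, 0.8) *
        if (isTRUE(rec$cluster)) 1.6 else 1.0
      ccx <- rec$x_um / ps_eff; ccy <- rec$y_um / ps_eff
      c0 <- max(1, floor(ccx - r_px - 1)); c1 <- min(width_px, ceiling(ccx + r_px + 1))
      r0 <- max(1, floor(ccy - r_px - 1)); r1 <- min(h, ceiling(ccy + r_px + 1))
      if (c0 > c1 || r0 > r1) next
      patch <- array(bg, dim = c(r1 - r0 + 1, c1 - c0 + 1, 3))
      patch <- paint_cell(patch, rec, ccy - r0 + 1, ccx - c0 + 1, 1 / ps_eff)
      for (ch in 1:3)
        canvas[r0:r1, c0:c1, ch] <- pmin(canvas[r0:r1, c0:c1, ch],
                                         patch[, , ch])
    }
  }
  if (borders) {
    # dark registration borders above and below the cell circle; their
    # centroid is the circle centre
    cx <- slide$circle_center_um[1] / ps_eff
    cy <- slide$circle_center_um[2] / ps_eff
    rad <- slide$circle_diameter_um / 2 / ps_eff
    bar_h <- max(2, round(0.03 * h))
    half_w <- round(rad * 0.9)
    for (sgn in c(-1, 1)) {
      rr <- round(cy + sgn * (rad + 2 * bar_h)) + seq(-bar_h, bar_h)
      rr <- rr[rr >= 1 & rr <= h]
      cc <- round(cx) + seq(-half_w, half_w)
      cc <- cc[cc >= 1 & cc <= width_px]
      canvas[rr, cc, ] <- 0.02
    }
  }
  canvas
}

#' Render a single-cell tile at a given defocus
#'
#' A 64 px (default) tile centred on one cell record, blurred by the
#' slide-independent defocus model. Used for building labeled training and
#' test sets.
#' @param record one-row cell record (as in `cell_records`).
#' @param dz_um defocus offset in um.
#' @param tile_px tile side.
#' @param pixel_size_um working resolution.
#' @param palette a [stain_palette()].
#' @param defocus a [defocus_model()].
#' @param noise_sd additive noise level.
#' @param seed noise seed.
#' @return RGB array (tile_px x tile_px x 3).
#' @export
render_cell_tile <- function(record, dz_um = 0, tile_px = 64,
                             pixel_size_um = 0.92,
                             palette = stain_palette(),
                             defocus = defocus_model(),
                             noise_sd = 0.005, seed = 1) {
  bg <- palette$background_value / 255
  sigma <- defocus_sigma(defocus, dz_um)
  pad <- ceiling(3 * sigma)
  side <- tile_px + 2 * pad
  patch <- array(bg, dim = c(side, side, 3))
  patch <- paint_cell(patch, record, side / 2, side / 2, 1 / pixel_size_um)
  if (sigma > 0.05) patch <- blur_image(patch, sigma)
  tile <- patch[pad + seq_len(tile_px), pad + seq_len(tile_px), , drop = FALSE]
  if (noise_sd > 0)
    tile <- with_seed(seed, clamp01(tile + stats::rnorm(length(tile), 0, noise_sd)))
  tile
}

#' Generate a balanced labeled cell-image training set
#'
#' In-focus tiles are rendered at small residual defocus (up to
#' `in_focus_max_um`); out-of-focus tiles at offsets sampled uniformly from
#' `[defocus_min_um, defocus_max_um]`. Ground-truth labels are attached.
#'
#' @param n_per_class images per class (total is twice this).
#' @param seed RNG seed.
#' @param defocus_min_um minimum defocus of the out-of-focus class
#'   (default 8).
#' @param defocus_max_um maximum defocus (default 20).
#' @param in_focus_max_um residual defocus of the in-focus class.
#' @param tile_px tile side in px.
#' @param pixel_size_um working resolution.
#' @param palette,defocus appearance and optics models.
#' @param noise_sd additive noise level.
#' @return list of `cell_image` lists with fields `pixels`, `location`,
#'   `area_px`, `true_label`, `defocus_um`.
#' @export
make_training_set <- function(n_per_class, seed = 1, defocus_min_um = 8,
                              defocus_max_um = 20, in_focus_max_um = 1.5,
                              tile_px = 64, pixel_size_um = 0.92,
                              palette = stain_palette(),
                              defocus = defocus_model(),
                              noise_sd = 0.005) {
  stopifnot(n_per_class >= 1, defocus_min_um > in_focus_max_um)
  n <- 2L * as.integer(n_per_class)
  with_seed(seed, {
    attrs <- sample_cell_attrs(n, palette, cluster_frac = 0.15)
    labels <- rep(c("in_focus", "out_of_focus"), each = n_per_class)
    dz <- c(stats::runif(n_per_class, 0, in_focus_max_um),
            stats::runif(n_per_class, defocus_min_um, defocus_max_um))
    seeds <- sample.int(2^30, n)
    lapply(seq_len(n), function(k) {
      rec <- attrs[k, ]
      rec$x_um <- 0; rec$y_um <- 0; rec$cluster <- FALSE
      r_px <- rec$radius_um / pixel_size_um
      structure(list(
        pixels = render_cell_tile(rec, dz[k], tile_px, pixel_size_um,
                                  palette, defocus, noise_sd, seeds[k]),
        location = c(NA_real_, NA_real_),
        region_index = NA_integer_,
        area_px = round(pi * r_px^2 * rec$ecc),
        true_label = labels[k],
        defocus_um = dz[k]), class = "cell_image")
    })
  })
}
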