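# Focus-point validity filters.
#
# A focus-point strip is valid only if in-focus cellular material is
# present. Three rule-based criteria are conjoined: (1) size — at least one
# connected object no smaller than a typical small superficial-cell nucleus;
# (2) edges — at least one Canny edge pixel, rejecting blurred images;
# (3) color — at least a minimum number of object pixels whose HSV values
# fall into one of the four stain classes (nuclei, cytoplasm, DAB/p16,
# Fast Red/Ki-67), rejecting gray dust and debris.

#' HSV stain-class table
#'
#' Per-class HSV intervals (hue may wrap the circle; saturation and value
#' do not), on [0, 1] scales. Defaults are derived from the stain
#' chemistry: hematoxylin-blue nuclei, pale low-saturation cytoplasm, DAB
#' brown and Fast Red. All intervals are user-overridable.
#'
#' @param nucleus,cytoplasm,p16,ki67 each a list with `h`, `s`, `v`
#'   length-2 intervals.
#' @return a `color_class_table` list.
#' @export
color_class_table <- function(
    nucleus   = list(h = c(0.50, 0.75), s = c(0.15, 1.00), v = c(0.10, 0.92)),
    cytoplasm = list(h = c(0.45, 0.75), s = c(0.05, 0.40), v = c(0.45, 0.97)),
    p16       = list(h = c(0.03, 0.14), s = c(0.20, 1.00), v = c(0.10, 0.92)),
    ki67      = list(h = c(0.90, 0.05), s = c(0.20, 1.00), v = c(0.15, 0.97))) {
  tab <- list(nucleus = nucleus, cytoplasm = cytoplasm, p16 = p16,
              ki67 = ki67)
  for (cls in tab) {
    stopifnot(all(unlist(cls) >= 0), all(unlist(cls) <= 1),
              cls$s[1] <= cls$s[2], cls$v[1] <= cls$v[2])
  }
  structure(tab, class = "color_class_table")
}

#' Configuration for the focus-point classifier
#'
#' @param size_min_px minimum object area in px (default 50 at the package's
#'   half-native working scale; the native-resolution rule is 200 px and
#'   scales with the square of the resolution factor).
#' @param canny_high,canny_sigma,canny_low_ratio Canny constants
#'   (defaults 0.07, 1.41, 0.4).
#' @param color_min_px minimum stained object pixels in any one class
#'   (default 10).
#' @param background_level fallback background grayscale level in [0, 1]
#'   (default 230/255) used when the image histogram has no clear mode.
#' @param bg_margin how far below the background level a pixel must be to
#'   count as object (intensity units, default 0.05).
#' @param hsv_table a [color_class_table()].
#' @return a `filter_config` list.
#' @export
filter_config <- function(size_min_px = 50, canny_high = 0.07,
                          canny_sigma = 1.41, canny_low_ratio = 0.4,
                          color_min_px = 10, background_level = 230 / 255,
                          bg_margin = 0.05,
                          hsv_table = color_class_table()) {
  stopifnot(size_min_px >= 0, canny_high > 0, canny_sigma > 0,
            color_min_px >= 0, background_level >= 0, background_level <= 1)
  structure(list(size_min_px = size_min_px, canny_high = canny_high,
                 canny_sigma = canny_sigma, canny_low_ratio = canny_low_ratio,
                 color_min_px = color_min_px,
                 background_level = background_level, bg_margin = bg_margin,
                 hsv_table = hsv_table), class = "filter_config")
}

# background grayscale level as the histogram mode, falling back to the
# configured constant when the image has no dominant bright level
estimate_background <- function(gray, fallback = 230 / 255) {
  h <- tabulate(pmin(pmax(floor(gray * 256) + 1L, 1L), 256L), nbins = 256L)
  m <- which.max(h)
  if (h[m] < 0.05 * length(gray)) return(fallback)
  (m - 0.5) / 256
}

#' Segment dark objects from the background
#'
#' Simple thresholding against the (estimated) background grayscale level,
#' followed by connected-component labeling.
#'
#' @param img RGB array or grayscale matrix in [0, 1].
#' @param background_level background grayscale level in [0, 1]; `NULL`
#'   (default) estimates it as the image histogram mode.
#' @param bg_margin object pixels must be darker than
#'   `background_level - bg_margin`.
#' @return list with `mask` (logical matrix), `labels` (integer matrix) and
#'   `areas` (per-object pixel counts; empty for a blank image).
#' @export
segment_objects <- function(img, background_level = NULL, bg_margin = 0.05) {
  gray <- rgb_to_gray(img)
  if (is.null(background_level)) background_level <- estimate_background(gray)
  stopifnot(background_level >= 0, background_level <= 1)
  mask <- gray < (background_level - bg_margin)
  labels <- unclass(EBImage::bwlabel(mask))
  n <- max(labels)
  areas <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer()
  list(mask = mask, labels = labels, areas = areas,
       background_level = background_level)
}

#' Size filter
#'
#' Passes iff any segmented object is at least `min_px` pixels — the area
#' of a typical small superficial-cell nucleus (200 px at native
#' resolution; 50 px at the package's default half-native scale).
#'
#' @param objects result of [segment_objects()] (or a numeric vector of
#'   object areas).
#' @param min_px minimum object area.
#' @return logical.
#' @export
size_filter <- function(objects, min_px = 50) {
  areas <- if (is.list(objects)) objects$areas else objects
  length(areas) > 0 && max(areas) >= min_px
}

#' Edge filter
#'
#' Canny edge detection on the grayscale image; the image passes iff at
#' least one edge pixel is present. Blurred images lose their edges and
#' fail.
#'
#' @param img RGB array or grayscale matrix.
#' @param high,sigma,low_ratio Canny constants.
#' @return list with `pass` (logical) and `edge_count`.
#' @export
edge_filter <- function(img, high = 0.07, sigma = 1.41, low_ratio = 0.4) {
  edges <- canny_edges(rgb_to_gray(img), sigma = sigma, high = high,
                       low_ratio = low_ratio)
  n <- sum(edges)
  list(pass = n >= 1, edge_count = n)
}

#' Color filter
#'
#' Counts object pixels whose HSV values fall into each stain class; the
#' image passes iff any single class reaches `min_pixels`. The pooled count
#' across classes is also reported.
#'
#' @param img RGB array.
#' @param mask logical object mask aligned with `img`.
#' @param table a [color_class_table()].
#' @param min_pixels threshold (default 10).
#' @return list with `pass`, per-class `counts` and `pooled` count.
#' @export
color_filter <- function(img, mask, table = color_class_table(),
                         min_pixels = 10) {
  stopifnot(length(dim(img)) == 3L)
  if (!all(dim(mask) == dim(img)[1:2]))
    stop("mask and image shapes do not match")
  counts <- stats::setNames(integer(length(table)), names(table))
  pooled <- 0L
  if (any(mask)) {
    r <- img[, , 1][mask]; g <- img[, , 2][mask]; b <- img[, , 3][mask]
    hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
    in_any <- rep(FALSE, ncol(hsv))
    for (nm in names(table)) {
      cls <- table[[nm]]
      sel <- hue_in_range(hsv[1, ], cls$h[1], cls$h[2]) &
        hsv[2, ] >= cls$s[1] & hsv[2, ] <= cls$s[2] &
        hsv[3, ] >= cls$v[1] & hsv[3, ] <= cls$v[2]
      counts[nm] <- sum(sel)
      in_any <- in_any | sel
    }
    pooled <- sum(in_any)
  }
  list(pass = any(counts >= min_pixels), counts = counts, pooled = pooled)
}

#' Classify a focus-point image
#'
#' Runs segmentation then the size, edge and color filters; the image is
#' valid iff all three pass. Diagnostics are populated even when an early
#' filter fails.
#'
#' @param img RGB array (a focus-point strip).
#' @param config a [filter_config()].
#' @return a `filter_verdict` list: `size_pass`, `edge_pass`, `color_pass`,
#'   `valid`, and `diagnostics` (largest object area, edge count, per-class
#'   and pooled color pixel counts, background level used).
#' @export
classify_focus_point <- function(img, config = filter_config()) {
  seg <- segment_objects(img, background_level = NULL,
                         bg_margin = config$bg_margin)
  size_ok <- size_filter(seg, config$size_min_px)
  edg <- edge_filter(img, high = config$canny_high,
                     sigma = config$canny_sigma,
                     low_ratio = config$canny_low_ratio)
  col <- color_filter(img, seg$mask, config$hsv_table, config$color_min_px)
  structure(list(
    size_pass = size_ok, edge_pass = edg$pass, color_pass = col$pass,
    valid = size_ok && edg$pass && col$pass,
    diagnostics = list(
      largest_area = if (length(seg$areas)) max(seg$areas) else 0L,
      edge_count = edg$edge_count,
      color_counts = col$counts, color_pooled = col$pooled,
      background_level = seg$background_level)), class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("focus point %s  (size %s, edge %s, color %s)\n",
              if (x$valid) "VALID" else "invalid",
              x$size_pass, x$edge_pass, x$color_pass))
  cat(sprintf("  largest object %d px, %d edge px, %d stained px\n",
              x$diagnostics$largest_area, x$diagnostics$edge_count,
              x$diagnostics$color_pooled))
  invisible(x)
}
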