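# Canny edge detection with the constants used by the focus-point edge
# filter: Gaussian smoothing, Sobel gradients, non-maximum suppression and
# hysteresis linking. The gradient magnitude is on the intensity scale of
# the unit-range image (a full black-to-white step has magnitude ~1 before
# smoothing), so the high threshold is absolute, not max-normalized: a
# uniformly blurred image genuinely loses its edges instead of having its
# faint gradients rescaled back above threshold.

sobel_gradients <- function(gray) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # d/dcol
  gx <- unclass(EBImage::filter2(gray, kx, boundary = "replicate")) / 4
  gy <- unclass(EBImage::filter2(gray, t(kx), boundary = "replicate")) / 4
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Canny edge detection
#'
#' @param gray grayscale matrix in [0, 1] (RGB arrays are converted).
#' @param sigma Gaussian smoothing sigma in pixels (default 1.41).
#' @param high high hysteresis threshold on the gradient magnitude of the
#'   unit-scaled image (default 0.07).
#' @param low_ratio low threshold as a fraction of `high` (default 0.4).
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(gray, sigma = 1.41, high = 0.07, low_ratio = 0.4) {
  gray <- rgb_to_gray(gray)
  if (nrow(gray) < 3 || ncol(gray) < 3)
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  g <- blur_image(gray, sigma)
  grd <- sobel_gradients(g)
  mag <- grd$mag
  if (max(mag) == 0) return(matrix(FALSE, nrow(mag), ncol(mag)))

  # non-maximum suppression: quantize gradient direction to 0/45/90/135 deg
  ang <- atan2(grd$gy, grd$gx)              # gy is d/drow
  d <- ((round(ang / (pi / 4)) %% 4) + 4) %% 4
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (k in 0:3) {
    sel <- d == k
    if (!any(sel)) next
    o <- offs[[as.character(k)]]
    a <- shift_mat(mag, o[1], o[2]); b <- shift_mat(mag, -o[1], -o[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  ridge <- mag >= n1 & mag >= n2

  low <- low_ratio * high
  weak <- ridge & mag >= low
  strong <- ridge & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(mag), ncol(mag)))
  if (!any(weak & !strong)) return(strong)

  # hysteresis: keep weak components touching a strong pixel
  lab <- unclass(EBImage::bwlabel(weak))
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, nrow(lab), ncol(lab))
}
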