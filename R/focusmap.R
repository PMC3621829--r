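# Focus-map construction: scattered interpolation of validated focus-point
# heights into a surface the scanner can follow. Thin-plate-spline
# interpolation is used: it is exact at the data points, reproduces a plane
# from three coplanar points, and extends smoothly beyond the point hull;
# evaluations are clamped to the observed z range so extrapolation can
# never leave the physically measured height band.

#' Build a focus map from validated focus points
#'
#' @param points data.frame with `x_um`, `y_um`, `z_um` (at least one row).
#' @return a `focus_map` with the fitted surface and the input points.
#' @export
build_focus_map <- function(points) {
  if (is.null(points) || nrow(points) < 1)
    stop("at least one valid focus point is required")
  pts <- points[, c("x_um", "y_um", "z_um")]
  n <- nrow(pts)
  fit <- NULL
  if (n >= 3) {
    # scale coordinates for conditioning
    sc <- max(diff(range(pts$x_um)), diff(range(pts$y_um)), 1)
    x <- pts$x_um / sc; y <- pts$y_um / sc; z <- pts$z_um
    r2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    K <- ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
    P <- cbind(1, x, y)
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    rhs <- c(z, 0, 0, 0)
    coef <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(coef) && all(is.finite(coef)))
      fit <- list(w = coef[1:n], a = coef[n + 1:3], x = x, y = y, sc = sc)
  }
  structure(list(points = pts, fit = fit, z_range = range(pts$z_um)),
            class = "focus_map")
}

#' Evaluate a focus map
#'
#' Exact at its data points; outside the data the surface is clamped to
#' the observed z range. With fewer than three (or degenerate) points the
#' map falls back to nearest-point heights.
#'
#' @param map a `focus_map`.
#' @param x_um,y_um coordinates (vectors).
#' @return z heights in um.
#' @export
focus_map_z <- function(map, x_um, y_um) {
  pts <- map$points
  if (is.null(map$fit)) {
    # nearest-point extrapolation (1 or 2 points, or collinear geometry)
    z <- vapply(seq_along(x_um), function(k) {
      d2 <- (pts$x_um - x_um[k])^2 + (pts$y_um - y_um[k])^2
      pts$z_um[which.min(d2)]
    }, numeric(1))
    return(z)
  }
  f <- map$fit
  xq <- x_um / f$sc; yq <- y_um / f$sc
  r2 <- outer(xq, f$x, "-")^2 + outer(yq, f$y, "-")^2
  U <- ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  z <- as.vector(U %*% f$w) + f$a[[1]] + f$a[[2]] * xq + f$a[[3]] * yq
  unname(pmin(pmax(z, map$z_range[1]), map$z_range[2]))
}

#' Focus map as a function of position
#'
#' Convenience wrapper returning `function(x_um, y_um)` for use as the
#' `focus` argument of [render_at()] and [score_slide()].
#'
#' @param map a `focus_map`.
#' @return a function of `(x_um, y_um)`.
#' @export
focus_map_fun <- function(map) function(x_um, y_um) focus_map_z(map, x_um, y_um)

#' RMSE of a focus map against the true focal surface
#'
#' Monte-Carlo estimate over the cell circle of a virtual slide.
#'
#' @param map a `focus_map`.
#' @param slide a `virtual_slide`.
#' @param n sample size.
#' @param seed sampling seed.
#' @return RMSE in um.
#' @export
focus_map_rmse <- function(map, slide, n = 500, seed = 1) {
  with_seed(seed, {
    th <- stats::runif(n, 0, 2 * pi)
    rr <- slide$circle_diameter_um / 2 * sqrt(stats::runif(n))
    x <- slide$circle_center_um[1] + rr * cos(th)
    y <- slide$circle_center_um[2] + rr * sin(th)
    sqrt(mean((focus_map_z(map, x, y) - surface_z(slide, x, y))^2))
  })
}
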