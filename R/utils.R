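# Internal helpers shared across modules. Images are plain R arrays:
# grayscale h x w matrices, RGB h x w x 3 arrays, values in [0, 1].
# Pixel coordinates are 0-based (row, col) with the origin top-left;
# physical coordinates are in micrometres with the same origin, x along
# columns and y along rows.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb the session
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from a parent seed and a string key.
# Keeps every derived seed inside 32-bit integer range.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647L)
}

#' Convert an RGB array to grayscale
#'
#' Standard luma weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param img RGB array (h x w x 3) or a matrix (returned unchanged).
#' @return grayscale matrix in [0, 1].
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# HSV representation of an RGB array; returns h x w x 3 with h, s, v in [0,1].
rgb_to_hsv_array <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]), maxColorValue = 1)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), dim = d)
}

# hsv triples -> rgb matrix (3 x n), h/s/v in [0,1]
hsv_to_rgb <- function(h, s, v) {
  grDevices::col2rgb(grDevices::hsv(h %% 1, clamp01(s), clamp01(v))) / 255
}

# Gaussian blur preserving array type; sigma 0 is the identity.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (is.matrix(img)) {
    unclass(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
  } else {
    out <- img
    for (k in seq_len(dim(img)[3]))
      out[, , k] <- unclass(EBImage::gblur(img[, , k], sigma = sigma,
                                           boundary = "replicate"))
    out
  }
}

# Membership of hue values in a possibly wrapping interval [lo, hi].
hue_in_range <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
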