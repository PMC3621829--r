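# Z-dimension analysis of focus-point height datasets: dust/cell layer
# separation, descriptive statistics and single-vs-multi-layer arithmetic.

#' Synthetic focus-point height dataset
#'
#' Cell-layer and dust-layer z values drawn from normal distributions,
#' with ground-truth layer labels attached. Positions are uniform on a
#' unit square (they do not affect the z statistics).
#'
#' @param n_cell,n_dust points per layer.
#' @param cell_mean,cell_sd cell-layer distribution in um (defaults match
#'   a typical normalized LBC cell layer around 100 um with a few um of
#'   spread).
#' @param dust_mean,dust_sd dust-layer distribution in um (nearer the
#'   objective).
#' @param seed RNG seed.
#' @return data.frame `x_um`, `y_um`, `z_um`, `truth`.
#' @export
simulate_z_dataset <- function(n_cell = 570, n_dust = 150,
                               cell_mean = 100, cell_sd = 4,
                               dust_mean = 40, dust_sd = 2, seed = 1) {
  with_seed(seed, {
    n <- n_cell + n_dust
    data.frame(
      x_um = stats::runif(n) * 1000, y_um = stats::runif(n) * 1000,
      z_um = c(stats::rnorm(n_cell, cell_mean, cell_sd),
               stats::rnorm(n_dust, dust_mean, dust_sd)),
      truth = rep(c("cell", "dust"), c(n_cell, n_dust)))
  })
}

#' Separate the dust layer from the cell layer
#'
#' One-dimensional two-cluster split of the z values by largest-gap
#' bisection: the biggest gap between consecutive sorted heights splits
#' the data, provided it exceeds `min_gap_factor` times the pooled
#' within-cluster standard deviation; otherwise all points are labeled
#' cell. The cluster nearer the objective (smaller z) is dust.
#'
#' @param data data.frame with a `z_um` column (>= 2 rows).
#' @param min_gap_factor gap significance guard (default 3).
#' @return the data with a `label` column (`cell` / `dust`).
#' @export
separate_layers <- function(data, min_gap_factor = 3) {
  stopifnot(nrow(data) >= 2, "z_um" %in% names(data))
  z <- data$z_um
  o <- order(z)
  gaps <- diff(z[o])
  g <- which.max(gaps)
  lower <- z[o][seq_len(g)]; upper <- z[o][-seq_len(g)]
  pooled_sd <- function(a, b) {
    va <- if (length(a) > 1) stats::var(a) else 0
    vb <- if (length(b) > 1) stats::var(b) else 0
    sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
           max(length(a) + length(b) - 2, 1))
  }
  s <- pooled_sd(lower, upper)
  data$label <- "cell"
  if (gaps[g] > min_gap_factor * s || (s == 0 && gaps[g] > 0)) {
    data$label[data$z_um <= max(lower)] <- "dust"
  }
  data
}

#' Descriptive z statistics
#'
#' @param data data.frame with `z_um` (typically the cell layer after
#'   [separate_layers()]), or a numeric vector of heights.
#' @return a `z_stats` list: `n_valid`, `mean`, `median`, `sd` (sample;
#'   0 for a single point), `min`, `max`, `range`, all in um.
#' @export
z_stats <- function(data) {
  z <- if (is.data.frame(data)) data$z_um else data
  if (length(z) < 1 || any(!is.finite(z))) stop("need finite z values")
  structure(list(n_valid = length(z), mean = mean(z),
                 median = stats::median(z),
                 sd = if (length(z) > 1) stats::sd(z) else 0,
                 min = min(z), max = max(z), range = max(z) - min(z)),
            class = "z_stats")
}

#' @export
print.z_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d, mean %.1f, median %.1f, sd %.1f, min %.1f, max %.1f, range %.1f um\n",
    x$n_valid, x$mean, x$median, x$sd, x$min, x$max, x$range))
  invisible(x)
}

#' Layers needed for a multi-layer scan
#'
#' Number of evenly spaced focal planes required to cover a z range:
#' `ceil(range / spacing)`, at least 1.
#'
#' @param z_range_um focal range to cover (>= 0).
#' @param spacing_um layer spacing (> 0).
#' @return integer layer count.
#' @export
layers_needed <- function(z_range_um, spacing_um) {
  if (spacing_um <= 0) stop("spacing must be positive")
  stopifnot(z_range_um >= 0)
  max(1L, as.integer(ceiling(z_range_um / spacing_um)))
}

#' Read / write focus-point height datasets as CSV
#'
#' Columns `x_um`, `y_um`, `z_um` and optionally `label`.
#' @param path CSV path.
#' @param data data.frame to write.
#' @return the data.frame (read), or `path` invisibly (write).
#' @export
read_z_dataset <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(d)))
  d
}

#' @rdname read_z_dataset
#' @export
write_z_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
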