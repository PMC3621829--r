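# Shared fixtures, built lazily and cached for the whole run. Everything is
# generated in code from fixed seeds; no data files are used.

.fx <- new.env(parent = emptyenv())

with_seed_for_test <- function(seed, code) withr::with_seed(seed, code)

# default-condition slide (500 cells, 21 um surface range, dust present)
fx_slide <- function() {
  if (is.null(.fx$slide)) .fx$slide <- make_virtual_slide(seed = 5)
  .fx$slide
}

# smaller slide for unit tests that render many tiles
fx_small_slide <- function() {
  if (is.null(.fx$small)) .fx$small <- make_virtual_slide(n_cells = 300,
                                                          seed = 11)
  .fx$small
}

# quick sharpness model (60 tiles per class) for unit tests; the
# full-size 800-per-class model is built inside the acceptance tests
fx_model <- function() {
  if (is.null(.fx$model)) {
    tr <- make_training_set(60, seed = 101)
    .fx$model <- train_sharpness_model(tr, seed = 1)
  }
  .fx$model
}

# uniform background strip
fx_blank_strip <- function(h = 64, w = 512, level = 230 / 255) {
  array(level, dim = c(h, w, 3))
}

# dark disk of a given radius on a bright background; the drawn mask is
# returned alongside so tests can count its pixels as an oracle
fx_disk_image <- function(radius, h = 64, w = 128, cx = w / 2, cy = h / 2,
                          dark = 0.2, bg = 230 / 255) {
  img <- array(bg, dim = c(h, w, 3))
  d2 <- outer(seq_len(h) - cy, rep(1, w))^2 + outer(rep(1, h),
                                                    seq_len(w) - cx)^2
  mask <- d2 <= radius^2
  for (ch in 1:3) { m <- img[, , ch]; m[mask] <- dark; img[, , ch] <- m }
  list(img = img, mask = mask)
}
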