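# Small fixtures built in code.

# uniform-colour RGB raster
flat_rgb <- function(h = 16L, w = 16L, rgb = c(40, 60, 200)) {
  raster_image(array(rep(rgb, each = h * w), c(h, w, 3L)), "RGB")
}

# HSV raster from a hue matrix (constant saturation/value)
hsv_from_hue <- function(hue, s = 200L, v = 200L) {
  raster_image(array(c(hue, matrix(s, nrow(hue), ncol(hue)),
                       matrix(v, nrow(hue), ncol(hue))),
                     c(dim(hue), 3L)), "HSV")
}

# a pixel_group from explicit 0-based coordinates
mk_group <- function(id, ys, xs) {
  structure(list(id = as.integer(id),
                 pixels = cbind(y = as.integer(ys), x = as.integer(xs)),
                 bbox = c(p1Y = min(ys), p1X = min(xs),
                          p2Y = max(ys), p2X = max(xs)),
                 n_pixels = length(ys)), class = "pixel_group")
}

# a solid rectangular group
rect_group <- function(id, y0, x0, h, w) {
  gg <- expand.grid(y = y0:(y0 + h - 1L), x = x0:(x0 + w - 1L))
  mk_group(id, gg$y, gg$x)
}

# a small, fast scene spec (smaller field, fewer oysters)
small_spec <- function(seed, n_oysters = 6L, ...) {
  scene_spec(image_size = 512L, mm_per_px = 0.75, n_oysters = n_oysters,
             seed = seed, ...)
}

# linearly separable size-share records for the MLP
separable_ann_data <- function(n_per_class = 60L, seed = 99L) {
  set.seed(seed)
  mk <- function(mu, cls) data.frame(
    pct_mean = stats::rnorm(n_per_class, mu, mu / 20),
    pct_std = stats::rnorm(n_per_class, mu / 2, mu / 40),
    pct_pixels = stats::rnorm(n_per_class, mu * 4, mu / 20),
    class = cls)
  rbind(mk(0.002, 0L), mk(0.01, 1L), mk(0.025, 2L))
}

# separable geometry records: class is a step function of pct_large
separable_rf_data <- function(n_per_class = 60L, seed = 99L) {
  set.seed(seed)
  mk <- function(lo, hi, cls) data.frame(
    pct_large = stats::runif(n_per_class, lo, hi),
    pct_width = stats::runif(n_per_class, lo / 2, hi / 2),
    pct_p1X = stats::runif(n_per_class, 0, 900),
    pct_p1Y = stats::runif(n_per_class, 0, 900),
    pct_p2X = stats::runif(n_per_class, 100, 1000),
    pct_p2Y = stats::runif(n_per_class, 100, 1000),
    class = cls)
  rbind(mk(10, 120, 0L), mk(250, 550, 1L), mk(700, 1100, 2L))
}
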