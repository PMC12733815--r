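#' @useDynLib oystermetry, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Raster image with an explicit colour space
#'
#' A minimal container for an 8-bit, 3-channel raster. Pixels are stored as
#' an `H x W x 3` integer array (channel values 0--255) in row-major image
#' convention: the first index is the image row (y, top to bottom), the
#' second the column (x, left to right). All coordinates reported by the
#' package are 0-based with the origin at the top-left pixel.
#'
#' The colour-space tag always reflects the last conversion applied;
#' conversions are explicit via [convert_colour()], never implicit. Hue uses
#' the 8-bit half-degree convention (0--179) so that hue arithmetic in the
#' segmentation stage stays integer-friendly.
#'
#' @param pixels numeric or integer `H x W x 3` array, values in 0--255.
#' @param colour_space one of `"RGB"`, `"HSV"`, `"YUV"`.
#' @param source_path optional path the raster was read from.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, colour_space = c("RGB", "HSV", "YUV"),
                         source_path = NULL) {
  colour_space <- match.arg(colour_space)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    stop("raster too small: need at least 8 x 8 pixels, got ",
         d[1], " x ", d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must be finite and in 0..255")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, colour_space = colour_space,
         source_path = source_path),
    class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %d x %d, %s%s>\n", d[1], d[2], x$colour_space,
              if (!is.null(x$source_path))
                paste0(", from ", x$source_path) else ""))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Read a PNG or JPEG image
#'
#' Decodes the file and returns an RGB [raster_image()]. Grayscale images
#' are promoted to three equal channels.
#'
#' @param path path to a PNG or JPEG file.
#' @return A `raster_image` with `colour_space = "RGB"`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
                    stop("cannot read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {                      # grayscale -> replicate
    dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  } else if (dim(dat)[3] > 3L) {                     # drop alpha
    dat <- dat[, , 1:3, drop = FALSE]
  } else if (dim(dat)[3] == 2L) {                    # gray + alpha
    dat <- array(rep(dat[, , 1L], 3L), c(dim(dat)[1:2], 3L))
  }
  # EBImage stores (x, y, c); transpose into (y, x, c)
  px <- round(aperm(dat, c(2L, 1L, 3L)) * 255)
  raster_image(pmax(pmin(px, 255), 0), "RGB", source_path = path)
}

#' Write a raster image to a PNG file
#'
#' @param img a `raster_image` (any colour space; pixels written as stored).
#' @param path output path; a `.png` extension is expected.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  dat <- aperm(img$pixels / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}

#' Downsample an image by four in each dimension
#'
#' Divides height and width by four (floor), averaging each 4 x 4 block
#' (area interpolation, the standard choice for downsampling). The colour
#' space is preserved. This is the resolution-reduction step applied before
#' segmentation to keep the pixel clustering cheap.
#'
#' @param img a `raster_image` with `H >= 32` and `W >= 32`.
#' @return A `raster_image` of dimensions `floor(H/4) x floor(W/4)`.
#' @export
resize_quarter <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  d <- dim(img$pixels)
  if (d[1] < 32L || d[2] < 32L)
    stop("image too small to resize: need at least 32 x 32, got ",
         d[1], " x ", d[2])
  H4 <- d[1] %/% 4L; W4 <- d[2] %/% 4L
  out <- array(0, c(H4, W4, 3L))
  for (ch in 1:3) {
    m <- img$pixels[seq_len(4L * H4), seq_len(4L * W4), ch]
    acc <- matrix(0, H4, W4)
    for (i in 1:4) for (j in 1:4)
      acc <- acc + m[seq(i, by = 4L, length.out = H4),
                     seq(j, by = 4L, length.out = W4)]
    out[, , ch] <- acc / 16
  }
  raster_image(round(out), img$colour_space, source_path = img$source_path)
}

# ---- colour transforms (vectorised, double precision, rounded at the end) --

.rgb_to_hsv <- function(px) {
  n <- prod(dim(px)[1:2])
  hsv <- grDevices::rgb2hsv(t(matrix(px, n, 3L)), maxColorValue = 255)
  h <- round(hsv[1L, ] * 180) %% 180          # half-degree hue, 0..179
  s <- round(hsv[2L, ] * 255)
  v <- round(hsv[3L, ] * 255)
  array(c(h, s, v), dim(px))
}

.hsv_to_rgb <- function(px) {
  n <- prod(dim(px)[1:2])
  h <- as.numeric(px[, , 1L]) * 2              # degrees 0..358
  s <- as.numeric(px[, , 2L]) / 255
  v <- as.numeric(px[, , 3L]) / 255
  c_ <- v * s
  hp <- h / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  r <- g <- b <- numeric(n)
  i <- floor(hp) %% 6
  sel <- i == 0; r[sel] <- c_[sel]; g[sel] <- x[sel]
  sel <- i == 1; r[sel] <- x[sel];  g[sel] <- c_[sel]
  sel <- i == 2; g[sel] <- c_[sel]; b[sel] <- x[sel]
  sel <- i == 3; g[sel] <- x[sel];  b[sel] <- c_[sel]
  sel <- i == 4; r[sel] <- x[sel];  b[sel] <- c_[sel]
  sel <- i == 5; r[sel] <- c_[sel]; b[sel] <- x[sel]
  out <- array(c(r + m, g + m, b + m), dim(px)) * 255
  pmax(pmin(round(out), 255), 0)
}

# BT.601 full-range luma/chroma with OpenCV-style scale factors; values
# outside 0..255 (extreme saturated colours) are clipped.
.rgb_to_yuv <- function(px) {
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  u <- 0.492 * (b - y) + 128
  v <- 0.877 * (r - y) + 128
  out <- array(c(y, u, v), dim(px))
  pmax(pmin(round(out), 255), 0)
}

.yuv_to_rgb <- function(px) {
  y <- px[, , 1L]; u <- px[, , 2L] - 128; v <- px[, , 3L] - 128
  r <- y + v / 0.877
  b <- y + u / 0.492
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(c(r, g, b), dim(px))
  pmax(pmin(round(out), 255), 0)
}

#' Convert a raster between colour spaces
#'
#' Standard 8-bit RGB/HSV/YUV transforms. Hue is on the 0--179 half-degree
#' scale; YUV is BT.601 full range. HSV<->YUV conversions route through RGB.
#' Conversions are deterministic for fixed input bytes. Because channels are
#' re-quantised to 8 bits, round trips are exact only up to rounding:
#' RGB->HSV->RGB is within 1 per channel for chroma up to ~60 (hue
#' quantisation dominates for strongly saturated colours), and RGB->YUV->RGB
#' is within 1 per channel for colours whose chroma stays inside the 8-bit
#' YUV gamut.
#'
#' @param img a `raster_image`.
#' @param target target colour space, one of `"RGB"`, `"HSV"`, `"YUV"`.
#' @return A `raster_image` in the target space. Converting to the current
#'   space is a no-op with a warning.
#' @export
convert_colour <- function(img, target = c("RGB", "HSV", "YUV")) {
  stopifnot(inherits(img, "raster_image"))
  target <- match.arg(target)
  if (identical(img$colour_space, target)) {
    warning("image is already in ", target, "; returning unchanged")
    return(img)
  }
  px <- img$pixels
  if (img$colour_space != "RGB") {
    px <- switch(img$colour_space, HSV = .hsv_to_rgb(px), YUV = .yuv_to_rgb(px))
  }
  out <- switch(target, RGB = px, HSV = .rgb_to_hsv(px), YUV = .rgb_to_yuv(px))
  raster_image(out, target, source_path = img$source_path)
}
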