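test_that("PNG write/read round trip preserves pixel bytes", {
  img <- flat_rgb(16, 20)
  img$pixels[3:6, 4:9, 1] <- 250L
  path <- withr::local_tempfile(fileext = ".png")
  save_image(img, path)
  back <- load_image(path)
  expect_equal(back$colour_space, "RGB")
  expect_identical(dim(back$pixels), dim(img$pixels))
  expect_identical(back$pixels, img$pixels)
})

test_that("grayscale images are promoted to three equal channels", {
  path <- withr::local_tempfile(fileext = ".png")
  g <- matrix(runif(20 * 12), 12, 20)      # EBImage layout: (x, y)
  EBImage::writeImage(EBImage::Image(g), path)
  img <- load_image(path)
  expect_identical(dim(img$pixels)[3], 3L)
  expect_identical(img$pixels[, , 1], img$pixels[, , 2])
  expect_identical(img$pixels[, , 1], img$pixels[, , 3])
})

test_that("unreadable files raise an I/O error naming the path", {
  path <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(c(137, 80, 78, 71, 1, 2, 3)), path)   # truncated header
  expect_error(load_image(path), "cannot read image")
  expect_error(load_image("/nonexistent/file.png"), "no such file")
})

test_that("resize_quarter floors dimensions and preserves colour space", {
  img <- flat_rgb(400, 400)
  out <- resize_quarter(img)
  expect_identical(dim(out$pixels)[1:2], c(100L, 100L))
  expect_identical(out$colour_space, "RGB")

  odd <- flat_rgb(1302, 1303)
  expect_identical(dim(resize_quarter(odd)$pixels)[1:2], c(325L, 325L))

  expect_error(resize_quarter(flat_rgb(30, 400)), "too small")
})

test_that("resize_quarter averages 4x4 blocks (area interpolation)", {
  px <- array(0, c(32, 32, 3))
  px[1:4, 1:4, ] <- 100          # one full block
  px[1:2, 5:8, ] <- 100          # half a block vertically
  img <- raster_image(px, "RGB")
  out <- resize_quarter(img)
  expect_equal(out$pixels[1, 1, 1], 100L)
  expect_equal(out$pixels[1, 2, 1], 50L)
  expect_equal(out$pixels[5, 5, 1], 0L)
})

test_that("repeated resize composes like iterated floor division", {
  img <- flat_rgb(523, 217)
  out <- resize_quarter(resize_quarter(img))
  expect_identical(dim(out$pixels)[1:2],
                   c((523L %/% 4L) %/% 4L, (217L %/% 4L) %/% 4L))
})

test_that("colour conversions hit the standard anchor points", {
  blue <- flat_rgb(8, 8, c(0, 0, 255))
  hsv <- convert_colour(blue, "HSV")
  expect_equal(hsv$pixels[1, 1, 1], 120L)    # blue hue, 0-179 scale
  expect_equal(hsv$pixels[1, 1, 2], 255L)

  gray <- flat_rgb(8, 8, c(128, 128, 128))
  hg <- convert_colour(gray, "HSV")
  expect_equal(hg$pixels[1, 1, 2], 0L)       # achromatic: saturation 0
  expect_equal(hg$pixels[1, 1, 3], 128L)

  yuv <- convert_colour(gray, "YUV")
  expect_equal(yuv$pixels[1, 1, 1], 128L)    # gray luma
  expect_equal(yuv$pixels[1, 1, 2], 128L)    # zero chroma offset
})

test_that("YUV round trip is within 1 per channel for in-gamut colours", {
  set.seed(1)
  n <- 500
  rgb <- cbind(sample(0:255, n, TRUE), sample(0:255, n, TRUE),
               sample(0:255, n, TRUE))
  y <- 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3]
  u <- 0.492 * (rgb[, 3] - y) + 128
  v <- 0.877 * (rgb[, 1] - y) + 128
  ok <- u >= 1 & u <= 254 & v >= 1 & v <= 254
  rgb <- rgb[ok, ][1:64, ]
  img <- raster_image(array(rgb, c(8, 8, 3)), "RGB")
  back <- convert_colour(convert_colour(img, "YUV"), "RGB")
  expect_lte(max(abs(back$pixels - img$pixels)), 1)
})

test_that("HSV round trip is within 1 per channel at moderate chroma", {
  set.seed(2)
  base <- sample(0:195, 64, TRUE)                  # shared per pixel
  off <- matrix(sample(0:60, 64 * 3, TRUE), 64, 3) # chroma <= 60
  img <- raster_image(array(base + off, c(8, 8, 3)), "RGB")
  back <- convert_colour(convert_colour(img, "HSV"), "RGB")
  expect_lte(max(abs(back$pixels - img$pixels)), 1)
})

test_that("conversions are deterministic and same-space is a warned no-op", {
  img <- flat_rgb(8, 8, c(12, 200, 99))
  a <- convert_colour(img, "HSV")
  b <- convert_colour(img, "HSV")
  expect_identical(a$pixels, b$pixels)
  expect_warning(out <- convert_colour(img, "RGB"), "already")
  expect_identical(out$pixels, img$pixels)
})

test_that("raster_image validates its contract", {
  expect_error(raster_image(array(0, c(4, 4, 3)), "RGB"), "at least 8 x 8")
  expect_error(raster_image(array(-1, c(8, 8, 3)), "RGB"), "0..255")
  expect_error(raster_image(matrix(0, 8, 8), "RGB"), "H x W x 3")
})
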