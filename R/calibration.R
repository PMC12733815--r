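#' Detect the circular reference object
#'
#' Circle Hough transform on the luma (Y) channel of a YUV image. A Sobel
#' gradient magnitude map is thresholded into an edge mask; for every
#' candidate radius a ring kernel (1 px wide, normalised to unit mass) is
#' correlated with the edge mask via FFT convolution, so the accumulator
#' value at a position is the fraction of that ring covered by edge pixels.
#' The global accumulator maximum across positions and radii wins; ties go
#' to the smaller radius, then the smaller centre in raster order
#' (deterministic).
#'
#' @param img a `raster_image` in YUV.
#' @param radius_range integer `c(min_px, max_px)` candidate radii; must fit
#'   inside the image.
#' @param accumulator_threshold minimum ring coverage (0--1) for a
#'   detection; below it the reference is declared not found. Default 0.5.
#' @param edge_threshold edge-mask cut as a fraction of the maximum gradient
#'   magnitude. Default 0.25.
#' @return List with `centre` (0-based `c(y, x)`), `radius_px` and `score`.
#' @export
detect_cap <- function(img, radius_range, accumulator_threshold = 0.5,
                       edge_threshold = 0.25) {
  stopifnot(inherits(img, "raster_image"))
  if (img$colour_space != "YUV")
    stop("detect_cap() needs a YUV image; convert first")
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  radii <- seq(as.integer(radius_range[1]), as.integer(radius_range[2]))
  stopifnot(length(radii) >= 1L, radii[1] >= 3L,
            2L * max(radii) + 3L <= min(H, W))

  ych <- img$pixels[, , 1L] / 255
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  gx <- EBImage::filter2(ych, kx, boundary = "replicate")
  gy <- EBImage::filter2(ych, t(kx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  # relative cut plus an absolute floor (0.1 on unit-luma Sobel units) so a
  # featureless image yields no edges rather than amplified noise
  edge <- (mag > max(edge_threshold * max(mag), 0.1)) * 1

  best <- list(score = -Inf, r = NA_integer_, y = NA_integer_,
               x = NA_integer_)
  for (r in radii) {
    sz <- 2L * r + 3L
    cc <- seq_len(sz) - (r + 2L)
    d <- sqrt(outer(cc^2, cc^2, "+"))
    ring <- (abs(d - r) <= 0.5) * 1
    ring <- ring / sum(ring)
    acc <- EBImage::filter2(edge, ring, boundary = "replicate")
    i <- which.max(acc)              # first maximum in column-major order
    if (acc[i] > best$score + 1e-12) {
      best <- list(score = acc[i], r = r,
                   y = (i - 1L) %% H, x = (i - 1L) %/% H)
    }
  }
  if (!is.finite(best$score) || best$score < accumulator_threshold)
    stop("reference object not found: best ring coverage ",
         sprintf("%.2f", max(best$score, 0)), " below threshold ",
         accumulator_threshold, "; check the radius range (",
         radius_range[1], "-", radius_range[2],
         " px) and that the cap is fully visible")

  # sub-pixel refinement: the integer-radius accumulator quantises the
  # scale, so re-estimate centre and radius from the edge pixels in a
  # 1.5-px annulus around the detected circle, weighted by gradient
  # magnitude (the Sobel ridge straddles the true edge)
  ei <- which(edge == 1)
  ey <- (ei - 1L) %% H; ex <- (ei - 1L) %/% H
  wt <- mag[ei]
  cy <- best$y; cx <- best$x; r <- best$r
  for (it in 1:3) {
    d <- sqrt((ey - cy)^2 + (ex - cx)^2)
    sel <- abs(d - r) <= 1.5
    if (sum(sel) < 5L) break
    w <- wt[sel]
    cy <- sum(ey[sel] * w) / sum(w); cx <- sum(ex[sel] * w) / sum(w)
    r <- sum(sqrt((ey[sel] - cy)^2 + (ex[sel] - cx)^2) * w) / sum(w)
  }
  list(centre = c(y = cy, x = cx), radius_px = r, score = best$score)
}

#' Build a pixel-to-millimetre calibration from the reference circle
#'
#' @param circle detection from [detect_cap()] (or any list with
#'   `centre` and `radius_px`).
#' @param known_diameter_mm physical diameter of the reference object. This
#'   has no default: it must be supplied for every image set.
#' @return A `scale_calibration` with `mm_per_px = known_diameter_mm /
#'   (2 * radius_px)`.
#' @export
make_calibration <- function(circle, known_diameter_mm) {
  if (missing(known_diameter_mm))
    stop("known_diameter_mm is required: supply the physical diameter ",
         "of the reference object (no default is assumed)")
  stopifnot(known_diameter_mm > 0, circle$radius_px > 0)
  structure(list(centre = circle$centre, radius_px = circle$radius_px,
                 known_diameter_mm = known_diameter_mm,
                 mm_per_px = known_diameter_mm / (2 * circle$radius_px)),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf(
    "<scale_calibration r=%g px, d=%g mm, %.4f mm/px>\n",
    x$radius_px, x$known_diameter_mm, x$mm_per_px))
  invisible(x)
}

#' Measure one pixel group in millimetres
#'
#' The group's binarised membership mask gives its contour (member pixels
#' adjacent to a non-member); the axis-aligned bounding box gives length
#' (longest side) and width (shortest side), scaled to millimetres.
#'
#' @param group a `pixel_group`.
#' @param cal a `scale_calibration`.
#' @return List with `length_mm`, `width_mm` (`length_mm >= width_mm`) and
#'   `contour` (m x 2 matrix of 0-based `(y, x)` boundary pixels).
#' @export
measure_group <- function(group, cal) {
  stopifnot(inherits(group, "pixel_group"), inherits(cal, "scale_calibration"))
  if (group$n_pixels == 0L) stop("cannot measure an empty group")
  bb <- group$bbox
  h <- bb["p2Y"] - bb["p1Y"] + 1L
  w <- bb["p2X"] - bb["p1X"] + 1L
  # membership mask over the (padded) bbox window for contour extraction
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[cbind(group$pixels[, "y"] - bb["p1Y"] + 2L,
          group$pixels[, "x"] - bb["p1X"] + 2L)] <- TRUE
  interior <- m[2:(h + 1), 2:(w + 1)] &
    m[1:h, 2:(w + 1)] & m[3:(h + 2), 2:(w + 1)] &
    m[2:(h + 1), 1:w] & m[2:(h + 1), 3:(w + 2)] &
    m[1:h, 1:w] & m[1:h, 3:(w + 2)] &
    m[3:(h + 2), 1:w] & m[3:(h + 2), 3:(w + 2)]
  edge <- which(m[2:(h + 1), 2:(w + 1)] & !interior, arr.ind = TRUE)
  contour <- cbind(y = edge[, 1] - 1L + bb["p1Y"],
                   x = edge[, 2] - 1L + bb["p1X"])
  list(length_mm = max(h, w) * cal$mm_per_px,
       width_mm = min(h, w) * cal$mm_per_px,
       contour = contour)
}

#' Measure a list of groups
#'
#' @param groups list of `pixel_group`.
#' @param cal a `scale_calibration`.
#' @return A data.frame with one row per group: `id`, `length_mm`,
#'   `width_mm` and the 0-based bounding-box corners `p1X`, `p1Y`, `p2X`,
#'   `p2Y` (upper-left / lower-right).
#' @export
measure_groups <- function(groups, cal) {
  if (length(groups) == 0L)
    return(data.frame(id = integer(), length_mm = numeric(),
                      width_mm = numeric(), p1X = integer(), p1Y = integer(),
                      p2X = integer(), p2Y = integer()))
  rows <- lapply(groups, function(g) {
    mm <- measure_group(g, cal)
    data.frame(id = g$id, length_mm = mm$length_mm, width_mm = mm$width_mm,
               p1X = g$bbox[["p1X"]], p1Y = g$bbox[["p1Y"]],
               p2X = g$bbox[["p2X"]], p2Y = g$bbox[["p2Y"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
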