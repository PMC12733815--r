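#' Size-share features for the group classifier
#'
#' For every group of one image: `pct_mean` is the group's pixel count as a
#' fraction of the image's pixels; `pct_std` is the population standard
#' deviation of `pct_mean` across all groups of the image (the same value is
#' attached to every row -- it is an image-level dispersion feature);
#' `pct_pixels` is the group's share of all grouped pixels, so it sums to 1
#' over the image.
#'
#' @param groups list of `pixel_group` from one image.
#' @param image_pixels total pixel count (`H * W`) of the segmented image.
#' @return A data.frame with one row per group: `id`, `pct_mean`, `pct_std`,
#'   `pct_pixels`. Empty input gives a zero-row frame.
#' @export
ann_features <- function(groups, image_pixels) {
  stopifnot(image_pixels > 0)
  if (length(groups) == 0L)
    return(data.frame(id = integer(), pct_mean = numeric(),
                      pct_std = numeric(), pct_pixels = numeric()))
  n <- vapply(groups, `[[`, integer(1), "n_pixels")
  id <- vapply(groups, `[[`, integer(1), "id")
  pm <- n / image_pixels
  data.frame(id = id,
             pct_mean = pm,
             pct_std = sqrt(mean((pm - mean(pm))^2)),
             pct_pixels = n / sum(n))
}

#' Geometry features for the refinement classifier
#'
#' Scales each measured group's length, width and bounding-box corners by
#' half the image size and multiplies by 1000. "Image size" is taken as
#' `max(H, W)` so the features are comparable across resolutions; lengths
#' enter in millimetres and are divided by the half-size expressed in
#' millimetres (`max(H, W) / 2 * mm_per_px`), which makes `pct_large`
#' identical to `length_px / half_size_px * 1000`. Corner coordinates
#' (0-based pixels) are scaled by the same rule.
#'
#' @param measures data.frame with columns `id`, `length_mm`, `width_mm`,
#'   `p1X`, `p1Y`, `p2X`, `p2Y` (as produced by [measure_groups()]).
#' @param image_H,image_W dimensions (pixels) of the measured image.
#' @param mm_per_px millimetres per pixel used for the measurements.
#' @return A data.frame with `id`, `pct_large`, `pct_width`, `pct_p1X`,
#'   `pct_p1Y`, `pct_p2X`, `pct_p2Y`.
#' @export
rf_features <- function(measures, image_H, image_W, mm_per_px) {
  stopifnot(image_H > 0, image_W > 0, mm_per_px > 0)
  half_px <- max(image_H, image_W) / 2
  half_mm <- half_px * mm_per_px
  data.frame(id = measures$id,
             pct_large = measures$length_mm / half_mm * 1000,
             pct_width = measures$width_mm / half_mm * 1000,
             pct_p1X = measures$p1X / half_px * 1000,
             pct_p1Y = measures$p1Y / half_px * 1000,
             pct_p2X = measures$p2X / half_px * 1000,
             pct_p2Y = measures$p2Y / half_px * 1000)
}

#' Write a size-share feature table as CSV
#'
#' Column order: `no,mean,std,pixels,class`.
#'
#' @param features data.frame from [ann_features()], with a `class` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ann_csv <- function(features, path) {
  stopifnot(all(c("pct_mean", "pct_std", "pct_pixels", "class") %in%
                  names(features)))
  out <- data.frame(no = seq_len(nrow(features)),
                    mean = features$pct_mean, std = features$pct_std,
                    pixels = features$pct_pixels, class = features$class)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a geometry feature table as CSV
#'
#' Column order: `no,large,width,p1x,p1y,p2x,p2y,class`.
#'
#' @param features data.frame from [rf_features()], with a `class` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rf_csv <- function(features, path) {
  stopifnot(all(c("pct_large", "pct_width", "pct_p1X", "pct_p1Y",
                  "pct_p2X", "pct_p2Y", "class") %in% names(features)))
  out <- data.frame(no = seq_len(nrow(features)),
                    large = features$pct_large, width = features$pct_width,
                    p1x = features$pct_p1X, p1y = features$pct_p1Y,
                    p2x = features$pct_p2X, p2y = features$pct_p2Y,
                    class = features$class)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
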