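#' Policy for the hue-adaptive clustering radius
#'
#' The clustering radius (epsilon) is derived from each image's average hue
#' rather than fixed, so that scenes with globally shifted hue (lighting,
#' white balance) keep a comparable neighbourhood criterion. The policy is
#' linear with clamping: `epsilon = clamp(scale_factor * mean(hue), floor,
#' cap)`, in hue units on the 0--179 scale.
#'
#' The default `scale_factor` was calibrated once on the synthetic scenes
#' shipped with the package (blue background near hue 115 gives epsilon
#' around 12, comfortably above intra-object hue texture and below the
#' object/background hue gap).
#'
#' @param scale_factor positive multiplier applied to the mean hue.
#' @param floor,cap clamping bounds (hue units); `floor <= cap`.
#' @return An `epsilon_policy` object.
#' @export
epsilon_policy <- function(scale_factor = 0.12, floor = 8, cap = 20) {
  stopifnot(scale_factor > 0, floor <= cap)
  structure(list(scale_factor = scale_factor, floor = floor, cap = cap),
            class = "epsilon_policy")
}

#' Compute the clustering radius from an image's average hue
#'
#' @param img a `raster_image` in HSV.
#' @param policy an [epsilon_policy()].
#' @return Positive scalar epsilon in hue units (0--179 scale).
#' @export
compute_epsilon <- function(img, policy = epsilon_policy()) {
  stopifnot(inherits(img, "raster_image"), inherits(policy, "epsilon_policy"))
  if (img$colour_space != "HSV")
    stop("compute_epsilon() needs an HSV image; convert first")
  h <- img$pixels[, , 1L]
  if (length(unique(as.integer(h))) == 1L)
    message("degenerate image: constant hue ", h[1L],
            "; epsilon falls back to the clamped policy value")
  min(max(policy$scale_factor * mean(h), policy$floor), policy$cap)
}

#' Hue-based density clustering of image pixels (modified DBSCAN)
#'
#' Clusters pixels by circular hue distance with the neighbourhood of a
#' pixel fixed to its 8 adjacent pixels. A pixel with at least
#' `min_neighbors` of its 8 neighbours within hue distance `epsilon` is a
#' core pixel (label 2, the "centroid" role); a non-core pixel within
#' `epsilon` of an adjacent core pixel is a boundary pixel (label 1); all
#' remaining pixels, and every pixel within `edge_margin` of the image
#' border, are outliers (label -1). Connected cores together with their
#' boundary pixels form one group. Hue distance is circular:
#' `min(|dh|, hue_range - |dh|)`.
#'
#' Group ids are assigned in raster-scan order of each group's first core
#' pixel; a boundary pixel adjacent to cores of several groups joins the
#' first in fixed neighbour order (top-left to bottom-right) -- both
#' deterministic tie-breaks.
#'
#' @param img a `raster_image` in HSV.
#' @param epsilon positive clustering radius in hue units.
#' @param min_neighbors required close neighbours for a core pixel (1--8).
#'   The default 8 is the strictest reading of an 8-neighbour density test.
#' @param edge_margin border width (pixels, >= 1) excluded from clustering.
#' @param hue_range circumference of the hue wheel (180 for 0--179 hues).
#' @return A `pixel_label_map`: list with `labels` (H x W matrix over
#'   \{-1, 1, 2\}), `group_ids` (H x W matrix, -1 = none, else 0-based group
#'   index) and `n_groups`.
#' @export
modified_dbscan <- function(img, epsilon, min_neighbors = 8L,
                            edge_margin = 1L, hue_range = 180) {
  stopifnot(inherits(img, "raster_image"))
  if (img$colour_space != "HSV")
    stop("modified_dbscan() needs an HSV image; convert first")
  stopifnot(epsilon > 0, min_neighbors >= 1L, min_neighbors <= 8L,
            edge_margin >= 1L)
  hue <- img$pixels[, , 1L]
  storage.mode(hue) <- "double"
  res <- dbscan_hue_cpp(hue, epsilon, as.integer(min_neighbors),
                        as.integer(edge_margin), hue_range)
  structure(list(labels = res$labels, group_ids = res$group_ids,
                 n_groups = res$n_groups, dim = dim(hue)),
            class = "pixel_label_map")
}

#' @export
print.pixel_label_map <- function(x, ...) {
  cat(sprintf("<pixel_label_map %d x %d, %d groups>\n",
              x$dim[1], x$dim[2], x$n_groups))
  invisible(x)
}

#' Extract pixel groups from a label map
#'
#' One `pixel_group` per distinct group id, sorted by decreasing pixel count
#' (ties by id). Coordinates and bounding boxes are 0-based, `(y, x)`,
#' origin top-left; the bounding box `(p1Y, p1X, p2Y, p2X)` is inclusive and
#' tight.
#'
#' @param map a `pixel_label_map`.
#' @return List of `pixel_group` objects, each with fields `id`, `pixels`
#'   (n x 2 matrix of 0-based `(y, x)`), `bbox` (named vector `p1Y`, `p1X`,
#'   `p2Y`, `p2X`) and `n_pixels`.
#' @export
extract_groups <- function(map) {
  stopifnot(inherits(map, "pixel_label_map"))
  ids <- map$group_ids
  sel <- which(ids >= 0L)
  if (length(sel) == 0L) return(list())
  H <- nrow(ids)
  y <- (sel - 1L) %% H            # 0-based row
  x <- (sel - 1L) %/% H           # 0-based col
  by_id <- split(seq_along(sel), ids[sel])
  groups <- lapply(by_id, function(ii) {
    yy <- y[ii]; xx <- x[ii]
    structure(list(
      id = ids[sel[ii[1L]]],
      pixels = cbind(y = yy, x = xx),
      bbox = c(p1Y = min(yy), p1X = min(xx), p2Y = max(yy), p2X = max(xx)),
      n_pixels = length(ii)), class = "pixel_group")
  })
  n <- vapply(groups, `[[`, integer(1), "n_pixels")
  id <- vapply(groups, `[[`, integer(1), "id")
  unname(groups[order(-n, id)])
}

#' @export
print.pixel_group <- function(x, ...) {
  cat(sprintf("<pixel_group id=%d, %d px, bbox y[%d,%d] x[%d,%d]>\n",
              x$id, x$n_pixels, x$bbox["p1Y"], x$bbox["p2Y"],
              x$bbox["p1X"], x$bbox["p2X"]))
  invisible(x)
}

#' Discard background-sized groups
#'
#' Any group covering more than one tenth of the image's pixels is taken to
#' be background and removed before counting or measurement. The rule is
#' strictly "more than": a group of exactly `total_pixels / 10` is kept.
#'
#' @param groups list of `pixel_group`.
#' @param total_pixels `H * W` of the segmented image.
#' @return The retained groups, in input order.
#' @export
discard_background <- function(groups, total_pixels) {
  stopifnot(total_pixels > 0)
  n <- vapply(groups, `[[`, integer(1), "n_pixels")
  drop <- n > total_pixels / 10
  if (any(drop)) {
    ids <- vapply(groups[drop], `[[`, integer(1), "id")
    message("discarding ", sum(drop), " background group(s): id ",
            paste(ids, collapse = ", "), " (", paste(n[drop], collapse = ", "),
            " px > ", format(total_pixels / 10), ")")
  }
  groups[!drop]
}
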