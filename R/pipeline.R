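#' Pipeline configuration
#'
#' Bundles every tunable of the measurement pipeline. The physical diameter
#' of the reference object has no default and must always be supplied.
#'
#' @param reference_diameter_mm physical diameter of the reference cap (mm).
#' @param hough_radius_range integer `c(min, max)` candidate cap radii in
#'   analysis pixels (after any resize).
#' @param policy an [epsilon_policy()].
#' @param min_neighbors,edge_margin,hue_range see [modified_dbscan()].
#' @param resize if TRUE (default) the image is downsampled by four before
#'   segmentation, and all analysis (including cap detection, by default)
#'   happens at that scale so the mm-per-px calibration is internally
#'   consistent.
#' @param accumulator_threshold,edge_threshold see [detect_cap()].
#' @return A `pipeline_config` list. `analysis_scale` (4 when resizing,
#'   else 1) is derived.
#' @export
pipeline_config <- function(reference_diameter_mm, hough_radius_range,
                            policy = epsilon_policy(),
                            min_neighbors = 8L, edge_margin = 1L,
                            hue_range = 180, resize = TRUE,
                            accumulator_threshold = 0.5,
                            edge_threshold = 0.25) {
  if (missing(reference_diameter_mm))
    stop("reference_diameter_mm is required (no default is assumed)")
  stopifnot(reference_diameter_mm > 0, length(hough_radius_range) == 2L)
  structure(list(reference_diameter_mm = reference_diameter_mm,
                 hough_radius_range = as.integer(hough_radius_range),
                 policy = policy, min_neighbors = min_neighbors,
                 edge_margin = edge_margin, hue_range = hue_range,
                 resize = resize, analysis_scale = if (resize) 4L else 1L,
                 accumulator_threshold = accumulator_threshold,
                 edge_threshold = edge_threshold),
            class = "pipeline_config")
}

#' Pipeline configuration matched to a synthetic scene spec
#'
#' Derives the reference diameter and a cap-radius search window from the
#' scene spec, at the analysis resolution implied by `resize` and `scale`.
#'
#' @param spec a [scene_spec()].
#' @param scale the resolution multiplier the scene will be rendered at.
#' @param resize whether the pipeline will downsample by four.
#' @param ... passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
scene_config <- function(spec, scale = 1, resize = TRUE, ...) {
  mmpp <- spec$mm_per_px / scale * (if (resize) 4 else 1)
  r_px <- spec$cap_diameter_mm / 2 / mmpp
  pipeline_config(reference_diameter_mm = spec$cap_diameter_mm,
                  hough_radius_range = c(max(3L, floor(r_px * 0.6)),
                                         ceiling(r_px * 1.4)),
                  resize = resize, ...)
}

#' Segment an RGB image into candidate pixel groups
#'
#' Runs the front half of the pipeline: optional resize by four, conversion
#' to HSV, hue-adaptive epsilon, density clustering, group extraction and
#' the background-discard rule.
#'
#' @param img a `raster_image` in RGB.
#' @param config a [pipeline_config()].
#' @return List with `groups` (post-discard), `discarded` (background
#'   groups), `map` (the `pixel_label_map`), `epsilon`, `hsv` and
#'   `rgb_small` (the analysed RGB raster).
#' @export
segment_image <- function(img, config) {
  stopifnot(inherits(img, "raster_image"), inherits(config, "pipeline_config"))
  if (img$colour_space != "RGB") stop("segment_image() expects an RGB image")
  small <- if (config$resize) resize_quarter(img) else img
  hsv <- convert_colour(small, "HSV")
  eps <- compute_epsilon(hsv, config$policy)
  map <- modified_dbscan(hsv, eps, config$min_neighbors, config$edge_margin,
                         config$hue_range)
  groups <- extract_groups(map)
  d <- dim(hsv$pixels)
  kept <- suppressMessages(discard_background(groups, d[1] * d[2]))
  kept_ids <- vapply(kept, `[[`, integer(1), "id")
  all_ids <- vapply(groups, `[[`, integer(1), "id")
  list(groups = kept, discarded = groups[!(all_ids %in% kept_ids)],
       map = map, epsilon = eps, hsv = hsv, rgb_small = small)
}

#' Run the full counting-and-measurement pipeline on one image
#'
#' Segmentation, MLP noise filtering, reference-circle calibration,
#' bounding-box measurement, random-forest refinement (noise drop and
#' fused-pair splitting) and per-image summary.
#'
#' @param img a `raster_image` in RGB.
#' @param ann_model trained [train_ann()] model.
#' @param rf_model trained [train_rf()] model.
#' @param config a [pipeline_config()].
#' @param image_id identifier for the report.
#' @return List with `report` (an `image_report`), `measurements` (the
#'   refined per-oyster rows), `calibration`, `kept`, `removed`,
#'   `ann_class`, `rf_class`, `measured` (pre-refinement rows) and
#'   `segmentation`.
#' @export
process_image <- function(img, ann_model, rf_model, config,
                          image_id = NA_character_) {
  seg <- segment_image(img, config)
  d <- dim(seg$hsv$pixels)

  feats <- ann_features(seg$groups, d[1] * d[2])
  filt <- filter_groups(ann_model, seg$groups, feats)

  yuv <- convert_colour(seg$rgb_small, "YUV")
  circle <- detect_cap(yuv, config$hough_radius_range,
                       config$accumulator_threshold, config$edge_threshold)
  cal <- make_calibration(circle, config$reference_diameter_mm)

  meas <- measure_groups(filt$kept, cal)
  rfeat <- rf_features(meas, d[1], d[2], cal$mm_per_px)
  rf_class <- if (nrow(meas)) predict(rf_model, rfeat) else integer()
  final <- refine(rf_model, meas, rfeat)
  list(report = summarize_image(final, image_id),
       measurements = final, calibration = cal,
       kept = filt$kept, removed = filt$removed, ann_class = filt$class,
       rf_class = rf_class, measured = meas, segmentation = seg)
}

#' Train the MLP filter and refinement forest from synthetic scenes
#'
#' Generates labelled feature tables from the given scenes and trains both
#' classifiers. The forest keeps its fixed seed of 42 (part of the method);
#' `seed` drives the MLP initialisation.
#'
#' @param specs list of `scene_spec` with seeds.
#' @param config a [pipeline_config()]; defaults to the first spec's
#'   [scene_config()].
#' @param seed seed for MLP training.
#' @return List with `ann`, `rf` (the trained models) and `training` (the
#'   labelled tables).
#' @export
train_models <- function(specs, config = scene_config(specs[[1]]),
                         seed = 1L) {
  sets <- generate_training_sets(specs, config)
  ann <- train_ann(sets$ann, sets$ann$class, seed = seed)
  rf <- train_rf(sets$rf, sets$rf$class, seed = 42L)
  list(ann = ann, rf = rf, training = sets)
}

#' Write per-oyster measurements as CSV
#'
#' @param measurements refined measurement rows ([refine()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate an image with classification outcomes
#'
#' Paints group contours onto the analysed RGB raster: kept single oysters
#' blue, fused pairs green, removed groups black.
#'
#' @param result output of [process_image()].
#' @return A `raster_image` (RGB) with contours painted.
#' @export
annotate_result <- function(result) {
  img <- result$segmentation$rgb_small
  px <- img$pixels
  paint <- function(groups, colour) {
    for (g in groups) {
      mm <- measure_group(g, result$calibration)
      idx <- cbind(mm$contour[, "y"] + 1L, mm$contour[, "x"] + 1L)
      for (ch in 1:3) px[cbind(idx, ch)] <<- colour[ch]
    }
  }
  paint(result$removed, c(0L, 0L, 0L))
  if (length(result$kept)) {
    paint(result$kept[result$rf_class == 0L], c(0L, 0L, 0L))
    paint(result$kept[result$rf_class == 1L], c(0L, 0L, 255L))
    paint(result$kept[result$rf_class == 2L], c(0L, 255L, 0L))
  }
  raster_image(px, "RGB")
}
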