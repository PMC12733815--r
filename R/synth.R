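#' Specification of a synthetic oyster scene
#'
#' Describes the study conditions the generator emulates: oysters spread
#' without touching on a uniform blue foam background, photographed
#' top-down, with a soda cap of known diameter in frame as the scale
#' reference. Oysters are hue-banded ellipses with truncated-Gaussian hue
#' texture; shadows are small darker off-blue blobs offset toward the lower
#' right of their oyster; debris specks are small hue-distinct discs. All
#' geometry is sampled in millimetres, so the same scene can be rendered at
#' any resolution.
#'
#' The default hue bands (background 115, shadows 95, oysters 12--24, cap
#' 150, debris 55) are pairwise separated by far more than the clustering
#' radius, while the hue jitter is truncated at `jitter_trunc` standard
#' deviations so intra-object neighbour hue distances stay strictly below
#' it: scenes are hue-separable by construction.
#'
#' @param image_size rendered image side in pixels (square).
#' @param mm_per_px millimetres per rendered pixel.
#' @param background_hsv background hue/saturation/value (H 0--179).
#' @param background_hue_sd background hue jitter sd (hue units).
#' @param n_oysters number of oysters (fused-pair members count as 2).
#' @param length_range_mm shell length (major axis) range.
#' @param width_ratio_range width/length ratio range.
#' @param oyster_hue_range hue band the per-oyster base hue is drawn from.
#' @param oyster_hue_sd within-shell hue texture sd.
#' @param oyster_sv saturation and value of oyster pixels.
#' @param orientation_sd_deg sd of the orientation jitter around the nearest
#'   image axis (oysters are laid out roughly axis-aligned, matching the
#'   axis-aligned bounding-box measurement primitive).
#' @param shadow_prob probability an oyster casts a visible shadow blob.
#' @param shadow_scale shadow axes as a fraction of the oyster's.
#' @param shadow_hsv shadow hue/saturation/value.
#' @param n_noise number of debris specks.
#' @param noise_radius_mm radius range of debris specks.
#' @param noise_hsv debris hue/saturation/value.
#' @param cap_diameter_mm physical diameter of the reference cap.
#' @param cap_hsv cap hue/saturation/value.
#' @param fused_prob per-candidate-pair probability that two oysters are
#'   fused; the number of fused pairs is binomial with `floor(n_oysters/2)`
#'   trials.
#' @param fused_offset_range centre separation of a fused pair as a
#'   fraction of the sum of their semi-major axes (along the shared axis).
#' @param min_gap_mm minimum clearance between placed objects.
#' @param jitter_trunc truncation of hue jitter, in standard deviations.
#' @param seed default seed used by [generate_scene()].
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(image_size = 1024L, mm_per_px = 0.5,
                       background_hsv = c(115, 180, 200),
                       background_hue_sd = 1.2,
                       n_oysters = 12L,
                       length_range_mm = c(60, 110),
                       width_ratio_range = c(0.45, 0.62),
                       oyster_hue_range = c(12, 24), oyster_hue_sd = 1.5,
                       oyster_sv = c(160, 170),
                       orientation_sd_deg = 3,
                       shadow_prob = 0.3, shadow_scale = 0.4,
                       shadow_hsv = c(95, 120, 90),
                       n_noise = 5L, noise_radius_mm = c(3, 5),
                       noise_hsv = c(55, 140, 150),
                       cap_diameter_mm = 30, cap_hsv = c(150, 60, 220),
                       fused_prob = 0.25, fused_offset_range = c(0.7, 0.9),
                       min_gap_mm = 6, jitter_trunc = 2.5,
                       seed = NULL) {
  spec <- as.list(environment())
  stopifnot(image_size >= 64L, mm_per_px > 0, n_oysters >= 0L,
            n_noise >= 0L, cap_diameter_mm > 0,
            length_range_mm[1] <= length_range_mm[2],
            shadow_prob >= 0, shadow_prob <= 1,
            fused_prob >= 0, fused_prob <= 1)
  # hue bands must be separated well beyond the truncated jitter
  bands <- c(background_hsv[1], oyster_hue_range, shadow_hsv[1],
             noise_hsv[1], cap_hsv[1])
  worst_jitter <- jitter_trunc * max(background_hue_sd, oyster_hue_sd)
  gap <- min(abs(background_hsv[1] - c(mean(oyster_hue_range),
                                       shadow_hsv[1], noise_hsv[1],
                                       cap_hsv[1])))
  if (gap <= 2 * worst_jitter + 2)
    stop("hue bands are not separable: background hue too close to an ",
         "object band given the jitter settings")
  structure(spec, class = "scene_spec")
}

.trunc_norm <- function(n, sd, trunc) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -trunc * sd), trunc * sd)
}

# Sample scene geometry in millimetres. Consumes RNG; callers seed first.
# Sequential rejection packing can dead-end, so the whole layout is retried
# (fresh draws, same RNG stream) a bounded number of times before erroring.
.sample_layout <- function(spec) {
  for (attempt in seq_len(25L)) {
    out <- tryCatch(.sample_layout_once(spec), error = function(e) e)
    if (!inherits(out, "error")) return(out)
  }
  stop("could not place all scene objects without overlap in 1000 ",
       "attempts; reduce n_oysters or enlarge the image")
}

.sample_layout_once <- function(spec) {
  field <- spec$image_size * spec$mm_per_px
  placed <- list()    # each: cx, cy, eff_r (clearance disc)
  # place an anchor point for a set of clearance discs given as offsets
  # (ox, oy, r) from the anchor; returns the anchor position
  place <- function(ox = 0, oy = 0, r) {
    bound <- max(sqrt(ox^2 + oy^2) + r)
    for (i in seq_len(1000L)) {
      cx <- stats::runif(1, bound, field - bound)
      cy <- stats::runif(1, bound, field - bound)
      ok <- TRUE
      for (p in placed) {
        if (any((cx + ox - p$cx)^2 + (cy + oy - p$cy)^2 <
                (r + p$eff_r + spec$min_gap_mm)^2)) { ok <- FALSE; break }
      }
      if (ok) return(c(cx, cy))
    }
    stop("layout dead end")
  }
  register <- function(cx, cy, eff_r)
    placed[[length(placed) + 1L]] <<- list(cx = cx, cy = cy, eff_r = eff_r)

  orient <- function() {
    base <- sample(c(0, 90), 1L)
    (base + .trunc_norm(1L, spec$orientation_sd_deg, 2)) %% 180
  }
  draw_axes <- function() {
    len <- stats::runif(1, spec$length_range_mm[1], spec$length_range_mm[2])
    wid <- len * stats::runif(1, spec$width_ratio_range[1],
                              spec$width_ratio_range[2])
    c(len, wid)
  }

  n_pairs <- if (spec$n_oysters >= 2L)
    stats::rbinom(1L, spec$n_oysters %/% 2L, spec$fused_prob) else 0L
  n_single <- spec$n_oysters - 2L * n_pairs

  blobs <- list(); next_blob <- 1L
  add_blob <- function(cx, cy, len, wid, th, hue, fused, pair) {
    blobs[[next_blob]] <<- data.frame(
      id = next_blob, cx_mm = cx, cy_mm = cy, length_mm = len,
      width_mm = wid, theta_deg = th, hue = hue, is_fused = fused,
      pair_id = pair)
    next_blob <<- next_blob + 1L
  }

  # fused pairs: shared axis, same hue band value, centres offset along it
  for (pp in seq_len(n_pairs)) {
    ax1 <- draw_axes(); ax2 <- draw_axes()
    th <- orient()
    f <- stats::runif(1, spec$fused_offset_range[1],
                      spec$fused_offset_range[2])
    a1 <- ax1[1] / 2; a2 <- ax2[1] / 2
    sep <- f * (a1 + a2)
    ux <- cos(th * pi / 180); uy <- sin(th * pi / 180)
    # one clearance disc per member (semi-major bounds ellipse + shadow)
    c0 <- place(ox = c(-ux, ux) * sep / 2, oy = c(-uy, uy) * sep / 2,
                r = c(a1, a2) * 1.1)
    hue <- stats::runif(1, spec$oyster_hue_range[1], spec$oyster_hue_range[2])
    add_blob(c0[1] - ux * sep / 2, c0[2] - uy * sep / 2, ax1[1], ax1[2],
             th, hue, TRUE, pp)
    add_blob(c0[1] + ux * sep / 2, c0[2] + uy * sep / 2, ax2[1], ax2[2],
             th, pmin(hue + stats::runif(1, -2, 2), spec$oyster_hue_range[2]),
             TRUE, pp)
    register(c0[1] - ux * sep / 2, c0[2] - uy * sep / 2, a1 * 1.1)
    register(c0[1] + ux * sep / 2, c0[2] + uy * sep / 2, a2 * 1.1)
  }
  # sample all singles, then place the largest first (packs more reliably)
  if (n_single > 0L) {
    singles <- lapply(seq_len(n_single), function(i)
      list(ax = draw_axes(), th = orient(),
           hue = stats::runif(1, spec$oyster_hue_range[1],
                              spec$oyster_hue_range[2])))
    ord <- order(-vapply(singles, function(s) s$ax[1], numeric(1)))
    for (s in singles[ord]) {
      # the semi-major disc bounds the ellipse and its offset shadow
      eff <- s$ax[1] / 2 * 1.1
      c0 <- place(r = eff)
      register(c0[1], c0[2], eff)
      add_blob(c0[1], c0[2], s$ax[1], s$ax[2], s$th, s$hue, FALSE,
               NA_integer_)
    }
  }
  blobs <- if (length(blobs)) do.call(rbind, blobs) else
    data.frame(id = integer(), cx_mm = numeric(), cy_mm = numeric(),
               length_mm = numeric(), width_mm = numeric(),
               theta_deg = numeric(), hue = numeric(), is_fused = logical(),
               pair_id = integer())

  # shadows hang off oysters toward the lower right
  shadows <- list()
  if (nrow(blobs)) {
    for (i in seq_len(nrow(blobs))) {
      if (stats::runif(1) > spec$shadow_prob) next
      b <- blobs[i, ]
      off <- b$width_mm / 2 * 0.8 + b$width_mm * spec$shadow_scale / 4
      shadows[[length(shadows) + 1L]] <- data.frame(
        blob_id = b$id,
        cx_mm = b$cx_mm + off / sqrt(2), cy_mm = b$cy_mm + off / sqrt(2),
        length_mm = b$length_mm * spec$shadow_scale,
        width_mm = b$width_mm * spec$shadow_scale,
        theta_deg = b$theta_deg)
    }
  }
  shadows <- if (length(shadows)) do.call(rbind, shadows) else
    data.frame(blob_id = integer(), cx_mm = numeric(), cy_mm = numeric(),
               length_mm = numeric(), width_mm = numeric(),
               theta_deg = numeric())

  cap_r <- spec$cap_diameter_mm / 2
  cc <- place(r = cap_r)
  register(cc[1], cc[2], cap_r)
  cap <- list(cx_mm = cc[1], cy_mm = cc[2], radius_mm = cap_r,
              diameter_mm = spec$cap_diameter_mm)

  noise <- list()
  for (k in seq_len(spec$n_noise)) {
    r <- stats::runif(1, spec$noise_radius_mm[1], spec$noise_radius_mm[2])
    c0 <- place(r = r)
    register(c0[1], c0[2], r)
    noise[[k]] <- data.frame(cx_mm = c0[1], cy_mm = c0[2], radius_mm = r)
  }
  noise <- if (length(noise)) do.call(rbind, noise) else
    data.frame(cx_mm = numeric(), cy_mm = numeric(), radius_mm = numeric())

  list(blobs = blobs, shadows = shadows, noise = noise, cap = cap,
       field_mm = field)
}

# paint a rotated ellipse into the H/S/V matrices held in env `img`
.paint_ellipse <- function(img, cx, cy, a, b, theta_deg, hsv, hue_sd,
                           trunc, mm_per_px) {
  S <- nrow(img$H)
  r_max <- max(a, b)
  rows <- max(1L, floor((cy - r_max) / mm_per_px)):
    min(S, ceiling((cy + r_max) / mm_per_px + 1))
  cols <- max(1L, floor((cx - r_max) / mm_per_px)):
    min(S, ceiling((cx + r_max) / mm_per_px + 1))
  ym <- (rows - 0.5) * mm_per_px - cy
  xm <- (cols - 0.5) * mm_per_px - cx
  ct <- cos(theta_deg * pi / 180); st <- sin(theta_deg * pi / 180)
  dx <- matrix(xm, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(ym, length(rows), length(cols))
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  mask <- (u / a)^2 + (v / b)^2 <= 1
  n <- sum(mask)
  if (n == 0L) return(invisible())
  sub <- img$H[rows, cols]
  sub[mask] <- hsv[1] + .trunc_norm(n, hue_sd, trunc)
  img$H[rows, cols] <- sub
  sub <- img$S[rows, cols]; sub[mask] <- hsv[2]; img$S[rows, cols] <- sub
  sub <- img$V[rows, cols]; sub[mask] <- hsv[3]; img$V[rows, cols] <- sub
  invisible()
}

#' Generate a synthetic oyster scene with ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns the RGB image
#' together with the full ground truth (per-blob geometry in mm and px,
#' shadow and debris inventories, the cap circle, and the mm-per-px used).
#' Deterministic for a fixed seed; the same spec and seed produce
#' byte-identical images. Because geometry is sampled in millimetres before
#' any rendering, `scale` re-renders the *same* scene at a multiple of the
#' base resolution (`scale = 2` doubles both image dimensions and halves
#' mm-per-px).
#'
#' @param spec a `scene_spec`.
#' @param seed integer seed; defaults to `spec$seed`.
#' @param scale resolution multiplier (default 1).
#' @return List with `image` (a `raster_image`, RGB) and `truth` (a
#'   `scene_truth` list).
#' @export
generate_scene <- function(spec, seed = spec$seed, scale = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(seed)) stop("a seed is required (spec$seed or `seed`)")
  set.seed(seed)
  layout <- .sample_layout(spec)

  mm_per_px <- spec$mm_per_px / scale
  S <- as.integer(round(spec$image_size * scale))
  img <- new.env()
  img$H <- matrix(spec$background_hsv[1] +
                    .trunc_norm(S * S, spec$background_hue_sd,
                                spec$jitter_trunc), S, S)
  img$S <- matrix(spec$background_hsv[2], S, S)
  img$V <- matrix(spec$background_hsv[3], S, S)

  sh <- layout$shadows
  for (i in seq_len(nrow(sh)))
    .paint_ellipse(img, sh$cx_mm[i], sh$cy_mm[i], sh$length_mm[i] / 2,
                   sh$width_mm[i] / 2, sh$theta_deg[i], spec$shadow_hsv,
                   spec$oyster_hue_sd, spec$jitter_trunc, mm_per_px)
  nz <- layout$noise
  for (i in seq_len(nrow(nz)))
    .paint_ellipse(img, nz$cx_mm[i], nz$cy_mm[i], nz$radius_mm[i],
                   nz$radius_mm[i], 0, spec$noise_hsv,
                   spec$oyster_hue_sd, spec$jitter_trunc, mm_per_px)
  bl <- layout$blobs
  for (i in seq_len(nrow(bl)))
    .paint_ellipse(img, bl$cx_mm[i], bl$cy_mm[i], bl$length_mm[i] / 2,
                   bl$width_mm[i] / 2, bl$theta_deg[i],
                   c(bl$hue[i], spec$oyster_sv), spec$oyster_hue_sd,
                   spec$jitter_trunc, mm_per_px)
  .paint_ellipse(img, layout$cap$cx_mm, layout$cap$cy_mm,
                 layout$cap$radius_mm, layout$cap$radius_mm, 0,
                 spec$cap_hsv, spec$background_hue_sd, spec$jitter_trunc,
                 mm_per_px)

  px <- array(c(round(img$H) %% 180,
                pmax(pmin(round(img$S), 255), 0),
                pmax(pmin(round(img$V), 255), 0)), c(S, S, 3L))
  hsv_img <- raster_image(px, "HSV")
  rgb_img <- suppressWarnings(convert_colour(hsv_img, "RGB"))

  bl$length_px <- bl$length_mm / mm_per_px
  bl$width_px <- bl$width_mm / mm_per_px
  truth <- structure(
    list(blobs = bl, shadows = layout$shadows, noise = layout$noise,
         cap = c(layout$cap, list(radius_px = layout$cap$radius_mm /
                                    mm_per_px)),
         field_mm = layout$field_mm, mm_per_px = mm_per_px,
         image_size = S, seed = seed, scale = scale),
    class = "scene_truth")
  list(image = rgb_img, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth %d oysters (%d fused), %d shadows, %d specks, cap r=%.1f mm, %g mm/px>\n",
    nrow(x$blobs), sum(x$blobs$is_fused), nrow(x$shadows), nrow(x$noise),
    x$cap$radius_mm, x$mm_per_px))
  invisible(x)
}

#' Auto-label segmented groups against scene ground truth
#'
#' A group whose pixels fall at least `overlap` (default 0.7) inside one
#' oyster ellipse is class 1; inside the union of a fused pair, class 2;
#' anything else (shadows, debris, the cap, background fragments) is class
#' 0. Ellipses are inflated by one analysis pixel to absorb boundary
#' rasterisation.
#'
#' @param groups list of `pixel_group` (analysis scale).
#' @param truth a `scene_truth`.
#' @param mm_per_px millimetres per analysis pixel (after any resize).
#' @param overlap membership threshold in (0, 1].
#' @return Integer vector of class labels, one per group.
#' @export
label_groups <- function(groups, truth, mm_per_px, overlap = 0.7) {
  if (length(groups) == 0L) return(integer())
  bl <- truth$blobs
  infl <- mm_per_px
  vapply(groups, function(g) {
    ym <- (g$pixels[, "y"] + 0.5) * mm_per_px
    xm <- (g$pixels[, "x"] + 0.5) * mm_per_px
    if (nrow(bl) == 0L) return(0L)
    fr <- vapply(seq_len(nrow(bl)), function(i) {
      ct <- cos(bl$theta_deg[i] * pi / 180)
      st <- sin(bl$theta_deg[i] * pi / 180)
      dx <- xm - bl$cx_mm[i]; dy <- ym - bl$cy_mm[i]
      u <- dx * ct + dy * st; v <- -dx * st + dy * ct
      a <- bl$length_mm[i] / 2 + infl; b <- bl$width_mm[i] / 2 + infl
      mean((u / a)^2 + (v / b)^2 <= 1)
    }, numeric(1))
    # fused pair first: a pair with one dominant member must still count 2
    if (any(bl$is_fused)) {
      for (pp in unique(bl$pair_id[bl$is_fused])) {
        fp <- fr[which(bl$pair_id == pp)]
        if (sum(fp) >= overlap && min(fp) >= 0.15) return(2L)
      }
    }
    if (max(fr) >= overlap) return(1L)
    0L
  }, integer(1))
}

#' Build labelled training tables from synthetic scenes
#'
#' Runs the segmentation and measurement stages on each scene, auto-labels
#' every surviving group by overlap with the ground truth, and returns both
#' feature tables (size-share features for the MLP filter, geometry
#' features for the refinement forest) with their class columns.
#'
#' @param specs list of `scene_spec`, each with a seed.
#' @param config a [pipeline_config()]; defaults to [scene_config()] of the
#'   first spec.
#' @return List with data.frames `ann` and `rf` (features + `class` +
#'   `scene`), and `n_scenes`.
#' @export
generate_training_sets <- function(specs, config = scene_config(specs[[1]])) {
  stopifnot(length(specs) >= 1L)
  ann_rows <- list(); rf_rows <- list()
  for (si in seq_along(specs)) {
    sc <- generate_scene(specs[[si]])
    seg <- segment_image(sc$image, config)
    if (length(seg$groups) == 0L) next
    d <- dim(seg$hsv$pixels)
    lab <- label_groups(seg$groups, sc$truth,
                        sc$truth$mm_per_px * config$analysis_scale)
    af <- ann_features(seg$groups, d[1] * d[2])
    af$class <- lab; af$scene <- si
    ann_rows[[si]] <- af

    yuv <- convert_colour(seg$rgb_small, "YUV")
    circle <- detect_cap(yuv, config$hough_radius_range,
                         config$accumulator_threshold)
    cal <- make_calibration(circle, config$reference_diameter_mm)
    meas <- measure_groups(seg$groups, cal)
    rf <- rf_features(meas, d[1], d[2], cal$mm_per_px)
    rf$class <- lab; rf$scene <- si
    rf_rows[[si]] <- rf
  }
  list(ann = do.call(rbind, ann_rows), rf = do.call(rbind, rf_rows),
       n_scenes = length(specs))
}
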