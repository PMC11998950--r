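#' Physical description of a centrifuged capillary tube
#'
#' Ground truth for the synthetic renderer: a four-zone tube (sealant plug,
#' packed red-cell column, buffy coat, plasma) after centrifugation. Defaults
#' describe a standard 75 mm x 1.1 mm bore microhaematocrit tube sealed with
#' a 10 mm clay plug and carrying a 25 mm finger-prick sample column. The
#' fill length matters for capture-geometry studies: parallax bias grows
#' roughly linearly with the physical length of the sample column (see the
#' methods vignette), so a longer venous-style fill shows proportionally
#' larger off-nadir bias.
#'
#' @param tube_length_mm Tube length (mm).
#' @param inner_diameter_mm Bore (mm).
#' @param plug_length_mm Sealant plug length (mm).
#' @param fill_length_mm Plug-top to plasma-top distance (mm);
#'   `plug_length_mm + fill_length_mm <= tube_length_mm`.
#' @param true_hct_pct Nominal hematocrit in percent, 0-100. The packed-cell
#'   column is `true_hct_pct/100 * fill_length_mm` long.
#' @param buffy_thickness_mm Buffy-coat band thickness (mm, may be 0). The
#'   band sits on top of the packed cells, inside the plasma fraction, so
#'   `true_hct_pct/100 * fill + buffy` must not exceed the fill length.
#' @param meniscus_depth_mm Signed plasma-top meniscus excursion (mm);
#'   positive = concave (edges climb above the axis), negative = convex.
#' @return A `tube_spec` object.
#' @export
tube_spec <- function(tube_length_mm = 75, inner_diameter_mm = 1.1,
                      plug_length_mm = 10, fill_length_mm = 25,
                      true_hct_pct = 42, buffy_thickness_mm = 0.5,
                      meniscus_depth_mm = 0.3) {
  for (nm in c("tube_length_mm", "inner_diameter_mm", "plug_length_mm",
               "fill_length_mm", "true_hct_pct", "buffy_thickness_mm",
               "meniscus_depth_mm")) {
    assign(nm, check_number(get(nm), nm))
  }
  if (min(tube_length_mm, inner_diameter_mm, plug_length_mm,
          fill_length_mm) <= 0 || buffy_thickness_mm < 0) {
    stop_microhct("Tube dimensions must be positive (buffy may be 0).",
                  "microhct_invalid_tube")
  }
  if (true_hct_pct < 0 || true_hct_pct > 100) {
    stop_microhct("`true_hct_pct` must be in [0, 100].", "microhct_invalid_tube")
  }
  if (plug_length_mm + fill_length_mm > tube_length_mm) {
    stop_microhct("Plug plus fill cannot exceed the tube length.",
                  "microhct_invalid_tube")
  }
  if (true_hct_pct / 100 * fill_length_mm + buffy_thickness_mm >
      fill_length_mm + 1e-9) {
    stop_microhct("Packed cells plus buffy coat exceed the fill length.",
                  "microhct_invalid_tube")
  }
  structure(
    list(tube_length_mm = tube_length_mm, inner_diameter_mm = inner_diameter_mm,
         plug_length_mm = plug_length_mm, fill_length_mm = fill_length_mm,
         true_hct_pct = true_hct_pct, buffy_thickness_mm = buffy_thickness_mm,
         meniscus_depth_mm = meniscus_depth_mm),
    class = "tube_spec"
  )
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf(
    "<tube_spec> %.0f mm tube, %.1f mm bore, %.0f mm plug, %.0f mm fill, Hct %.1f%%\n",
    x$tube_length_mm, x$inner_diameter_mm, x$plug_length_mm, x$fill_length_mm,
    x$true_hct_pct))
  invisible(x)
}

# Interface positions in the world frame (cm), tube centred on the origin
# with the plug towards -y. y_buffy is the top of the packed RBC column: the
# line the buffy marker targets, so that packed cells / fill equals the true
# hematocrit exactly.
tube_geometry <- function(tube) {
  fill <- tube$fill_length_mm / 10
  plug <- tube$plug_length_mm / 10
  len <- tube$tube_length_mm / 10
  y_plug_top <- -len / 2 + plug
  list(
    radius_cm = tube$inner_diameter_mm / 20,
    y_tube_bottom = -len / 2,
    y_tube_top = len / 2,
    y_plug_top = y_plug_top,
    y_buffy = y_plug_top + tube$true_hct_pct / 100 * fill,
    y_buffy_top = y_plug_top + tube$true_hct_pct / 100 * fill +
      tube$buffy_thickness_mm / 10,
    y_plasma_top = y_plug_top + fill,
    meniscus_cm = tube$meniscus_depth_mm / 10
  )
}

#' Renderer configuration
#'
#' Raster size, zone palette and noise model for the synthetic tube
#' renderer. Zone colours must be pairwise separable: the minimum pairwise
#' Euclidean RGB distance of the default palette is about 0.34 (buffy vs
#' plasma), and automatic detection classifies colours against half the
#' minimum separation.
#'
#' @param width_px,height_px Raster size. The default tall thin raster
#'   matches a phone screen cropped to the capture rectangle.
#' @param colors Named list of RGB triplets in `[0, 1]`: `background`,
#'   `glass`, `plug`, `rbc`, `buffy`, `plasma`.
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian noise per
#'   channel (clipped to `[0, 1]`); 0 disables noise.
#' @param seed Integer seed driving the noise; rendering is byte-identical
#'   for identical inputs and seed.
#' @return A `render_config` object.
#' @export
render_config <- function(width_px = 192, height_px = 1136,
                          colors = default_palette(),
                          noise_sd = 0, seed = 1L) {
  width_px <- as.integer(check_number(width_px, "width_px"))
  height_px <- as.integer(check_number(height_px, "height_px"))
  noise_sd <- check_number(noise_sd, "noise_sd")
  seed <- as.integer(check_number(seed, "seed"))
  if (noise_sd < 0) stop_microhct("`noise_sd` must be >= 0.", "microhct_invalid_config")
  needed <- c("background", "glass", "plug", "rbc", "buffy", "plasma")
  if (!is.list(colors) || !all(needed %in% names(colors)) ||
      !all(vapply(colors, function(x) is.numeric(x) && length(x) == 3L &&
                    all(x >= 0 & x <= 1), logical(1)))) {
    stop_microhct("`colors` must name RGB triplets for all six zones.",
                  "microhct_invalid_config")
  }
  if (min_color_separation(colors) < 0.15) {
    stop_microhct("Zone colours are not separable enough (min pairwise RGB distance < 0.15).",
                  "microhct_invalid_config")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 colors = colors[needed], noise_sd = noise_sd, seed = seed),
            class = "render_config")
}

#' Default zone palette
#' @return Named list of RGB triplets.
#' @export
default_palette <- function() {
  list(
    background = c(0.25, 0.25, 0.28),
    glass      = c(0.62, 0.72, 0.82),
    plug       = c(0.85, 0.55, 0.15),
    rbc        = c(0.55, 0.05, 0.08),
    buffy      = c(0.92, 0.90, 0.78),
    plasma     = c(0.95, 0.85, 0.45)
  )
}

min_color_separation <- function(colors) {
  m <- do.call(rbind, colors)
  min(stats::dist(m))
}

#' Render a synthetic tube photograph
#'
#' Produces a raster photograph of a centrifuged tube lying in the bench
#' plane, seen through the pinhole camera at `pose`, together with the
#' ground-truth marker rows. Rendering inverse-maps every pixel through the
#' camera model into the tube plane and paints it by zone, so zone
#' boundaries in the raster coincide with the projections of the physical
#' interfaces to sub-pixel accuracy. The truth markers are the projected
#' rows of the plug top, the packed-cell top, and the plasma top at the
#' extremum of its meniscus (the row a careful human would target).
#'
#' @param tube A [tube_spec()].
#' @param pose A [camera_pose()]. The whole tube must fall inside the field
#'   of view; otherwise a framing error is raised.
#' @param cfg A [render_config()].
#' @param intr Optional [camera_intrinsics()]; defaults to intrinsics
#'   matching `cfg`'s raster with the default focal length.
#' @return A `rendered_sample`: list with `image` (array), `truth_markers`
#'   ([marker_set()]), `pose`, `tube`, `intrinsics`, `seed`.
#' @export
render_tube <- function(tube, pose = camera_pose(), cfg = render_config(),
                        intr = NULL) {
  stopifnot(inherits(tube, "tube_spec"), inherits(pose, "camera_pose"),
            inherits(cfg, "render_config"))
  if (is.null(intr)) {
    intr <- camera_intrinsics(image_width_px = cfg$width_px,
                              image_height_px = cfg$height_px)
  }
  if (intr$image_width_px != cfg$width_px || intr$image_height_px != cfg$height_px) {
    stop_microhct("Intrinsics raster size must match the render config.",
                  "microhct_invalid_config")
  }
  g <- tube_geometry(tube)

  # framing: the measured sample column (plug top to plasma top, plus a 2 mm
  # margin so both terminal transitions are visible) must project inside the
  # raster; the empty glass ends of the capillary may crop, as they do in a
  # real phone frame
  margin <- 0.2
  y_lo <- max(g$y_tube_bottom, g$y_plug_top - margin)
  y_hi <- min(g$y_tube_top, g$y_plasma_top + abs(g$meniscus_cm) + margin)
  corners <- list(c(-g$radius_cm, y_lo, 0), c(g$radius_cm, y_lo, 0),
                  c(-g$radius_cm, y_hi, 0), c(g$radius_cm, y_hi, 0))
  for (pt in corners) {
    px <- tryCatch(project_point(pose, intr, pt),
                   microhct_projection_error = function(e) {
                     stop_microhct("Tube lies at or behind the camera plane.",
                                   "microhct_framing_error")
                   })
    if (px[1] < 1 || px[1] > cfg$width_px || px[2] < 1 || px[2] > cfg$height_px) {
      stop_microhct("The sample column is outside the field of view at this pose.",
                    "microhct_framing_error")
    }
  }

  # inverse map: pixel -> bench-plane point (vectorised over the raster)
  rot_t <- t(pose_rotation(pose))
  cen <- pose_centre(pose)
  u <- (seq_len(cfg$width_px) - intr$principal_point[1]) / intr$focal_px
  v <- (seq_len(cfg$height_px) - intr$principal_point[2]) / intr$focal_px
  one_h <- rep(1, cfg$height_px)
  one_w <- rep(1, cfg$width_px)
  # world ray direction d = rot_t %*% c(u, v, 1), per pixel
  dx <- outer(rot_t[1, 2] * v, one_w) + outer(one_h, rot_t[1, 1] * u) + rot_t[1, 3]
  dy <- outer(rot_t[2, 2] * v, one_w) + outer(one_h, rot_t[2, 1] * u) + rot_t[2, 3]
  dz <- outer(rot_t[3, 2] * v, one_w) + outer(one_h, rot_t[3, 1] * u) + rot_t[3, 3]
  tt <- -cen[3] / dz
  tt[dz >= 0] <- NA_real_          # rays that never reach the bench
  wx <- cen[1] + tt * dx
  wy <- cen[2] + tt * dy

  zone <- zone_map(wx, wy, g)
  pal <- do.call(rbind, cfg$colors)  # 6 x 3, rows in zone-id order
  img <- array(0, dim = c(cfg$height_px, cfg$width_px, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(pal[zone, ch], nrow = cfg$height_px)
  if (cfg$noise_sd > 0) {
    withr::local_seed(cfg$seed)
    img <- img + array(rnorm(length(img), sd = cfg$noise_sd), dim = dim(img))
    img[] <- pmin(pmax(img, 0), 1)
  }

  rows <- vapply(list(g$y_plug_top, g$y_buffy, g$y_plasma_top),
                 function(y) project_point(pose, intr, c(0, y, 0))[["row"]],
                 numeric(1))
  structure(
    list(image = img,
         truth_markers = marker_set(lower_row = rows[1], buffy_row = rows[2],
                                    upper_row = rows[3]),
         pose = pose, tube = tube, intrinsics = intr, config = cfg,
         seed = cfg$seed),
    class = "rendered_sample"
  )
}

# zone ids: 1 background, 2 glass, 3 plug, 4 rbc, 5 buffy, 6 plasma
zone_map <- function(wx, wy, g) {
  zone <- matrix(1L, nrow = nrow(wx), ncol = ncol(wx))
  in_tube <- !is.na(wx) & abs(wx) <= g$radius_cm &
    wy >= g$y_tube_bottom & wy <= g$y_tube_top
  zone[in_tube] <- 2L
  zone[in_tube & wy <= g$y_plug_top] <- 3L
  zone[in_tube & wy > g$y_plug_top & wy <= g$y_buffy] <- 4L
  zone[in_tube & wy > g$y_buffy & wy <= g$y_buffy_top] <- 5L
  # plasma top: parabolic meniscus with its extremum on the tube axis
  bound <- g$y_plasma_top + g$meniscus_cm * (wx / g$radius_cm)^2
  zone[in_tube & wy > g$y_buffy_top & wy <= bound] <- 6L
  zone
}

#' @export
print.rendered_sample <- function(x, ...) {
  cat(sprintf(
    "<rendered_sample> %dx%d px, true Hct %.1f%%, pitch %.1f°, seed %d\n",
    dim(x$image)[1], dim(x$image)[2], x$tube$true_hct_pct, x$pose$pitch_deg,
    x$seed))
  invisible(x)
}

#' Render a cohort of tubes with uniformly drawn hematocrits
#'
#' @param n Number of samples (>= 1).
#' @param hct_range Length-2 interval within `[0, 100]` from which true
#'   hematocrits are drawn uniformly. Defaults to 38-48, the normal adult
#'   range the validation cohort spanned.
#' @param pose,cfg Passed to [render_tube()].
#' @param seed Cohort seed; per-sample seeds and hematocrit draws derive
#'   deterministically from it.
#' @param tube Template [tube_spec()] whose `true_hct_pct` is replaced per
#'   sample.
#' @return List of `rendered_sample` objects.
#' @export
render_cohort <- function(n, hct_range = c(38, 48), pose = camera_pose(),
                          cfg = render_config(), seed = 1L,
                          tube = tube_spec()) {
  n <- as.integer(check_number(n, "n"))
  if (n < 1L) stop_microhct("`n` must be >= 1.", "microhct_invalid_config")
  if (length(hct_range) != 2L || any(!is.finite(hct_range)) ||
      hct_range[1] > hct_range[2] || hct_range[1] < 0 || hct_range[2] > 100) {
    stop_microhct("`hct_range` must be an interval within [0, 100].",
                  "microhct_invalid_config")
  }
  withr::local_seed(as.integer(seed))
  hcts <- runif(n, hct_range[1], hct_range[2])
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  purrr::map2(hcts, seeds, function(h, s) {
    tb <- tube
    tb$true_hct_pct <- h
    cf <- cfg
    cf$seed <- s
    render_tube(tb, pose, cf)
  })
}

#' Write / read a rendered sample as PNG plus JSON sidecar
#'
#' The raster goes to `path` as PNG; tube spec, pose, truth markers and seed
#' go to `paste0(path, ".json")` (sidecar schema version 1).
#'
#' @param sample A `rendered_sample`.
#' @param path PNG file path.
#' @return `path`, invisibly (`write_rendered_sample`); a `rendered_sample`
#'   without a config (`read_rendered_sample`).
#' @export
write_rendered_sample <- function(sample, path) {
  stopifnot(inherits(sample, "rendered_sample"))
  png::writePNG(sample$image, path)
  side <- list(
    schema_version = 1L,
    tube = unclass(sample$tube),
    pose = unclass(sample$pose),
    intrinsics = unclass(sample$intrinsics),
    truth_markers = unclass(sample$truth_markers),
    seed = sample$seed
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rendered_sample
#' @export
read_rendered_sample <- function(path) {
  img <- png::readPNG(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(image = img,
         truth_markers = do.call(marker_set, side$truth_markers),
         pose = do.call(camera_pose, side$pose[c("pitch_deg", "yaw_deg",
                                                 "roll_deg", "height_cm",
                                                 "setback_cm")]),
         tube = do.call(tube_spec, side$tube),
         intrinsics = do.call(camera_intrinsics,
                              side$intrinsics[c("focal_px", "image_width_px",
                                                "image_height_px",
                                                "principal_point")]),
         config = NULL,
         seed = side$seed),
    class = "rendered_sample"
  )
}
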