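#' Locate the tube axis in an image
#'
#' Finds the largest non-background connected component and returns its
#' principal axis. Detection is palette-based: pixels further than the
#' classification threshold from the background colour count as foreground.
#' The axis angle is the in-plane tilt of the tube from vertical, positive
#' clockwise (matching [adjustment()]'s rotation sign, so rotating by the
#' negative of the detected angle straightens the tube).
#'
#' @param image A `height x width x 3` array in `[0, 1]`.
#' @param cfg A [render_config()] supplying the palette. For real
#'   photographs supply a config whose colours approximate the scene.
#' @return List with `angle_deg`, `centre` (`c(col, row)`), `slope`
#'   (d col / d row along the axis) and `rows` (row extent of the component).
#' @export
locate_tube_axis <- function(image, cfg = render_config()) {
  check_image(image)
  stopifnot(inherits(cfg, "render_config"))
  thr <- classification_threshold(cfg)
  smoothed <- smooth_image(image)
  bgd <- color_distance(smoothed, cfg$colors$background)
  mask <- bgd > thr
  if (!any(mask)) {
    stop_microhct("No tube-like region found in the image.", "microhct_no_tube")
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labd <- t(EBImage::imageData(lab))
  counts <- tabulate(labd[labd > 0])
  keep <- which.max(counts)
  idx <- which(labd == keep, arr.ind = TRUE)
  rows <- idx[, 1]
  cols <- idx[, 2]
  cen <- c(col = mean(cols), row = mean(rows))
  cv <- stats::cov(cbind(cols, rows))
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]              # (col, row) direction of largest spread
  if (v[2] < 0) v <- -v             # orient along increasing row
  angle <- atan2(-v[1], v[2]) * 180 / pi
  if (abs(angle) > 45) {
    stop_microhct("Tube axis is more than 45 degrees from vertical; rotate the image first.",
                  "microhct_orientation_error")
  }
  # central-band halfwidth: half of half the tube width, from the median
  # per-row width of the component, shrunk by the ~1 px dilation the box
  # smoothing adds on each side
  widths <- tabulate(rows)
  w_med <- stats::median(widths[widths > 0])
  halfwidth <- max(1, (w_med / 2 - 1) * 0.5)
  list(angle_deg = angle, centre = cen, slope = v[1] / v[2],
       rows = range(rows), halfwidth = halfwidth)
}

# 3x3 box smoothing per channel; suppresses pixel noise before palette
# distances are taken (the box is small against the ~12 px tube width, so
# interface locations are not shifted systematically).
smooth_image <- function(image) {
  k <- matrix(1 / 9, 3, 3)
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- t(EBImage::imageData(
      EBImage::filter2(EBImage::Image(t(image[, , ch])), k)))
  }
  out
}

# Run-length encode a row classification (rows need not be contiguous after
# speckle removal; a gap splits the run).
zone_runs <- function(known) {
  known <- known[order(known$row), ]
  brk <- c(1L, as.integer(known$zone[-1] != known$zone[-nrow(known)] |
                            diff(known$row) > 3))
  run <- cumsum(brk)
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(known, run = run), .data$run, .data$zone),
    row_top = min(.data$row), row_bottom = max(.data$row), n = dplyr::n(),
    .groups = "drop")
  merged <- dplyr::arrange(out, .data$row_top)
  # merge adjacent runs of the same zone (can appear after speckle removal)
  if (nrow(merged) > 1) {
    same <- merged$zone[-1] == merged$zone[-nrow(merged)]
    grp <- cumsum(c(1L, as.integer(!same)))
    merged <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(merged, grp = grp), .data$grp, .data$zone),
      row_top = min(.data$row_top), row_bottom = max(.data$row_bottom),
      n = sum(.data$n), .groups = "drop")
    merged <- dplyr::arrange(merged, .data$row_top)
  }
  merged[, c("zone", "row_top", "row_bottom", "n")]
}

color_distance <- function(image, color) {
  sqrt((image[, , 1] - color[1])^2 + (image[, , 2] - color[2])^2 +
         (image[, , 3] - color[3])^2)
}

classification_threshold <- function(cfg) {
  min_color_separation(cfg$colors) / 2
}

#' Classify image rows into tube zones
#'
#' Samples each image row in a narrow band around the tube axis (the central
#' half of the tube width), averages the colour, and assigns the nearest
#' palette zone when it lies within the classification threshold (half the
#' minimum pairwise palette separation); otherwise the row is `unknown`.
#' Sampling near the axis is what makes the meniscus rule work: the
#' plasma-top boundary is read at the tube centre, which is the extremum of
#' a parabolic meniscus whether concave or convex.
#'
#' @param image A raster array.
#' @param axis Result of [locate_tube_axis()].
#' @param cfg A [render_config()].
#' @return A tibble with columns `row`, `zone` (factor: glass, plug, rbc,
#'   buffy, plasma, unknown) and attribute-free column `dist`. Errors if
#'   more than half the tube rows are unknown.
#' @export
classify_rows <- function(image, axis, cfg = render_config()) {
  check_image(image)
  thr <- classification_threshold(cfg)
  h <- dim(image)[1]; w <- dim(image)[2]
  # the smoothed mask dilates the component by ~1 row at each tube end
  rows <- seq(min(axis$rows[1] + 1, axis$rows[2]),
              max(axis$rows[2] - 1, axis$rows[1]))
  halfw <- axis$halfwidth
  zones <- c("glass", "plug", "rbc", "buffy", "plasma")
  pal <- do.call(rbind, cfg$colors[zones])
  out_zone <- character(length(rows))
  out_dist <- numeric(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[i]
    xc <- axis$centre[["col"]] + axis$slope * (r - axis$centre[["row"]])
    cl <- max(1, round(xc - halfw)):min(w, round(xc + halfw))
    colr <- c(mean(image[r, cl, 1]), mean(image[r, cl, 2]), mean(image[r, cl, 3]))
    d <- sqrt(colSums((t(pal) - colr)^2))
    j <- which.min(d)
    if (d[j] <= thr) {
      out_zone[i] <- zones[j]
      out_dist[i] <- d[j]
    } else {
      out_zone[i] <- "unknown"
      out_dist[i] <- min(d)
    }
  }
  if (mean(out_zone == "unknown") > 0.5) {
    stop_microhct("More than half of the tube rows could not be classified.",
                  "microhct_classification_failure")
  }
  tibble::tibble(row = rows, zone = out_zone, dist = out_dist)
}

#' Detect the measurement markers in a tube image
#'
#' The automatic stand-in for the human operator: locates the tube, labels
#' its rows by zone, and places the three markers at zone transitions. Each
#' transition sits at the midpoint between the last row of one zone and the
#' first row of the next. Degenerate tubes are handled: with no red-cell
#' zone (hematocrit 0) the buffy marker coincides with the lower marker;
#' with no plasma (hematocrit 100) it coincides with the upper marker.
#'
#' @param image A raster array.
#' @param cfg A [render_config()] supplying the palette.
#' @return A `detection_result`: list with `markers` ([marker_set()]),
#'   `axis_angle_deg`, `zone_sequence` (tibble of zone extents, bottom to
#'   top) and `confidence` (fraction of classified tube rows).
#' @export
detect_markers <- function(image, cfg = render_config()) {
  axis <- locate_tube_axis(image, cfg)
  cls <- classify_rows(image, axis, cfg)
  known <- cls[cls$zone != "unknown", ]
  confidence <- nrow(known) / nrow(cls)

  runs <- zone_runs(known)
  # drop single-row speckles (noise), then re-merge neighbouring same-zone runs
  if (any(runs$n < 2) && nrow(runs) > 1) {
    kept <- known[known$row %in% unlist(Map(seq, runs$row_top[runs$n >= 2],
                                            runs$row_bottom[runs$n >= 2])), ]
    runs <- zone_runs(kept)
  }

  seq_zones <- runs$zone
  want <- c("plug", "rbc", "buffy", "plasma")
  present <- want[want %in% seq_zones]
  # zones must appear once each, ordered bottom (large rows) to top
  ord <- runs[runs$zone %in% want, ]
  if (nrow(ord) == 0 || anyDuplicated(ord$zone) ||
      !identical(ord$zone, rev(present))) {
    stop_microhct("Zone sequence is not monotone plug -> rbc -> buffy -> plasma.",
                  "microhct_detection_error")
  }

  top_of <- function(z) ord$row_top[ord$zone == z]
  bottom_of <- function(z) ord$row_bottom[ord$zone == z]
  above <- function(z) {
    # first classified row above zone z (smaller row index), else boundary
    r <- ord$row_top[ord$zone == z]
    cand <- c(runs$row_bottom[runs$row_bottom < r], axis$rows[1] - 1)
    max(cand)
  }
  midpoint <- function(low_row, high_row) (low_row + high_row) / 2

  if (!"plug" %in% ord$zone) {
    stop_microhct("No plug zone found.", "microhct_detection_error")
  }
  has_rbc <- "rbc" %in% ord$zone
  has_plasma <- "plasma" %in% ord$zone

  if (has_rbc) {
    lower <- midpoint(top_of("plug"), bottom_of("rbc"))
    z_above_rbc <- if ("buffy" %in% ord$zone) "buffy" else if (has_plasma) "plasma" else NULL
    if (is.null(z_above_rbc)) {
      buffy <- upper <- midpoint(top_of("rbc"), above("rbc"))
    } else {
      buffy <- midpoint(top_of("rbc"), bottom_of(z_above_rbc))
      upper <- if (has_plasma) midpoint(top_of("plasma"), above("plasma"))
               else midpoint(top_of(z_above_rbc), above(z_above_rbc))
    }
  } else {
    # hematocrit 0: plug abuts buffy/plasma directly
    z_above <- if ("buffy" %in% ord$zone) "buffy" else "plasma"
    lower <- buffy <- midpoint(top_of("plug"), bottom_of(z_above))
    upper <- if (has_plasma) midpoint(top_of("plasma"), above("plasma"))
             else midpoint(top_of(z_above), above(z_above))
  }

  structure(
    list(markers = marker_set(lower_row = lower, buffy_row = buffy,
                              upper_row = upper),
         axis_angle_deg = axis$angle_deg,
         zone_sequence = ord[rev(seq_len(nrow(ord))),
                             c("zone", "row_bottom", "row_top")],
         confidence = confidence),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> axis %.2f°, confidence %.2f\n",
              x$axis_angle_deg, x$confidence))
  print(x$markers)
  invisible(x)
}
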