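#' Marker set: the three measurement lines
#'
#' The whole hematocrit measurement consumes three horizontal lines placed on
#' the image: `lower` at the plug-top/RBC interface, `buffy` at the
#' RBC/plasma interface (at the maximum excursion of any meniscus), and
#' `upper` at the top of the plasma. Rows are real-valued (markers can sit
#' between pixel rows), row 0 is the image top and rows increase downward,
#' so with the plug at the bottom of the screen `lower_row > upper_row`.
#'
#' @param lower_row,buffy_row,upper_row Marker pixel rows; must satisfy
#'   `upper_row <= buffy_row <= lower_row` with `upper_row < lower_row`.
#' @return A `marker_set` object.
#' @export
marker_set <- function(lower_row, buffy_row, upper_row) {
  lower_row <- check_number(lower_row, "lower_row")
  buffy_row <- check_number(buffy_row, "buffy_row")
  upper_row <- check_number(upper_row, "upper_row")
  if (lower_row <= upper_row) {
    stop_microhct("Degenerate sample: `lower_row` must exceed `upper_row`.",
                  "microhct_degenerate_sample")
  }
  if (buffy_row > lower_row || buffy_row < upper_row) {
    stop_microhct("`buffy_row` must lie between `upper_row` and `lower_row`.",
                  "microhct_marker_order")
  }
  structure(list(lower_row = lower_row, buffy_row = buffy_row,
                 upper_row = upper_row),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> lower %.2f, buffy %.2f, upper %.2f (rows)\n",
              x$lower_row, x$buffy_row, x$upper_row))
  invisible(x)
}

#' Pixel-ratio hematocrit from a marker set
#'
#' The measurement at the heart of the method: hematocrit is the packed-cell
#' column (pixels between the `lower` and `buffy` lines) as a percentage of
#' the whole sample column (pixels between `lower` and `upper`). The ratio is
#' invariant to zoom and translation of the image, which is what lets a user
#' magnify freely before placing the markers. The reported value is rounded
#' half-up to 0.1 percentage points; the unrounded value is retained in
#' `hct_raw`.
#'
#' @param markers A [marker_set()].
#' @return A one-row tibble of class `hct_result` with columns `hct_pct`
#'   (reported, 0.1 steps), `hct_raw`, `blood_px`, `total_px` and
#'   `resolution_pct` (percentage points per pixel, `100/total_px`).
#' @examples
#' compute_hct(marker_set(900, 450, 100))  # 56.25, reported 56.3
#' @export
compute_hct <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  blood_px <- markers$lower_row - markers$buffy_row
  total_px <- markers$lower_row - markers$upper_row
  raw <- 100 * blood_px / total_px
  out <- tibble::tibble(
    hct_pct = round_half_up(raw, 1),
    hct_raw = raw,
    blood_px = blood_px,
    total_px = total_px,
    resolution_pct = 100 / total_px
  )
  class(out) <- c("hct_result", class(out))
  out
}

#' On-screen measurement resolution
#'
#' The smallest hematocrit increment a screen can register: one pixel out of
#' the pixels spanned by the sample column. For a viewport of `viewport_px`
#' logical pixels of which the plug-to-plasma distance occupies fraction
#' `occupancy`, that increment is `100 / (occupancy * viewport_px)` percent.
#'
#' @param viewport_px Screen height in logical pixels (>= 1).
#' @param occupancy Fraction of the screen height spanned by the sample
#'   column, in (0, 1]. Defaults to 0.75, the occupancy a user reaches after
#'   pinch-to-zoom framing.
#' @return Percent per pixel, unrounded.
#' @examples
#' hct_resolution(586, 0.75)   # 0.2276 -> 0.23 at two decimals
#' hct_resolution(932, 0.75)   # 0.1431 -> 0.1 at one decimal
#' hct_resolution(1000, 1)     # exactly 0.1
#' @export
hct_resolution <- function(viewport_px, occupancy = 0.75) {
  viewport_px <- check_number(viewport_px, "viewport_px")
  occupancy <- check_number(occupancy, "occupancy")
  if (viewport_px < 1) {
    stop_microhct("`viewport_px` must be >= 1.", "microhct_invalid_argument")
  }
  if (occupancy <= 0 || occupancy > 1) {
    stop_microhct("`occupancy` must be in (0, 1].", "microhct_invalid_argument")
  }
  100 / (occupancy * viewport_px)
}

#' Image adjustment state
#'
#' Rotation is applied in 0.5 degree steps (the rotation buttons); zoom is a
#' magnification factor >= 1 (pinch-to-zoom). While zoomed, rotation is
#' disabled so the tube stays vertical on screen.
#'
#' @param rotation_deg Accumulated rotation, a multiple of 0.5 degrees.
#'   Positive rotates the image content clockwise.
#' @param zoom Magnification factor (>= 1).
#' @return An `adjustment` object.
#' @export
adjustment <- function(rotation_deg = 0, zoom = 1) {
  rotation_deg <- check_number(rotation_deg, "rotation_deg")
  zoom <- check_number(zoom, "zoom")
  if (abs(rotation_deg / 0.5 - round(rotation_deg / 0.5)) > 1e-9) {
    stop_microhct("`rotation_deg` must be a multiple of 0.5.", "microhct_invalid_adjustment")
  }
  if (zoom < 1) {
    stop_microhct("`zoom` must be >= 1.", "microhct_invalid_adjustment")
  }
  structure(list(rotation_deg = rotation_deg, zoom = zoom), class = "adjustment")
}

#' Step the rotation by one 0.5 degree press
#'
#' @param adj An [adjustment()].
#' @param direction `"left"` (counter-clockwise, -0.5) or `"right"`
#'   (clockwise, +0.5).
#' @return The updated [adjustment()].
#' @export
rotate_step <- function(adj, direction = c("right", "left")) {
  stopifnot(inherits(adj, "adjustment"))
  direction <- match.arg(direction)
  step <- if (direction == "right") 0.5 else -0.5
  adjustment(rotation_deg = adj$rotation_deg + step, zoom = adj$zoom)
}

#' Apply an adjustment to a raster image
#'
#' Rotates the image about its centre by `rotation_deg` (clockwise positive,
#' bilinear interpolation), then magnifies by `zoom` as a central
#' crop-and-scale. The output raster keeps the input size. Mirroring the app
#' contract, a non-zero rotation combined with `zoom > 1` is a state error:
#' rotation is disabled once the image is zoomed.
#'
#' @param image An `height x width x 3` numeric array in `[0, 1]`.
#' @param adj An [adjustment()].
#' @param bg Background colour used for pixels rotated in from outside the
#'   frame (RGB in `[0, 1]`).
#' @return An array with the same dimensions as `image`.
#' @export
apply_adjustment <- function(image, adj, bg = c(0, 0, 0)) {
  stopifnot(inherits(adj, "adjustment"))
  check_image(image)
  if (adj$zoom > 1 && adj$rotation_deg != 0) {
    stop_microhct("Rotation is disabled while the image is zoomed.",
                  "microhct_state_error")
  }
  out <- image
  if (adj$rotation_deg != 0) {
    out <- ebi_to_array(
      EBImage::rotate(array_to_ebi(out), angle = adj$rotation_deg,
                      filter = "bilinear",
                      output.dim = c(dim(out)[2], dim(out)[1]),
                      bg.col = grDevices::rgb(bg[1], bg[2], bg[3]))
    )
  }
  if (adj$zoom > 1) {
    h <- dim(out)[1]; w <- dim(out)[2]
    ch <- h / adj$zoom; cw <- w / adj$zoom
    r0 <- (h - ch) / 2; c0 <- (w - cw) / 2
    ebi <- array_to_ebi(out)
    # crop the central window, then scale back up to the input size
    win <- ebi[max(1, floor(c0) + 1):min(w, ceiling(c0 + cw)),
               max(1, floor(r0) + 1):min(h, ceiling(r0 + ch)), ]
    out <- ebi_to_array(EBImage::resize(win, w = w, h = h, filter = "bilinear"))
  }
  out[] <- pmin(pmax(out, 0), 1)
  out
}

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      !is.numeric(image)) {
    stop_microhct("`image` must be a height x width x 3 numeric array.",
                  "microhct_invalid_argument")
  }
  invisible(image)
}

# microhct stores rasters as (row, col, channel); EBImage as (x, y, channel).
array_to_ebi <- function(a) {
  EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
}

ebi_to_array <- function(img) {
  aperm(EBImage::imageData(img), c(2, 1, 3))
}
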