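#' Camera pose for tube capture
#'
#' Describes where the phone camera sits relative to a capillary tube lying
#' flat on the bench. Angles follow the on-screen convention for a tube
#' photographed from above: *pitch* rotates the camera about the horizontal
#' axis perpendicular to the tube (positive pitch tilts the camera top away
#' from the tube, swinging the view along the tube towards its plasma end),
#' *yaw* rotates about the tube's long axis, and *roll* spins the camera about
#' its own optical axis (tilting the tube in the image). `setback_cm` moves
#' the camera horizontally along the tube axis, away from the plug end, from
#' the point directly above the tube centre; combined with a matching pitch it
#' reproduces the "standing back from the bench" capture.
#'
#' @param pitch_deg,yaw_deg,roll_deg Camera angles in degrees (finite).
#' @param height_cm Vertical height of the camera above the tube plane (cm,
#'   positive). Default 19.5 cm, a typical small-tripod working height.
#' @param setback_cm Horizontal offset from directly above the tube (cm,
#'   non-negative).
#' @return A `camera_pose` object (a named list).
#' @examples
#' camera_pose()                         # nadir
#' camera_pose(pitch_deg = 33, setback_cm = 10)
#' @export
camera_pose <- function(pitch_deg = 0, yaw_deg = 0, roll_deg = 0,
                        height_cm = 19.5, setback_cm = 0) {
  pitch_deg <- check_number(pitch_deg, "pitch_deg")
  yaw_deg <- check_number(yaw_deg, "yaw_deg")
  roll_deg <- check_number(roll_deg, "roll_deg")
  height_cm <- check_number(height_cm, "height_cm")
  setback_cm <- check_number(setback_cm, "setback_cm")
  if (height_cm <= 0) {
    stop_microhct("`height_cm` must be > 0.", "microhct_invalid_pose")
  }
  if (setback_cm < 0) {
    stop_microhct("`setback_cm` must be >= 0.", "microhct_invalid_pose")
  }
  structure(
    list(pitch_deg = pitch_deg, yaw_deg = yaw_deg, roll_deg = roll_deg,
         height_cm = height_cm, setback_cm = setback_cm),
    class = "camera_pose"
  )
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf(
    "<camera_pose> pitch %.1f°, yaw %.1f°, roll %.1f°, height %.1f cm, setback %.1f cm\n",
    x$pitch_deg, x$yaw_deg, x$roll_deg, x$height_cm, x$setback_cm))
  invisible(x)
}

#' Pinhole camera intrinsics
#'
#' A distortion-free pinhole model. The default focal length is chosen so
#' that the default 75 mm tube photographed at the default 19.5 cm height
#' spans about 75% of the default 1136-pixel raster height -- the screen
#' occupancy a user aims for after framing the sample.
#'
#' @param focal_px Focal length in pixels (> 0).
#' @param image_width_px,image_height_px Raster size in pixels.
#' @param principal_point Length-2 numeric `(col, row)`; defaults to the
#'   raster centre. Must lie inside the raster.
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(focal_px = 0.75 * 1136 * 19.5 / 7.5,
                              image_width_px = 192,
                              image_height_px = 1136,
                              principal_point = NULL) {
  focal_px <- check_number(focal_px, "focal_px")
  if (focal_px <= 0) stop_microhct("`focal_px` must be > 0.", "microhct_invalid_intrinsics")
  image_width_px <- as.integer(check_number(image_width_px, "image_width_px"))
  image_height_px <- as.integer(check_number(image_height_px, "image_height_px"))
  if (image_width_px < 1L || image_height_px < 1L) {
    stop_microhct("Raster dimensions must be >= 1 pixel.", "microhct_invalid_intrinsics")
  }
  if (is.null(principal_point)) {
    principal_point <- c((image_width_px + 1) / 2, (image_height_px + 1) / 2)
  }
  if (length(principal_point) != 2L || !all(is.finite(principal_point))) {
    stop_microhct("`principal_point` must be two finite numbers.", "microhct_invalid_intrinsics")
  }
  if (principal_point[1] < 1 || principal_point[1] > image_width_px ||
      principal_point[2] < 1 || principal_point[2] > image_height_px) {
    stop_microhct("`principal_point` must lie inside the raster.", "microhct_invalid_intrinsics")
  }
  structure(
    list(focal_px = focal_px, image_width_px = image_width_px,
         image_height_px = image_height_px,
         principal_point = as.numeric(principal_point)),
    class = "camera_intrinsics"
  )
}

#' Capture-quality gate
#'
#' The on-screen reticule indicator: capture is allowed (indicator green)
#' only when both |pitch| and |yaw| are strictly below 5 degrees. Roll and
#' setback do not enter the gate.
#'
#' @param pose A [camera_pose()].
#' @return A one-row tibble with logical columns `pitch_ok`, `yaw_ok`,
#'   `passed` (`passed == pitch_ok & yaw_ok`).
#' @examples
#' capture_gate(camera_pose(pitch_deg = 4.9, yaw_deg = 4.9))$passed  # TRUE
#' capture_gate(camera_pose(pitch_deg = 5))$passed                   # FALSE
#' @export
capture_gate <- function(pose) {
  stopifnot(inherits(pose, "camera_pose"))
  pitch_ok <- abs(pose$pitch_deg) < 5
  yaw_ok <- abs(pose$yaw_deg) < 5
  tibble::tibble(pitch_ok = pitch_ok, yaw_ok = yaw_ok,
                 passed = pitch_ok && yaw_ok)
}

# World frame: tube axis along y (plug towards -y, plasma towards +y), z up,
# tube plane z = 0. Camera centre at (0, -setback, height). The world->camera
# rotation is Rz(roll) %*% Rx(pitch) %*% Ry(yaw) %*% R_base where R_base is
# the nadir orientation (camera x = world x, camera y = -world y so image
# rows grow towards the plug, optical axis = -world z).
pose_rotation <- function(pose) {
  d <- pi / 180
  base <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  th <- pose$pitch_deg * d
  rx <- rbind(c(1, 0, 0), c(0, cos(th), sin(th)), c(0, -sin(th), cos(th)))
  ph <- pose$yaw_deg * d
  ry <- rbind(c(cos(ph), 0, -sin(ph)), c(0, 1, 0), c(sin(ph), 0, cos(ph)))
  rho <- -pose$roll_deg * d  # positive roll tilts the tube clockwise in the image
  rz <- rbind(c(cos(rho), sin(rho), 0), c(-sin(rho), cos(rho), 0), c(0, 0, 1))
  rz %*% rx %*% ry %*% base
}

pose_centre <- function(pose) c(0, -pose$setback_cm, pose$height_cm)

#' Project a world point to pixel coordinates
#'
#' Pinhole projection of a point in the tube-plane frame (cm; see
#' [camera_pose()] for the frame convention) to image pixel coordinates
#' (`col` grows rightward, `row` grows downward, pixel centres at integers).
#'
#' @param pose A [camera_pose()].
#' @param intr A [camera_intrinsics()].
#' @param world_point Numeric length 3 `(x, y, z)` in cm.
#' @return Named numeric vector `c(col, row)`.
#' @export
project_point <- function(pose, intr, world_point) {
  stopifnot(inherits(pose, "camera_pose"), inherits(intr, "camera_intrinsics"))
  if (length(world_point) != 3L || !all(is.finite(world_point))) {
    stop_microhct("`world_point` must be three finite numbers.", "microhct_invalid_argument")
  }
  p_cam <- as.numeric(pose_rotation(pose) %*% (world_point - pose_centre(pose)))
  if (p_cam[3] <= 1e-9) {
    stop_microhct("Point is at or behind the camera plane.", "microhct_projection_error")
  }
  c(col = intr$focal_px * p_cam[1] / p_cam[3] + intr$principal_point[1],
    row = intr$focal_px * p_cam[2] / p_cam[3] + intr$principal_point[2])
}

#' Apparent (parallax-biased) hematocrit under a camera pose
#'
#' Projects a tube's three physical interface points (plug top, packed-cell
#' top, plasma top) through the pinhole model and applies the pixel-ratio
#' measurement to the projected rows. At nadir this recovers the true
#' hematocrit exactly (parallel rays preserve ratios of collinear points);
#' off-nadir poses foreshorten the far end of the column and bias the ratio,
#' which is the parallax error the capture gate exists to prevent.
#'
#' @param pose A [camera_pose()].
#' @param intr A [camera_intrinsics()]. The result is invariant to the focal
#'   length (ratios of collinear projections), so any valid intrinsics give
#'   the same value.
#' @param tube A [tube_spec()].
#' @return Apparent hematocrit in percent (unrounded).
#' @examples
#' tube <- tube_spec(true_hct_pct = 42)
#' apparent_hct(camera_pose(), camera_intrinsics(), tube)  # 42
#' apparent_hct(camera_pose(pitch_deg = 33, setback_cm = 10),
#'              camera_intrinsics(), tube)                 # biased upward
#' @export
apparent_hct <- function(pose, intr, tube) {
  stopifnot(inherits(tube, "tube_spec"))
  g <- tube_geometry(tube)
  rows <- vapply(
    list(g$y_plug_top, g$y_buffy, g$y_plasma_top),
    function(y) project_point(pose, intr, c(0, y, 0))[["row"]],
    numeric(1)
  )
  ms <- marker_set(lower_row = rows[1], buffy_row = rows[2], upper_row = rows[3])
  compute_hct(ms)$hct_raw
}
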