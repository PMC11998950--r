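# Shared fixtures: a wide-angle intrinsics/config pair for poses that swing
# the view far from the tube, and a cached nadir render used by several files.

wide_intrinsics <- function(cfg = render_config()) {
  camera_intrinsics(focal_px = 700, image_width_px = cfg$width_px,
                    image_height_px = cfg$height_px)
}

nadir_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- render_tube(tube_spec(true_hct_pct = 42), camera_pose(),
                            render_config())
    }
    cache
  }
})

# Independent projection oracle: explicit 3x4 homogeneous projection matrix
# P = K [R | -R C], evaluated by matrix multiplication on homogeneous
# coordinates (built from scratch, not via project_point's internals).
oracle_project <- function(pose, intr, pt) {
  d <- pi / 180
  rotx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), sin(a)), c(0, -sin(a), cos(a)))
  roty <- function(a) rbind(c(cos(a), 0, -sin(a)), c(0, 1, 0), c(sin(a), 0, cos(a)))
  rotz <- function(a) rbind(c(cos(a), sin(a), 0), c(-sin(a), cos(a), 0), c(0, 0, 1))
  base <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  r <- rotz(-pose$roll_deg * d) %*% rotx(pose$pitch_deg * d) %*%
    roty(pose$yaw_deg * d) %*% base
  cam <- c(0, -pose$setback_cm, pose$height_cm)
  k <- rbind(c(intr$focal_px, 0, intr$principal_point[1]),
             c(0, intr$focal_px, intr$principal_point[2]),
             c(0, 0, 1))
  p <- k %*% cbind(r, -r %*% cam)
  h <- as.numeric(p %*% c(pt, 1))
  c(col = h[1] / h[3], row = h[2] / h[3])
}

random_marker_set <- function() {
  upper <- runif(1, 0, 400)
  lower <- upper + runif(1, 10, 600)
  buffy <- runif(1, upper, lower)
  marker_set(lower_row = lower, buffy_row = buffy, upper_row = upper)
}
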