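test_that("rendering is deterministic for identical inputs and seed", {
  cfg <- render_config(noise_sd = 0.05, seed = 99)
  a <- render_tube(tube_spec(), camera_pose(), cfg)
  b <- render_tube(tube_spec(), camera_pose(), cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_markers, b$truth_markers)
  # a different seed changes the noise
  cfg2 <- render_config(noise_sd = 0.05, seed = 100)
  expect_false(identical(render_tube(tube_spec(), camera_pose(), cfg2)$image,
                         a$image))
})

test_that("noise-free zone boundaries coincide with truth markers within a pixel", {
  rs <- nadir_sample()
  img <- rs$image
  centre_col <- round(dim(img)[2] / 2)
  pal <- default_palette()
  col_at <- function(r) img[r, centre_col, ]
  zone_of <- function(r) {
    d <- vapply(pal, function(p) sqrt(sum((col_at(r) - p)^2)), numeric(1))
    names(which.min(d))
  }
  zones <- vapply(seq_len(dim(img)[1]), zone_of, character(1))
  scan_boundary <- function(a, b) {
    i <- which(zones[-length(zones)] == b & zones[-1] == a)
    (i[1] + i[1] + 1) / 2
  }
  expect_lt(abs(scan_boundary("plug", "rbc") - rs$truth_markers$lower_row), 1)
  expect_lt(abs(scan_boundary("rbc", "buffy") - rs$truth_markers$buffy_row), 1)
  expect_lt(abs(scan_boundary("plasma", "glass") - rs$truth_markers$upper_row), 1)
})

test_that("truth markers reproduce the true hematocrit at nadir", {
  rs <- nadir_sample()
  expect_equal(compute_hct(rs$truth_markers)$hct_raw, 42, tolerance = 1e-9)
  # quantisation-level agreement is all that is claimed in general
  res <- compute_hct(rs$truth_markers)$resolution_pct
  expect_lt(abs(compute_hct(rs$truth_markers)$hct_pct - 42), 100 * res)
})

test_that("a hematocrit-0 tube renders with buffy and lower markers coincident", {
  rs <- render_tube(tube_spec(true_hct_pct = 0, buffy_thickness_mm = 0),
                    camera_pose(), render_config())
  expect_equal(rs$truth_markers$buffy_row, rs$truth_markers$lower_row)
})

test_that("raster and analytic paths agree off-nadir (cross-oracle)", {
  pose <- camera_pose(33, setback_cm = 10)
  tube <- tube_spec(true_hct_pct = 42)
  rs <- render_tube(tube, pose, render_config())
  from_truth <- compute_hct(rs$truth_markers)
  analytic <- apparent_hct(pose, rs$intrinsics, tube)
  expect_lt(abs(from_truth$hct_raw - analytic), from_truth$resolution_pct)
  expect_false(isTRUE(all.equal(analytic, 42)))
})

test_that("cohorts are reproducible and respect the hematocrit range", {
  a <- render_cohort(5, c(38, 48), seed = 7)
  b <- render_cohort(5, c(38, 48), seed = 7)
  expect_length(a, 5)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  hcts <- vapply(a, function(s) s$tube$true_hct_pct, numeric(1))
  expect_true(all(hcts >= 38 & hcts <= 48))
  one <- render_cohort(1, c(42, 42), seed = 3)
  expect_equal(one[[1]]$tube$true_hct_pct, 42)
  expect_error(render_cohort(3, c(50, 40)), class = "microhct_invalid_config")
})

test_that("cohort truth markers recover true hematocrit to quantisation accuracy", {
  cohort <- render_cohort(10, c(38, 48), seed = 11)
  errs <- vapply(cohort, function(s) {
    r <- compute_hct(s$truth_markers)
    abs(r$hct_raw - s$tube$true_hct_pct)
  }, numeric(1))
  px_equiv <- compute_hct(cohort[[1]]$truth_markers)$resolution_pct
  expect_lt(mean(errs), px_equiv)
})

test_that("parallax bias grows monotonically with pitch at fixed setback", {
  cfg <- render_config()
  intr <- wide_intrinsics(cfg)
  biases <- vapply(c(0, 10, 20, 30, 40), function(p) {
    rs <- render_tube(tube_spec(true_hct_pct = 42),
                      camera_pose(p, setback_cm = 10), cfg, intr = intr)
    abs(compute_hct(rs$truth_markers)$hct_raw - 42)
  }, numeric(1))
  expect_true(all(diff(biases) >= -1e-9))
})

test_that("a pose that frames out the sample column raises a framing error", {
  expect_error(
    render_tube(tube_spec(), camera_pose(pitch_deg = 40), render_config()),
    class = "microhct_framing_error"
  )
})

test_that("PNG plus sidecar round-trips a rendered sample", {
  rs <- render_tube(tube_spec(true_hct_pct = 45),
                    camera_pose(10, setback_cm = 3.4),
                    render_config(noise_sd = 0.02, seed = 12))
  path <- file.path(withr::local_tempdir(), "tube.png")
  write_rendered_sample(rs, path)
  back <- read_rendered_sample(path)
  expect_equal(back$truth_markers$lower_row, rs$truth_markers$lower_row)
  expect_equal(back$tube$true_hct_pct, 45)
  expect_equal(back$pose$pitch_deg, 10)
  # PNG stores 8-bit channels: equal to within one grey level
  expect_lt(max(abs(back$image - rs$image)), 1 / 255)
})
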