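test_that("pixel-ratio hematocrit matches the worked example and boundaries", {
  r <- compute_hct(marker_set(900, 450, 100))
  expect_equal(r$hct_raw, 56.25)
  expect_equal(r$hct_pct, 56.3)   # reported value rounds half-up to 0.1
  expect_equal(r$blood_px, 450)
  expect_equal(r$total_px, 800)
  expect_equal(r$resolution_pct, 100 / 800)
  expect_equal(compute_hct(marker_set(900, 900, 100))$hct_pct, 0)
  expect_equal(compute_hct(marker_set(900, 100, 100))$hct_pct, 100)
})

test_that("marker sets enforce ordering", {
  expect_error(marker_set(100, 50, 200), class = "microhct_degenerate_sample")
  expect_error(marker_set(300, 400, 100), class = "microhct_marker_order")
  expect_error(marker_set(300, 50, 100), class = "microhct_marker_order")
})

test_that("hematocrit is invariant to translation, zoom and row-axis mirroring", {
  withr::local_seed(17)
  for (i in 1:1000) {
    m <- random_marker_set()
    h <- compute_hct(m)$hct_raw
    expect_true(h >= 0 && h <= 100)
    k <- runif(1, 0.1, 10)
    c0 <- runif(1, -50, 1000)
    zoomed <- marker_set(m$lower_row * k + c0, m$buffy_row * k + c0,
                         m$upper_row * k + c0)
    expect_equal(compute_hct(zoomed)$hct_raw, h, tolerance = 1e-9)
    # mirror: rows r -> C - r flips which physical end is "up";
    # the complementary marker roles restore the same reading
    cc <- 2000
    mirrored <- marker_set(cc - m$upper_row,
                           cc - m$upper_row - (m$lower_row - m$buffy_row),
                           cc - m$lower_row)
    expect_equal(compute_hct(mirrored)$hct_raw, h, tolerance = 1e-9)
  }
})

test_that("screen resolution model reproduces the printed increments", {
  expect_equal(round(hct_resolution(586, 0.75), 2), 0.23)
  expect_equal(round(hct_resolution(932, 0.75), 1), 0.1)
  expect_equal(hct_resolution(1000, 1), 0.1)
})

test_that("resolution is strictly decreasing in viewport and occupancy", {
  expect_lt(hct_resolution(800, 0.75), hct_resolution(600, 0.75))
  expect_lt(hct_resolution(600, 0.9), hct_resolution(600, 0.5))
  expect_error(hct_resolution(600, 0), class = "microhct_invalid_argument")
  expect_error(hct_resolution(600, 1.2), class = "microhct_invalid_argument")
  expect_error(hct_resolution(0, 0.5), class = "microhct_invalid_argument")
})

test_that("rotation buttons step by exactly half a degree", {
  a <- adjustment()
  expect_equal(rotate_step(a, "right")$rotation_deg, 0.5)
  left3 <- rotate_step(rotate_step(rotate_step(a, "left"), "left"), "left")
  expect_equal(left3$rotation_deg, -1.5)
  withr::local_seed(5)
  acc <- a
  for (i in 1:50) {
    acc <- rotate_step(acc, sample(c("left", "right"), 1))
  }
  expect_equal(acc$rotation_deg %% 0.5, 0)
  expect_error(adjustment(rotation_deg = 0.3), class = "microhct_invalid_adjustment")
  expect_error(adjustment(zoom = 0.5), class = "microhct_invalid_adjustment")
})

test_that("identity adjustment returns the raster byte-identical", {
  img <- nadir_sample()$image
  expect_identical(apply_adjustment(img, adjustment()), img)
})

test_that("rotating +0.5 then -0.5 degrees is a near-inverse", {
  img <- nadir_sample()$image
  bg <- default_palette()$background
  once <- apply_adjustment(img, adjustment(rotation_deg = 0.5), bg = bg)
  back <- apply_adjustment(once, adjustment(rotation_deg = -0.5), bg = bg)
  # bilinear interpolation blurs edges; away from the few interface rows the
  # round trip is close to identity
  expect_lt(mean(abs(back - img)), 0.01)
})

test_that("rotation is disabled while zoomed", {
  img <- nadir_sample()$image
  expect_error(apply_adjustment(img, adjustment(rotation_deg = 0.5, zoom = 2)),
               class = "microhct_state_error")
  zoomed <- apply_adjustment(img, adjustment(zoom = 1.5))
  expect_identical(dim(zoomed), dim(img))
})

test_that("counter-rotating a rolled capture straightens the tube", {
  rs <- render_tube(tube_spec(), camera_pose(roll_deg = 2), render_config())
  expect_gt(abs(locate_tube_axis(rs$image)$angle_deg), 1.5)
  fixed <- apply_adjustment(rs$image, adjustment(rotation_deg = -2),
                            bg = default_palette()$background)
  expect_lt(abs(locate_tube_axis(fixed)$angle_deg), 0.5)
})
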