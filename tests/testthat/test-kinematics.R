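test_that("ballistic reconstruction matches the numerical projectile oracle", {
  k <- compute_kinematics(0.4, 0.2)
  expect_equal(k$v_h, 2.0)
  expect_equal(k$v_v, 0.98)
  expect_equal(k$takeoff_speed, 2.22719554597256, tolerance = 1e-12)
  expect_equal(k$takeoff_angle_deg, 26.1048540090993, tolerance = 1e-10)
  expect_equal(k$jump_height_m, 0.049)
  # independent check: a projectile launched with (v_h, v_v) lands at the
  # observed displacement after the observed airborne time
  o <- projectile_landing(k$v_h, k$v_v)
  expect_equal(o$airborne_s, 0.2, tolerance = 1e-6)
  expect_equal(o$displacement_m, 0.4, tolerance = 1e-6)
})

test_that("zero displacement is the vertical-jump limit, not an error", {
  k <- compute_kinematics(0, 0.2)
  expect_equal(k$v_h, 0)
  expect_equal(k$takeoff_angle_deg, 90)
  expect_equal(k$takeoff_speed, 0.98)
  expect_equal(k$v_v, 0.98)
})

test_that("invalid observations are rejected", {
  expect_error(compute_kinematics(1.0, 0), "airborne_s")
  expect_error(compute_kinematics(-0.1, 0.2), "displacement")
  expect_error(forward_ballistics(0, 45), "speed")
  expect_error(forward_ballistics(2, 0), "angle")
  expect_error(forward_ballistics(2, 91), "angle")
})

test_that("forward ballistics matches the integration oracle and the 90-degree limit", {
  fb <- forward_ballistics(2.0, 45)
  expect_equal(fb$airborne_s, 0.288615012725595, tolerance = 1e-9)
  expect_equal(fb$displacement_m, 0.408163265301020, tolerance = 1e-9)
  o <- projectile_landing(2 * cos(pi / 4), 2 * sin(pi / 4))
  expect_equal(fb$airborne_s, o$airborne_s, tolerance = 1e-6)
  expect_equal(fb$displacement_m, o$displacement_m, tolerance = 1e-6)
  expect_equal(forward_ballistics(2.5, 90)$displacement_m, 0)
})

test_that("round trip forward -> inverse recovers speed and angle on a dense grid", {
  speeds <- seq(0.1, 5, length.out = 30)
  angles <- seq(1, 90, length.out = 45)
  grid <- expand.grid(speed = speeds, angle = angles)
  fb <- forward_ballistics(grid$speed, grid$angle)
  k <- compute_kinematics(fb$displacement_m, fb$airborne_s)
  expect_lt(max(abs(k$takeoff_speed - grid$speed) / grid$speed), 1e-9)
  expect_lt(max(abs(k$takeoff_angle_deg - grid$angle) / grid$angle), 1e-9)
})

test_that("jump height depends only on airborne time (g t^2 / 8)", {
  t <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  d <- c(0, 0.1, 0.6, 0.2, 1.4)
  k <- compute_kinematics(d, t)
  expect_equal(k$jump_height_m, 9.8 * t^2 / 8, tolerance = 1e-12)
  # and the speed/angle invariants hold
  expect_equal(k$takeoff_speed^2, k$v_h^2 + k$v_v^2, tolerance = 1e-12)
  expect_true(all(k$takeoff_angle_deg >= 0 & k$takeoff_angle_deg <= 90))
})

test_that("at fixed airborne time, speed rises and angle falls with displacement", {
  d <- seq(0, 2, by = 0.1)
  k <- compute_kinematics(d, 0.25)
  expect_true(all(diff(k$takeoff_speed) > 0))
  expect_true(all(diff(k$takeoff_angle_deg) < 0))
})

test_that("frame-period conversion reproduces the published per-rate periods", {
  expect_equal(round(frames_to_ms(1, 120), 1), 8.3)
  expect_equal(frames_to_ms(1, 250), 4.0)
  expect_equal(round(frames_to_ms(1, 240), 1), 4.2)
  expect_equal(frames_to_ms(0, 120), 0)
  expect_equal(frames_to_ms(10, 250), 40)
  expect_error(frames_to_ms(1, 0), "fps")
  expect_error(frames_to_ms(-1, 250), "frames")
})

test_that("down-sampling halves indices with floor and preserves event order", {
  expect_identical(downsample_frames(10, 500, 250), 5L)
  expect_identical(downsample_frames(11, 500, 250), 5L)
  seqs <- sort(sample.int(1000, 50))
  down <- downsample_frames(seqs, 500, 250)
  expect_true(all(diff(down) >= 0))
  # event times move by less than one target-frame period
  expect_true(all(abs(seqs / 500 - down / 250) < 1 / 250))
  expect_error(downsample_frames(10, 500, 240), "multiple")
})

test_that("event-frame timing yields reaction, take-off and overall times", {
  t <- timing_from_frames(0, 3, 10, fps = 250)
  expect_equal(t$reaction_ms, 12)
  expect_equal(t$takeoff_ms, 28)
  expect_equal(t$overall_ms, 40)
  expect_equal(timing_from_frames(0, 0, 5, 250)$reaction_ms, 0)
  expect_error(timing_from_frames(5, 3, 10, 250), "premature")
  expect_error(timing_from_frames(0, 6, 5, 250), "toeoff")
})
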