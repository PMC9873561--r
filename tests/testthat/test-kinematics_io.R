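test_that("CSV dialect round-trips recordings", {
  set.seed(3)
  rec <- make_recording(5)
  rec$joint_angles[] <- rnorm(5 * 66, sd = 20)
  rec$segment_positions[] <- rnorm(5 * 69, sd = 0.5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_recording_csv(rec, path)
  back <- load_recording(path, "csv")
  expect_equal(nrow(back$joint_angles), 5)
  expect_equal(back$sample_rate, 60)
  expect_equal(back$joint_angles, rec$joint_angles, tolerance = 1e-9)
  expect_equal(back$segment_positions, rec$segment_positions, tolerance = 1e-9)
})

test_that("smallest valid CSV loads and schema violations name the column", {
  rec <- make_recording(2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_recording_csv(rec, path)
  expect_equal(nrow(load_recording(path, "csv")$joint_angles), 2)

  df <- data.table::fread(path, data.table = FALSE)
  df[["LeftKnee_Z_deg"]] <- NULL
  data.table::fwrite(df, path)
  expect_error(load_recording(path, "csv"), "LeftKnee_Z_deg")
})

test_that("MVNX subset reader enforces the 22-joint/23-segment model", {
  path <- tempfile(fileext = ".mvnx")
  on.exit(unlink(path))
  write_mvnx_fixture(path, n_frames = 3)
  rec <- load_recording(path, "mvnx_subset")
  expect_length(rec$skeleton$joint_names, 22)
  expect_length(rec$skeleton$segment_names, 23)
  expect_equal(nrow(rec$joint_angles), 3)  # calibration frame skipped
  expect_equal(rec$sample_rate, 60)

  bad <- tempfile(fileext = ".mvnx")
  on.exit(unlink(bad), add = TRUE)
  write_mvnx_fixture(bad, n_segments = 22)
  expect_error(load_recording(bad, "mvnx_subset"), "schema error")
})

test_that("gaps up to 0.5 s are linearly interpolated, longer gaps rejected", {
  ang <- matrix(0, 200, 66, dimnames = list(NULL, kinedmd:::joint_angle_cols()))
  pos <- matrix(0, 200, 69, dimnames = list(NULL, kinedmd:::segment_position_cols()))
  ang[, 1] <- seq_len(200)
  ang[101:110, 1] <- NA  # 10 frames < 30-frame limit
  rec <- new_recording(ang, pos)
  expect_equal(rec$joint_angles[101:110, 1], 101:110)  # linear bridge is exact

  ang[101:140, 1] <- NA  # 40 frames > limit
  expect_error(new_recording(ang, pos), "gap")
})

test_that("smoothing is a centered moving average with shrinking edges", {
  rec <- make_recording(101, angles = list(RightHip_Z_deg = rep(5, 101)))
  expect_equal(smooth_recording(rec)$joint_angles[, "RightHip_Z_deg"],
               rep(5, 101))  # constant invariance (and idempotence)

  imp <- numeric(101); imp[51] <- 1
  rec <- make_recording(101, angles = list(RightHip_Z_deg = imp))
  sm <- smooth_recording(rec, 21)$joint_angles[, "RightHip_Z_deg"]
  expect_equal(sm[41:61], rep(1 / 21, 21))  # box-kernel plateau
  expect_equal(sum(sm), 1)

  expect_error(smooth_recording(rec, 20), "odd")
  expect_identical(eval(formals(smooth_recording)$window), 21L)

  set.seed(4)
  rec <- make_recording(200, angles = list(LeftElbow_Z_deg = rnorm(200)))
  sm <- smooth_recording(rec)$joint_angles[, "LeftElbow_Z_deg"]
  raw <- rec$joint_angles[, "LeftElbow_Z_deg"]
  expect_gte(min(sm), min(raw))  # smoothing never widens the range
  expect_lte(max(sm), max(raw))
  expect_equal(nrow(smooth_recording(rec)$joint_angles), 200)
})

test_that("differentiation applies central differences at the sample rate", {
  n <- 120
  rec <- make_recording(n, angles = list(RightKnee_Z_deg = seq_len(n)))  # 1 deg/frame
  der <- differentiate(rec)
  expect_equal(der$joint_angular_velocity[2:(n - 1), "RightKnee_Z_deg"],
               rep(60, n - 2))  # 1 deg/frame at 60 Hz
  expect_equal(der$segment_linear_velocity[, "Pelvis_x_m"], rep(0, n))
  expect_equal(der$segment_linear_acceleration[, "Pelvis_x_m"], rep(0, n))

  # sinusoid: interior acceleration amplitude ~ A (2 pi f)^2 within 2%
  A <- 0.1; f <- 1; fs <- 60; t <- (0:(fs * 10 - 1)) / fs
  rec <- make_recording(length(t),
                        positions = list(RightHand_x_m = A * sin(2 * pi * f * t)))
  acc <- differentiate(rec)$segment_linear_acceleration[, "RightHand_x_m"]
  expect_equal(max(abs(acc[30:(length(t) - 30)])), A * (2 * pi * f)^2,
               tolerance = 0.02)

  expect_error(differentiate(make_recording(2)), ">= 3 frames")
})

test_that("derivatives of a smoothed recording stay finite", {
  set.seed(5)
  rec <- make_recording(300, angles = list(LeftHip_X_deg = rnorm(300, sd = 30)),
                        positions = list(LeftFoot_z_m = cumsum(rnorm(300, sd = 0.01))))
  der <- differentiate(smooth_recording(rec))
  expect_true(all(is.finite(der$joint_angular_velocity)))
  expect_true(all(is.finite(der$segment_linear_acceleration)))
})
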