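test_that("workspace volume counts occupied 2-cm voxels times 8 cm^3", {
  n <- 120
  # everything resting exactly at the pelvis: one voxel
  rec <- make_recording(n, positions = uniform_positions(n, function(n)
    matrix(0.005, n, 3)))
  expect_equal(unname(compute_workspace_volume(rec)), c(8, 8, 8))

  # whole body alternating between two known distinct voxels
  x <- rep(c(0.005, 0.045), length.out = n)  # cells 0 and 2 (2-cm grid)
  rec2 <- make_recording(n, positions = uniform_positions(n, function(n)
    cbind(x, 0.005, 0.005)))
  expect_equal(compute_workspace_volume(rec2)[["wsvol_full"]], 16)

  # union of voxel sets is no larger than the sum of the parts
  set.seed(8)
  rec3 <- make_recording(200)
  rec3$segment_positions[] <- rnorm(200 * 69, sd = 0.3)
  v <- compute_workspace_volume(rec3)
  expect_lte(v[["wsvol_full"]], v[["wsvol_upper"]] + v[["wsvol_lower"]])

  expect_error(compute_workspace_volume(make_recording(0)))
})

test_that("workspace volume is invariant to rigid whole-body translation", {
  set.seed(9)
  rec <- make_recording(150)
  rec$segment_positions[] <- rnorm(150 * 69, sd = 0.2)
  shifted <- rec
  drift <- cbind(seq(0, 3, length.out = 150),
                 seq(0, -2, length.out = 150),
                 seq(0, 1, length.out = 150))
  for (seg in default_skeleton()$segment_names) {
    idx <- kinedmd:::segment_cols_idx(seg)
    shifted$segment_positions[, idx] <- shifted$segment_positions[, idx] + drift
  }
  expect_equal(compute_workspace_volume(shifted), compute_workspace_volume(rec))
  expect_equal(compute_hip_orbit_area(shifted), compute_hip_orbit_area(rec))
})

test_that("hip orbit area matches a brute-force cell-count oracle", {
  n <- 120
  rec <- make_recording(n)  # stationary: one 4-cm^2 cell per plane
  expect_equal(unname(compute_hip_orbit_area(rec)), c(4, 4, 4))

  # circular orbit of radius 6 cm in the sagittal (x-z) plane
  n <- 2000
  th <- seq(0, 2 * pi, length.out = n)
  r_m <- 0.06
  rec <- make_recording(n, positions = list(
    RightUpperLeg_x_m = r_m * cos(th), RightUpperLeg_z_m = r_m * sin(th)))
  area <- compute_hip_orbit_area(rec)
  # independent oracle: enumerate the 2x2 cm cells the sampled ring visits
  cells <- unique(paste(floor(r_m * 100 * cos(th) / 2),
                        floor(r_m * 100 * sin(th) / 2)))
  expect_equal(area[["hiporbit_sagittal"]], 4 * length(cells))

  rec2 <- make_recording(n, positions = list(
    RightUpperLeg_x_m = 2 * r_m * cos(th), RightUpperLeg_z_m = 2 * r_m * sin(th)))
  expect_true(all(compute_hip_orbit_area(rec2) >= area))  # monotone occupancy
})

test_that("extremity speed statistics follow the Euclidean magnitude", {
  n <- 300
  der <- differentiate(make_recording(n))
  st <- compute_extremity_velocity_stats(der)
  expect_length(st, 8)
  expect_equal(unname(st), rep(0, 8))  # stationary extremities

  t <- (0:(n - 1)) / 60
  rec <- make_recording(n, positions = list(RightHand_x_m = 0.3 * t,
                                            RightHand_y_m = 0.4 * t))
  st <- compute_extremity_velocity_stats(differentiate(rec))
  expect_equal(st[["extvel_RightHand_mean"]], 0.5)  # 3-4-5 norm
  expect_equal(st[["extvel_RightHand_var"]], 0)

  # speeds scale linearly under time-uniform velocity scaling
  rec2 <- rec
  rec2$segment_positions <- rec$segment_positions * 3
  st2 <- compute_extremity_velocity_stats(differentiate(rec2))
  expect_equal(st2[["extvel_RightHand_mean"]], 3 * st[["extvel_RightHand_mean"]])
})

test_that("average joint velocity is the mean absolute angular velocity", {
  n <- 300
  expect_equal(max(abs(compute_avg_joint_velocity(differentiate(make_recording(n))))), 0)
  rec <- make_recording(n, angles = list(RightHip_Z_deg = 0.5 * seq_len(n)))  # 30 deg/s
  av <- compute_avg_joint_velocity(differentiate(rec))
  expect_length(av, 9)
  expect_equal(av[["avgjv_RightHip_Z_deg"]], 30, tolerance = 0.01)
})

test_that("autocorrelation FWHM matches the closed-form sinusoid value", {
  n <- 1800  # 30 s at 60 Hz
  t <- (0:(n - 1)) / 60
  rec <- make_recording(n, angles = list(LeftKnee_Z_deg = sin(2 * pi * t / 3)))
  fw <- compute_autocorr_fwhm(differentiate(rec))
  expect_length(fw, 17)
  # velocity is cos(2 pi t / 3): autocorr cos(2 pi tau / 3), FWHM = 1 s
  expect_equal(fw[["acffwhm_LeftKnee_Z_deg"]], 1, tolerance = 2 / 60)
  # every silent channel hits the 20-s cap
  expect_equal(fw[["acffwhm_RightWrist_Z_deg"]], 20)

  set.seed(11)
  recw <- make_recording(n, angles = list(LeftKnee_Z_deg = cumsum(rnorm(n))))
  fww <- compute_autocorr_fwhm(differentiate(recw))
  # white noise decorrelates within a couple of samples (central differences
  # leave an MA(1) trace, so the crossing sits just past one lag)
  expect_lte(fww[["acffwhm_LeftKnee_Z_deg"]], 2.5 / 60)

  expect_error(compute_autocorr_fwhm(differentiate(make_recording(600))), "twice")
})

test_that("logistic scale fit recovers a known generator and handles degeneracy", {
  set.seed(12)
  x <- rlogis(1e5, location = 0, scale = 2)
  s <- fit_logistic_scale(x)
  expect_gt(s, 1.9); expect_lt(s, 2.1)
  expect_equal(fit_logistic_scale(rep(3, 2000)), 0)

  n <- 1500
  set.seed(13)
  rec <- make_recording(n, angles = list(RightElbow_Z_deg = cumsum(rnorm(n))))
  ls <- compute_logistic_scale(differentiate(rec))
  expect_length(ls, 8)
  expect_true(all(ls >= 0))
})

test_that("joint velocity correlations behave like Pearson r", {
  n <- 10000
  set.seed(14)
  a <- cumsum(rnorm(n)); b <- cumsum(rnorm(n))
  rec <- make_recording(n, angles = list(RightHip_Z_deg = a,
                                         RightKnee_Z_deg = -a,
                                         LeftHip_Z_deg = a,
                                         LeftKnee_Z_deg = b))
  cfg <- family_config(correlation_pairs = list(
    c("RightHip_Z_deg", "RightHip_Z_deg"),     # self: +1
    c("RightHip_Z_deg", "RightKnee_Z_deg"),    # negation: -1
    c("LeftHip_Z_deg", "LeftKnee_Z_deg")))     # independent: ~0
  r <- compute_joint_correlations(differentiate(rec), cfg)
  expect_equal(unname(r[1]), 1)
  expect_equal(unname(r[2]), -1)
  expect_lt(abs(r[3]), 0.05)
  r_def <- compute_joint_correlations(differentiate(rec))
  expect_length(r_def, 15)
  expect_true(all(r_def >= -1 & r_def <= 1))
})

test_that("histogram-threshold motion detection isolates the rest mode", {
  expect_false(any(detect_motion(numeric(5000))))
  expect_identical(eval(formals(detect_motion)$bins), 100L)

  set.seed(15)
  n <- 10000
  moving <- seq_len(n) <= 0.3 * n
  x <- ifelse(moving, 10 + rnorm(n), rnorm(n, sd = 0.05))
  frac <- mean(detect_motion(x))
  expect_equal(frac, 0.3, tolerance = 0.02 / 0.3)
})

test_that("duty cycle ORs the per-axis masks", {
  n <- 6000
  dc0 <- compute_duty_cycle(differentiate(make_recording(n)))
  expect_length(dc0, 15)
  expect_equal(unname(dc0), rep(0, 15))  # frozen joints

  # one axis moving 40% of the time at a clear velocity plateau
  vel <- ifelse(seq_len(n) <= 0.4 * n, 30, 0) + rnorm(n, sd = 0.05)
  rec <- make_recording(n, angles = list(RightElbow_X_deg = cumsum(vel) / 60))
  dc <- compute_duty_cycle(differentiate(rec))
  expect_equal(dc[["duty_RightElbow"]], 0.4, tolerance = 0.05)
  expect_true(all(dc >= 0 & dc <= 1))
})

test_that("segment acceleration statistics match the analytic sinusoid", {
  n <- 1800
  t <- (0:(n - 1)) / 60
  rec <- make_recording(n, positions = list(LeftFoot_x_m = 0.3 * t))  # constant v
  sa <- compute_segment_accel_stats(differentiate(rec))
  expect_length(sa, 9)
  expect_equal(sa[["segacc_LeftFoot_mean"]], 0, tolerance = 1e-8)
  expect_equal(sa[["segacc_LeftFoot_var"]], 0, tolerance = 1e-8)

  A <- 0.1; f <- 1
  rec <- make_recording(n, positions = list(RightHand_x_m = A * sin(2 * pi * f * t)))
  sa <- compute_segment_accel_stats(differentiate(rec))
  # mean |A w^2 cos| = (2/pi) A w^2
  expect_equal(sa[["segacc_RightHand_mean"]], (2 / pi) * A * (2 * pi * f)^2,
               tolerance = 0.03)
})

test_that("full extraction yields 87 deterministic named features", {
  rec <- generate_recording(list(subject_id = "S", group = "DMD"), 9, 45, seed = 21)
  fp1 <- extract_fingerprints(rec)
  fp2 <- extract_fingerprints(rec)
  expect_identical(fp1, fp2)
  expect_length(fp1, 87)
  expect_true(all(is.finite(fp1)))
  expect_equal(unname(attr(fp1, "families")),
               c(3L, 3L, 8L, 9L, 17L, 8L, 15L, 15L, 9L))
  expect_equal(sum(fingerprint_families()), 87L)
})

test_that("Kruskal-Wallis screening matches rank arithmetic", {
  # two identical groups: H = 0, p = 1
  X <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
  r0 <- kruskal_wallis_screen(X, c("A", "A", "A", "B", "B", "B"))
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)

  # fully separated groups
  X <- matrix(c(1:10, 101:110), ncol = 1, dimnames = list(NULL, "f"))
  r1 <- kruskal_wallis_screen(X, rep(c("A", "B"), each = 10))
  expect_lt(r1$p, 0.001)
  expect_equal(r1$df, 1)

  # medians per group are reported
  expect_named(r1, c("feature", "H", "df", "p", "median_A", "median_B"))
  expect_equal(r1$median_A, 5.5)
})

test_that("group medians on a default synthetic cohort match reported directions", {
  coh <- shared_cohort()
  is_dmd <- coh$manifest$group == "DMD"
  med <- function(col) {
    c(dmd = median(coh$features[is_dmd, col]),
      hc = median(coh$features[!is_dmd, col]))
  }
  for (col in c("wsvol_full", "extvel_RightHand_mean", "duty_RightKnee")) {
    m <- med(col)
    expect_lt(m[["dmd"]], m[["hc"]])
  }
  m <- med("acffwhm_RightKnee_Z_deg")
  expect_gt(m[["dmd"]], m[["hc"]])
})
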