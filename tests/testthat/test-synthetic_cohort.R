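test_that("cohort generation counts visits and is bit-reproducible", {
  cfg <- generator_config(n_dmd = 2L, n_hc = 2L, recording_duration_s = 30)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_equal(nrow(a$manifest), 2 * 3 + 2 * 2)  # DMD 0/6/12, HC 0/12
  expect_identical(a$manifest, b$manifest)
  vid <- a$manifest$visit_id[1]
  expect_identical(a$recordings[[vid]]$joint_angles,
                   b$recordings[[vid]]$joint_angles)
  expect_true(all(a$manifest$severity[a$manifest$group == "HC"] == 0))
})

test_that("recording frame count follows duration and severity slows movement", {
  prof <- list(subject_id = "S1", group = "DMD")
  rec <- generate_recording(prof, age = 10, duration_s = 60, seed = 5)
  expect_equal(nrow(rec$joint_angles), 3600)

  speed_of <- function(severity) {
    rec <- generate_recording(prof, 10, 120, seed = 5, severity = severity)
    st <- compute_extremity_velocity_stats(differentiate(smooth_recording(rec)))
    mean(st[grep("_mean$", names(st))])
  }
  expect_lt(speed_of(0.8), speed_of(0))  # same seed stream, strictly slower

  hip_mean <- function(severity) {
    rec <- generate_recording(prof, 10, 120, seed = 5, severity = severity)
    mean(rec$joint_angles[, "RightHip_Z_deg"])
  }
  shift <- hip_mean(0.8) - hip_mean(0)
  expect_equal(shift, generator_config()$hip_shift_deg * 0.8, tolerance = 0.25)
})

test_that("clinical scores respect the scale definitions", {
  prof <- list(subject_id = "S1", group = "DMD")
  sc <- generate_clinical_scores(prof, age = 20, seed = 1, severity = 1)
  expect_equal(sc$sixmwd_m, 0)
  expect_false(sc$ambulatory)

  quiet <- generator_config(noise_nsaa = 0, noise_sixmwd_m = 0,
                            noise_pul = 0, noise_myogrip = 0)
  sc0 <- generate_clinical_scores(prof, age = 8, seed = 1, config = quiet,
                                  severity = 0)
  expect_equal(sc0$nsaa, 34L)  # 17 activities x max grade 2
  expect_true(sc0$ambulatory)

  draws <- vapply(seq_len(500), function(i) {
    generate_clinical_scores(prof, 10, seed = i, severity = 0.5)$nsaa
  }, integer(1))
  expect_true(all(draws >= 0 & draws <= 34))

  mean_at <- function(s) {
    mean(vapply(seq_len(60), function(i) {
      sc <- generate_clinical_scores(prof, 10, seed = 1000 + i, severity = s)
      c(sc$nsaa + sc$pul + sc$myogrip_pct)
    }, numeric(1)))
  }
  expect_gt(mean_at(0.2), mean_at(0.8))  # monotone decreasing in expectation
})

test_that("fingerprints move monotonically with severity", {
  prof <- list(subject_id = "S1", group = "DMD")
  sev <- c(0, 0.25, 0.5, 0.75)
  fps <- vapply(sev, function(s) {
    fp <- extract_fingerprints(generate_recording(prof, 10, 45, seed = 42,
                                                  severity = s))
    c(speed = mean(fp[grep("extvel_.*_mean", names(fp))]),
      wsvol = fp[["wsvol_full"]],
      duty = mean(fp[grep("^duty_", names(fp))]),
      logscale = mean(fp[grep("^logscale_", names(fp))]),
      fwhm = mean(fp[grep("^acffwhm_", names(fp))]))
  }, numeric(5))
  n_inversions <- function(x) sum(diff(x) > 0)
  for (metric in c("speed", "wsvol", "duty", "logscale")) {
    expect_lte(n_inversions(fps[metric, ]), 1)  # non-increasing, <= 1 inversion
  }
  expect_lte(sum(diff(fps["fwhm", ]) < 0), 1)   # FWHM increases with severity
})

test_that("groups separate on mean extremity speed", {
  mean_speed <- function(group, id, seed) {
    prof <- list(subject_id = id, group = group)
    age <- runif(1, 5, 16)
    rec <- generate_recording(prof, age, 30, seed = seed)
    st <- compute_extremity_velocity_stats(differentiate(smooth_recording(rec)))
    mean(st[grep("_mean$", names(st))])
  }
  for (seed0 in c(101, 202, 303)) {
    set.seed(seed0)
    dmd <- vapply(1:15, function(i) mean_speed("DMD", paste0("D", i),
                                               seed0 * 100 + i), numeric(1))
    hc <- vapply(1:15, function(i) mean_speed("HC", paste0("H", i),
                                              seed0 * 100 + 50 + i), numeric(1))
    p <- kruskal.test(list(dmd, hc))$p.value
    expect_lt(p, 0.05)
  }
})
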