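#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: two groups (DMD and healthy controls), ages in childhood, visits
#' on a 6-monthly grid, and severity-dependent kinematics and clinical
#' scores. Severity follows the same tanh family as the progression
#' biomarker, with default truth `(alpha, beta) = (0.15, 1.8)` (a feasible
#' point of the age-5/age-15 clinical constraint boxes), which makes
#' biomarker parameter recovery a well-posed experiment.
#'
#' All effect sizes are per unit severity and are calibrated only to
#' reproduce the *direction* of the group differences seen in patients
#' (lower speeds, smaller workspace, hip-angle shift, stronger knee flexion,
#' lower duty cycle, smaller logistic velocity scale, weakened sagittal
#' anticorrelation, stronger coronal coupling) -- never any real cohort's
#' absolute values.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a list of class `kine_generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_dmd = 15L, n_hc = 15L,
    age_range_dmd = c(5, 16), age_range_hc = c(4, 16),
    visits_dmd = c(0, 6, 12), visits_hc = c(0, 12),
    recording_duration_s = 120,
    severity_alpha = 0.15, severity_beta = 1.8,
    ambul_threshold = 0.55,
    # kinematic effect sizes, per unit severity
    velocity_attenuation = 0.6,   # fractional amplitude loss at severity 1
    hip_shift_deg = 15,           # rightward hip flexion-angle shift
    knee_shift_deg = 10,          # stronger (more negative) knee flexion
    dutycycle_drop = 0.35,        # activity-gate duty loss
    logistic_scale_drop = 0.5,    # shrink of the velocity-noise scale
    coronal_coupling_gain = 0.6,  # left/right hip abduction coupling gain
    sagittal_anticorr_loss = 0.7, # loss of hip-knee sagittal anticorrelation
    freq_slowdown = 0.3,          # fractional oscillation slowdown
    nonambulant_attenuation = 0.25, # extra lower-body gain when non-ambulant
    base_duty = 0.55,             # healthy activity-gate duty
    velnoise_scale_deg_s = 2,     # logistic velocity-noise scale at severity 0
    # clinical score model
    sixmwd_max_m = 520, nsaa_max = 34L, pul_max = 42L,
    noise_sixmwd_m = 25, noise_nsaa = 1.5, noise_pul = 1.5, noise_myogrip = 5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              "unknown generator option(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  assert_that(cfg$n_dmd >= 1 && cfg$n_hc >= 1, "group counts must be >= 1")
  assert_that(all(c(cfg$velocity_attenuation, cfg$hip_shift_deg,
                    cfg$knee_shift_deg, cfg$dutycycle_drop,
                    cfg$logistic_scale_drop, cfg$coronal_coupling_gain,
                    cfg$sagittal_anticorr_loss) >= 0),
              "effect sizes must be >= 0")
  class(cfg) <- "kine_generator_config"
  cfg
}

#' Severity of a synthetic DMD subject at a given age
#'
#' Severity is the same normalised tanh progression curve used for the
#' biomarker: 0 at age 0, 1 at age 25, monotone in between. Healthy controls
#' have severity identically 0.
#'
#' @param age age in years, clamped to `[0, 25]`.
#' @param alpha,beta curve parameters (see [evaluate_biomarker()]).
#' @return severity in `[0, 1]`.
#' @export
severity_at_age <- function(age, alpha = 0.15, beta = 1.8) {
  evaluate_biomarker(pmin(pmax(age, 0), 25), alpha, beta)
}

#' Generate one synthetic kinematic recording
#'
#' The movement model is a sum of gated sinusoid oscillations: each channel
#' oscillates at subject-specific frequencies, switched on and off by a
#' two-state activity-bout gate, on top of a joint-specific baseline angle,
#' with additive logistic-distributed velocity noise integrated into the
#' angle streams. Severity scales oscillation amplitude and frequency,
#' lowers the gate duty, shifts the hip and knee baselines, shrinks the
#' velocity-noise scale, weakens the sagittal hip-knee anticorrelation and
#' strengthens the coronal hip-hip coupling. Non-ambulant severities
#' attenuate (never zero) the lower-body channels so upper-body features
#' stay informative.
#'
#' All random draws are made before any severity-dependent scaling, so two
#' calls with the same seed and different severities share the same
#' underlying noise stream.
#'
#' @param profile list with at least `subject_id`; optional `group`,
#'   `severity_params` (alpha, beta).
#' @param age age in years at the visit.
#' @param duration_s recording length in seconds (>= 30).
#' @param seed integer seed for this recording.
#' @param config a [generator_config()].
#' @param severity optional explicit severity in `[0, 1]`, overriding the
#'   profile curve (used by calibration experiments).
#' @return a `kine_recording` at 60 Hz.
#' @export
generate_recording <- function(profile, age, duration_s, seed,
                               config = generator_config(), severity = NULL) {
  assert_that(duration_s >= 30, "`duration_s` must be >= 30 s")
  fs <- 60
  n <- round(duration_s * fs)
  if (is.null(severity)) {
    sp <- profile$severity_params %||% c(config$severity_alpha, config$severity_beta)
    severity <- if (identical(profile$group, "HC")) 0
                else severity_at_age(age, sp[[1]], sp[[2]])
  }
  s <- severity
  ambulant <- s < config$ambul_threshold
  sk <- default_skeleton()
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs

  ## activity gate: 2-s blocks, on with probability = target duty; the same
  ## uniforms are thresholded for every severity so higher severity always
  ## yields a subset of the on-blocks
  duty <- min(max(config$base_duty - config$dutycycle_drop * s, 0.05), 0.95)
  block <- 2 * fs
  nb <- ceiling(n / block)
  u_gate <- runif(nb)
  gate <- rep(as.numeric(u_gate < duty), each = block)[seq_len(n)]
  gate <- moving_average(gate, 31L)  # soften bout edges

  amp_scale <- 1 - config$velocity_attenuation * s
  f_scale <- 1 - config$freq_slowdown * s
  lower_gain <- if (ambulant) 1 else config$nonambulant_attenuation

  osc <- function(amp, f_lo = 0.3, f_hi = 0.9, k = 2L) {
    f <- runif(k, f_lo, f_hi) * f_scale
    ph <- runif(k, 0, 2 * pi)
    w <- runif(k, 0.5, 1)
    amp * amp_scale * colSums(w * sin(outer(f * 2 * pi, t) + ph)) / sum(w)
  }

  ## ----- joint angles -----------------------------------------------------
  ang_cols <- joint_angle_cols(sk)
  ang <- matrix(0, n, 66L, dimnames = list(NULL, ang_cols))
  base_amp <- c(X = 10, Y = 8, Z = 25)
  lower_joints <- c("RightHip", "RightKnee", "RightAnkle", "RightBallFoot",
                    "LeftHip", "LeftKnee", "LeftAnkle", "LeftBallFoot")
  ## shared latents for coupling structure
  lat_sag <- list(Right = osc(1, 0.4, 0.8), Left = osc(1, 0.4, 0.8))
  lat_cor <- osc(1, 0.3, 0.7)
  w_anti <- 1 - config$sagittal_anticorr_loss * s  # surviving anticorrelation
  w_cor <- min(config$coronal_coupling_gain * s, 0.95)

  for (joint in sk$joint_names) {
    g_j <- if (joint %in% lower_joints) lower_gain else 1
    side <- if (startsWith(joint, "Right")) "Right"
            else if (startsWith(joint, "Left")) "Left" else ""
    for (axis in c("X", "Y", "Z")) {
      cn <- paste0(joint, "_", axis, "_deg")
      a0 <- base_amp[[axis]]
      own <- osc(a0)
      core <- if (axis == "Z" && joint %in% c("RightHip", "LeftHip")) {
        a0 * amp_scale * lat_sag[[side]]
      } else if (axis == "Z" && joint %in% c("RightKnee", "LeftKnee")) {
        a0 * amp_scale * (-w_anti * lat_sag[[side]]) +
          sqrt(max(1 - w_anti^2, 0)) * own
      } else if (axis == "X" && joint %in% c("RightHip", "LeftHip")) {
        a0 * amp_scale * w_cor * lat_cor + (1 - w_cor) * own
      } else own
      ang[, cn] <- core * g_j * gate
    }
  }
  ## baselines and severity shifts
  ang[, "RightElbow_Z_deg"] <- ang[, "RightElbow_Z_deg"] + 45
  ang[, "LeftElbow_Z_deg"] <- ang[, "LeftElbow_Z_deg"] + 45
  for (hip in c("RightHip_Z_deg", "LeftHip_Z_deg")) {
    ang[, hip] <- ang[, hip] + config$hip_shift_deg * s
  }
  for (knee in c("RightKnee_Z_deg", "LeftKnee_Z_deg")) {
    ang[, knee] <- ang[, knee] - config$knee_shift_deg * s
  }
  ## integrated logistic velocity noise (leaky integration keeps angles
  ## bounded); mostly gated so rest periods stay quiet for the motion detector
  sig <- config$velnoise_scale_deg_s * (1 - config$logistic_scale_drop * s)
  eta <- matrix(rlogis(n * 66L), n, 66L) * (sig / fs) * (0.1 + 0.9 * gate)
  drift <- apply_cols(eta, function(e) stats::filter(e, 0.98, "recursive"))
  ang <- ang + drift

  ## ----- segment positions ------------------------------------------------
  pos_cols <- segment_position_cols(sk)
  pos <- matrix(0, n, 69L, dimnames = list(NULL, pos_cols))
  offsets <- segment_offsets()
  pos_amp <- segment_pos_amplitudes()
  lower_segs <- lower_body_segments()
  pelvis_wander <- cbind(osc(0.8, 0.1, 0.3), osc(0.8, 0.1, 0.3), osc(0.1, 0.1, 0.3))
  pelvis_wander <- pelvis_wander * gate
  for (seg in sk$segment_names) {
    idx <- segment_cols_idx(seg, sk)
    g_s <- if (seg %in% lower_segs) lower_gain else 1
    a <- pos_amp[[seg]]
    seg_osc <- if (seg == "Pelvis") matrix(0, n, 3)
               else cbind(osc(a), osc(a), osc(a * 0.6)) * g_s * gate
    noise <- matrix(rnorm(n * 3L), n, 3L) * 0.003
    noise <- apply_cols(noise, function(e) stats::filter(e, 0.9, "recursive")) * 0.5
    pos[, idx] <- pelvis_wander + matrix(offsets[[seg]], n, 3, byrow = TRUE) +
      seg_osc + noise
  }

  new_recording(ang, pos,
                subject_id = profile$subject_id %||% "S", visit_id = profile$visit_id %||% "V",
                sample_rate = fs, skeleton = sk)
}

# crude static body layout (meters, pelvis at origin): x forward, y left, z up
segment_offsets <- function() {
  list(
    Pelvis = c(0, 0, 0), L5 = c(0, 0, 0.10), L3 = c(0, 0, 0.18),
    T12 = c(0, 0, 0.26), T8 = c(0, 0, 0.34), Neck = c(0, 0, 0.46),
    Head = c(0, 0, 0.58),
    RightShoulder = c(0, -0.08, 0.42), RightUpperArm = c(0, -0.18, 0.40),
    RightForearm = c(0.02, -0.20, 0.16), RightHand = c(0.05, -0.22, -0.05),
    LeftShoulder = c(0, 0.08, 0.42), LeftUpperArm = c(0, 0.18, 0.40),
    LeftForearm = c(0.02, 0.20, 0.16), LeftHand = c(0.05, 0.22, -0.05),
    RightUpperLeg = c(0, -0.09, -0.05), RightLowerLeg = c(0, -0.10, -0.45),
    RightFoot = c(0.05, -0.10, -0.85), RightToe = c(0.15, -0.10, -0.88),
    LeftUpperLeg = c(0, 0.09, -0.05), LeftLowerLeg = c(0, 0.10, -0.45),
    LeftFoot = c(0.05, 0.10, -0.85), LeftToe = c(0.15, 0.10, -0.88))
}

segment_pos_amplitudes <- function() {
  list(
    Pelvis = 0, L5 = 0.03, L3 = 0.03, T12 = 0.04, T8 = 0.04, Neck = 0.04,
    Head = 0.05,
    RightShoulder = 0.05, RightUpperArm = 0.10, RightForearm = 0.16,
    RightHand = 0.25,
    LeftShoulder = 0.05, LeftUpperArm = 0.10, LeftForearm = 0.16,
    LeftHand = 0.25,
    RightUpperLeg = 0.05, RightLowerLeg = 0.12, RightFoot = 0.16,
    RightToe = 0.16,
    LeftUpperLeg = 0.05, LeftLowerLeg = 0.12, LeftFoot = 0.16, LeftToe = 0.16)
}

#' Generate synthetic clinical scores for one visit
#'
#' Scores decrease with severity in expectation, with Gaussian noise and
#' the scales' ceiling/floor effects: NSAA is an integer in `[0, 34]`
#' (17 activities graded 0-2), PUL an integer in `[0, pul_max]`, 6MWD is
#' non-negative meters and 0 for non-ambulant visits, MyoGrip a percent
#' predicted. Ambulatory status is `severity < ambul_threshold`.
#'
#' @param profile list with `subject_id`, `group`, optional `severity_params`.
#' @param age age in years.
#' @param seed integer seed for the score noise.
#' @param config a [generator_config()].
#' @param severity optional explicit severity.
#' @return a one-row `data.frame` with columns `sixmwd_m, nsaa, pul,
#'   myogrip_pct, ambulatory, severity`.
#' @export
generate_clinical_scores <- function(profile, age, seed,
                                     config = generator_config(),
                                     severity = NULL) {
  if (is.null(severity)) {
    sp <- profile$severity_params %||% c(config$severity_alpha, config$severity_beta)
    severity <- if (identical(profile$group, "HC")) 0
                else severity_at_age(age, sp[[1]], sp[[2]])
  }
  s <- severity
  set.seed(seed)
  eps <- rnorm(4)
  ambulatory <- s < config$ambul_threshold
  nsaa <- round(config$nsaa_max * (1 - s) + eps[1] * config$noise_nsaa)
  nsaa <- as.integer(min(max(nsaa, 0), config$nsaa_max))
  sixmwd <- if (!ambulatory) 0 else
    max(config$sixmwd_max_m * (1 - s) + eps[2] * config$noise_sixmwd_m, 0)
  pul <- round(config$pul_max * (1 - 0.9 * s^1.1) + eps[3] * config$noise_pul)
  pul <- as.integer(min(max(pul, 0), config$pul_max))
  myogrip <- min(max(100 * (1 - 0.85 * s) + eps[4] * config$noise_myogrip, 0), 120)
  data.frame(sixmwd_m = sixmwd, nsaa = nsaa, pul = pul,
             myogrip_pct = myogrip, ambulatory = ambulatory, severity = s)
}

#' Generate a full synthetic cohort
#'
#' Draws subject profiles (group, baseline age), then one recording and one
#' clinical-score row per subject-visit. DMD subjects are seen at 0, 6 and
#' 12 months; controls at 0 and 12 months (configurable). Each subject-visit
#' uses named substreams of the base seed (kinematics vs scores), so the
#' whole cohort is bit-reproducible from `(config, seed)`.
#'
#' @param config a [generator_config()].
#' @param seed integer base seed.
#' @param out_dir optional directory; when given, per-visit recording CSVs
#'   and `manifest.csv` are written there and recordings are not kept in
#'   memory.
#' @param keep_recordings keep generated recordings in the returned list
#'   (default `TRUE` when `out_dir` is `NULL`).
#' @return list with `manifest` (data.frame) and `recordings` (named list of
#'   `kine_recording`, or `NULL` when written to disk).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1,
                            out_dir = NULL,
                            keep_recordings = is.null(out_dir)) {
  set.seed(derive_seed(seed, "profiles"))
  profiles <- list()
  for (i in seq_len(config$n_dmd)) {
    profiles[[length(profiles) + 1L]] <- list(
      subject_id = sprintf("DMD%02d", i), group = "DMD",
      baseline_age = round(runif(1, config$age_range_dmd[1], config$age_range_dmd[2]), 2),
      visit_months = config$visits_dmd,
      severity_params = c(config$severity_alpha, config$severity_beta))
  }
  for (i in seq_len(config$n_hc)) {
    profiles[[length(profiles) + 1L]] <- list(
      subject_id = sprintf("HC%02d", i), group = "HC",
      baseline_age = round(runif(1, config$age_range_hc[1], config$age_range_hc[2]), 2),
      visit_months = config$visits_hc,
      severity_params = c(config$severity_alpha, config$severity_beta))
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  recordings <- list()
  for (p in profiles) {
    for (m in p$visit_months) {
      age <- p$baseline_age + m / 12
      visit_id <- sprintf("%s_m%02d", p$subject_id, m)
      kin_seed <- derive_seed(seed, p$subject_id, m, "kinematics")
      score_seed <- derive_seed(seed, p$subject_id, m, "scores")
      prof <- c(p, list(visit_id = visit_id))
      scores <- generate_clinical_scores(prof, age, score_seed, config)
      rec_path <- NA_character_
      rec <- generate_recording(prof, age, config$recording_duration_s,
                                kin_seed, config)
      if (!is.null(out_dir)) {
        rec_path <- file.path(out_dir, "recordings", paste0(visit_id, ".csv"))
        write_recording_csv(rec, rec_path)
      }
      if (keep_recordings) recordings[[visit_id]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = p$subject_id, visit_id = visit_id, group = p$group,
        age_years = round(age, 4), visit_month = m,
        ambulatory = scores$ambulatory, nsaa = scores$nsaa,
        sixmwd_m = round(scores$sixmwd_m, 2), pul = scores$pul,
        myogrip_pct = round(scores$myogrip_pct, 2),
        recording_path = rec_path, severity = round(scores$severity, 6))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(manifest = manifest,
       recordings = if (keep_recordings) recordings else NULL)
}
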