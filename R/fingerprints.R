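#' Default fingerprint family configuration
#'
#' Nine feature families are computed per recording; under the default
#' configuration their dimensions are 3, 3, 8, 9, 17, 8, 15, 15 and 9 -- 87
#' named scalar features in total. The channel subsets behind the
#' per-channel families cover the major limb and trunk joints and are fully
#' configurable.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `kine_family_config`.
#' @export
family_config <- function(...) {
  vel <- function(joint, axis) paste0(joint, "_", axis, "_deg")
  cfg <- list(
    voxel_cm = 2,            # workspace voxel edge
    cell_cm = 2,             # hip-orbit plane cell edge
    autocorr_max_lag_s = 10, # autocorrelation horizon
    fwhm_cap_s = 20,         # FWHM reported when no half-max crossing
    hist_bins = 100L,        # motion-detector histogram bins
    p_set = 0.005,           # motion-detector probability threshold
    hip_segment = "RightUpperLeg",
    reference_segment = "Pelvis",
    extremity_segments = c("RightHand", "LeftHand", "RightFoot", "LeftFoot"),
    avg_velocity_channels = vel(c("RightShoulder", "LeftShoulder",
                                  "RightElbow", "LeftElbow",
                                  "RightHip", "LeftHip",
                                  "RightKnee", "LeftKnee", "L5S1"), "Z"),
    fwhm_channels = c(vel(c("RightShoulder", "LeftShoulder",
                            "RightElbow", "LeftElbow",
                            "RightWrist", "LeftWrist",
                            "RightHip", "LeftHip",
                            "RightKnee", "LeftKnee",
                            "RightAnkle", "LeftAnkle"), "Z"),
                      vel(c("RightHip", "LeftHip"), "X"),
                      vel(c("L5S1", "T9T8", "C1Head"), "Z")),
    logistic_channels = vel(c("RightElbow", "LeftElbow",
                              "RightKnee", "LeftKnee",
                              "RightShoulder", "LeftShoulder",
                              "RightHip", "LeftHip"), "Z"),
    correlation_pairs = list(
      c(vel("RightHip", "Z"), vel("RightKnee", "Z")),
      c(vel("LeftHip", "Z"), vel("LeftKnee", "Z")),
      c(vel("RightHip", "X"), vel("LeftHip", "X")),
      c(vel("RightKnee", "Z"), vel("LeftKnee", "Z")),
      c(vel("RightHip", "Z"), vel("LeftHip", "Z")),
      c(vel("RightShoulder", "Z"), vel("RightElbow", "Z")),
      c(vel("LeftShoulder", "Z"), vel("LeftElbow", "Z")),
      c(vel("RightShoulder", "Z"), vel("LeftShoulder", "Z")),
      c(vel("RightElbow", "Z"), vel("LeftElbow", "Z")),
      c(vel("RightHip", "Z"), vel("RightAnkle", "Z")),
      c(vel("LeftHip", "Z"), vel("LeftAnkle", "Z")),
      c(vel("RightShoulder", "X"), vel("LeftShoulder", "X")),
      c(vel("RightHip", "Z"), vel("LeftKnee", "Z")),
      c(vel("LeftHip", "Z"), vel("RightKnee", "Z")),
      c(vel("L5S1", "Z"), vel("T9T8", "Z"))),
    duty_joints = c("RightShoulder", "LeftShoulder", "RightElbow", "LeftElbow",
                    "RightWrist", "LeftWrist", "RightHip", "LeftHip",
                    "RightKnee", "LeftKnee", "RightAnkle", "LeftAnkle",
                    "L5S1", "T9T8", "C1Head"),
    accel_entries = list(
      c("RightHand", "mean"), c("RightHand", "var"),
      c("LeftHand", "mean"), c("LeftHand", "var"),
      c("RightFoot", "mean"), c("RightFoot", "var"),
      c("LeftFoot", "mean"), c("LeftFoot", "var"),
      c("Pelvis", "mean")),
    smooth_window = 21L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              "unknown family option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over  # whole-value replacement (options may be lists)
  class(cfg) <- "kine_family_config"
  cfg
}

#' Expected family sizes of the default fingerprint vector
#' @return named integer vector summing to 87.
#' @export
fingerprint_families <- function() {
  c(workspace_volume = 3L, hip_orbit_area = 3L, extremity_velocity = 8L,
    avg_joint_velocity = 9L, autocorr_fwhm = 17L, logistic_scale = 8L,
    joint_velocity_correlations = 15L, duty_cycle = 15L,
    segment_acceleration = 9L)
}

row_norms <- function(m) sqrt(rowSums(m^2))

relative_positions <- function(recording, segments, reference) {
  sk <- recording$skeleton
  ref <- recording$segment_positions[, segment_cols_idx(reference, sk), drop = FALSE]
  lapply(segments, function(seg) {
    recording$segment_positions[, segment_cols_idx(seg, sk), drop = FALSE] - ref
  })
}

count_cells <- function(coords, edge_cm) {
  idx <- floor(coords * 100 / edge_cm)  # meters -> cm, half-open cells
  nrow(unique(data.table::as.data.table(idx)))
}

#' Workspace volume (full body, upper body, lower body)
#'
#' Segment positions are re-expressed relative to the pelvis; occupancy of a
#' half-open 2 x 2 x 2 cm voxel grid anchored at the pelvis-frame origin is
#' counted (each voxel once, regardless of visit frequency) and multiplied
#' by the single-voxel volume of 8 cm^3. Computed over all 22 non-reference
#' segments, the upper-body subset and the lower-body subset.
#'
#' @param recording a `kine_recording`.
#' @param config a [family_config()].
#' @return named numeric vector of 3 volumes in cm^3.
#' @export
compute_workspace_volume <- function(recording, config = family_config()) {
  assert_that(n_frames(recording) >= 1, "empty recording")
  sk <- recording$skeleton
  all_segs <- setdiff(sk$segment_names, config$reference_segment)
  subsets <- list(full = all_segs,
                  upper = intersect(upper_body_segments(), sk$segment_names),
                  lower = intersect(lower_body_segments(), sk$segment_names))
  vol1 <- config$voxel_cm^3
  ## encode each segment's visited voxels once as scalar keys
  ## (voxel indices within +/-2048 cells, i.e. +/-40 m from the pelvis)
  rel <- relative_positions(recording, all_segs, config$reference_segment)
  keys <- lapply(rel, function(r) {
    idx <- floor(r * 100 / config$voxel_cm)
    assert_that(all(abs(idx) < 2048), "positions implausibly far from the pelvis")
    ((idx[, 1] + 2048) * 4096 + (idx[, 2] + 2048)) * 4096 + (idx[, 3] + 2048)
  })
  names(keys) <- all_segs
  out <- vapply(subsets, function(segs) {
    length(unique(unlist(keys[segs], use.names = FALSE))) * vol1
  }, numeric(1))
  setNames(out, paste0("wsvol_", names(subsets)))
}

#' Hip orbit area on the three anatomical planes
#'
#' The hip position relative to the pelvis is projected onto the sagittal
#' (x-z), coronal (y-z) and transverse (x-y) planes; the occupied 2 x 2 cm
#' cell count per plane is multiplied by the single-cell area of 4 cm^2.
#'
#' @inheritParams compute_workspace_volume
#' @return named numeric vector of 3 areas in cm^2.
#' @export
compute_hip_orbit_area <- function(recording, config = family_config()) {
  assert_that(n_frames(recording) >= 1, "empty recording")
  rel <- relative_positions(recording, config$hip_segment,
                            config$reference_segment)[[1]]
  planes <- list(sagittal = c(1, 3), coronal = c(2, 3), transverse = c(1, 2))
  cell1 <- config$cell_cm^2
  out <- vapply(planes, function(ax) {
    count_cells(rel[, ax, drop = FALSE], config$cell_cm) * cell1
  }, numeric(1))
  setNames(out, paste0("hiporbit_", names(planes)))
}

#' Mean and variance of extremity speeds
#'
#' Per extremity (both hands and both feet), the per-frame speed is the
#' Euclidean magnitude of the 3-D linear velocity; its mean and variance
#' over the recording give 8 features.
#'
#' @param derived a `kine_derived` (see [differentiate()]).
#' @param config a [family_config()].
#' @return named numeric vector of 8 values (m/s and (m/s)^2).
#' @export
compute_extremity_velocity_stats <- function(derived, config = family_config()) {
  sk <- derived$skeleton
  missing <- setdiff(config$extremity_segments, sk$segment_names)
  if (length(missing)) {
    stop_arg("schema error: missing extremity segment(s): ",
             paste(missing, collapse = ", "))
  }
  out <- lapply(config$extremity_segments, function(seg) {
    sp <- row_norms(derived$segment_linear_velocity[, segment_cols_idx(seg, sk),
                                                    drop = FALSE])
    setNames(c(mean(sp), var(sp)),
             paste0("extvel_", seg, "_", c("mean", "var")))
  })
  unlist(out)
}

#' Mean absolute angular velocity of configured joints
#'
#' @inheritParams compute_extremity_velocity_stats
#' @return named numeric vector (deg/s), 9 values by default.
#' @export
compute_avg_joint_velocity <- function(derived, config = family_config()) {
  v <- derived$joint_angular_velocity
  check_channels(config$avg_velocity_channels, colnames(v))
  out <- vapply(config$avg_velocity_channels,
                function(ch) mean(abs(v[, ch])), numeric(1))
  setNames(out, paste0("avgjv_", config$avg_velocity_channels))
}

check_channels <- function(wanted, have) {
  missing <- setdiff(wanted, have)
  if (length(missing)) {
    stop_arg("schema error: missing channel(s): ", paste(missing, collapse = ", "))
  }
}

#' Autocorrelation full width at half maximum of joint angular velocities
#'
#' The normalised autocorrelation (r(0) = 1) of each configured angular
#' velocity channel is evaluated up to a 10-s lag. The FWHM is twice the
#' first lag at which the autocorrelation crosses 0.5, located with
#' sub-sample linear interpolation. Channels that never cross within the
#' horizon (including degenerate constant channels) return the cap of
#' 2 x 10 s = 20 s.
#'
#' @inheritParams compute_extremity_velocity_stats
#' @return named numeric vector (seconds), 17 values by default.
#' @export
compute_autocorr_fwhm <- function(derived, config = family_config()) {
  v <- derived$joint_angular_velocity
  fs <- derived$sample_rate
  max_lag <- round(config$autocorr_max_lag_s * fs)
  assert_that(nrow(v) >= 2 * max_lag,
              "recording must be at least twice the autocorrelation horizon (",
              2 * config$autocorr_max_lag_s, " s)")
  check_channels(config$fwhm_channels, colnames(v))
  out <- vapply(config$fwhm_channels, function(ch) {
    acf_fwhm(v[, ch], fs, max_lag, config$fwhm_cap_s)
  }, numeric(1))
  setNames(out, paste0("acffwhm_", config$fwhm_channels))
}

acf_fwhm <- function(x, fs, max_lag, cap_s) {
  if (sd(x) == 0) return(cap_s)
  r <- as.vector(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  below <- which(r < 0.5)
  if (length(below) == 0) return(cap_s)
  i <- below[1]                 # r[i] is lag i-1; first lag below half max
  r_prev <- r[i - 1]            # i >= 2 because r[1] = 1
  frac <- (r_prev - 0.5) / (r_prev - r[i])
  tau <- (i - 2 + frac) / fs
  2 * tau
}

#' Maximum-likelihood logistic scale of a sample
#'
#' Fits a logistic distribution by maximum likelihood, initialised at the
#' moment estimate `sqrt(3) * sd / pi`; a zero-variance sample returns 0 so
#' batch extraction stays total.
#'
#' @param x numeric vector.
#' @return the fitted scale parameter (same units as `x`).
#' @export
fit_logistic_scale <- function(x) {
  if (sd(x) == 0) return(0)
  start <- list(location = median(x), scale = logistic_moment_scale(x))
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "logistic", start = start)),
    error = function(e) NULL)
  if (is.null(fit)) return(start$scale)  # fall back to the moment estimate
  unname(fit$estimate["scale"])
}

#' Logistic scale of joint angular velocity distributions
#'
#' Joint velocities in natural behaviour are well described by a logistic
#' distribution; its scale parameter measures the range of velocities used.
#'
#' @inheritParams compute_extremity_velocity_stats
#' @return named numeric vector (deg/s), 8 values by default.
#' @export
compute_logistic_scale <- function(derived, config = family_config()) {
  v <- derived$joint_angular_velocity
  check_channels(config$logistic_channels, colnames(v))
  assert_that(nrow(v) >= 1000,
              "logistic scale fit requires >= 1000 samples per channel")
  out <- vapply(config$logistic_channels,
                function(ch) fit_logistic_scale(v[, ch]), numeric(1))
  setNames(out, paste0("logscale_", config$logistic_channels))
}

#' Pearson correlations of joint angular velocity pairs
#'
#' @inheritParams compute_extremity_velocity_stats
#' @return named numeric vector in `[-1, 1]`, 15 values by default.
#' @export
compute_joint_correlations <- function(derived, config = family_config()) {
  v <- derived$joint_angular_velocity
  check_channels(unique(unlist(config$correlation_pairs)), colnames(v))
  out <- vapply(config$correlation_pairs, function(pr) {
    r <- suppressWarnings(cor(v[, pr[1]], v[, pr[2]]))
    if (is.na(r)) 0 else r
  }, numeric(1))
  setNames(out, vapply(config$correlation_pairs,
                       function(pr) paste0("jvcorr_", pr[1], "__", pr[2]),
                       character(1)))
}

#' Histogram-threshold motion detection
#'
#' A 100-bin histogram, evenly spaced over the range of the absolute signal,
#' is scanned in increasing value starting after the modal bin; the
#' threshold is the left edge of the first bin whose empirical probability
#' falls below `p_set`. Frames whose absolute value exceeds the threshold
#' are classified as motion. A constant (zero-range) channel, or one where
#' no bin falls below `p_set`, yields an all-false mask.
#'
#' @param channel numeric vector (typically an angular velocity).
#' @param bins number of histogram bins.
#' @param p_set probability threshold separating the rest mode.
#' @return logical vector, `TRUE` where the channel is in motion.
#' @export
detect_motion <- function(channel, bins = 100L, p_set = 0.005) {
  n <- length(channel)
  assert_that(n >= bins, "need at least `bins` samples")
  v <- abs(channel)
  rng <- range(v)
  if (diff(rng) == 0) return(rep(FALSE, n))
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(bin, nbins = bins) / n
  modal <- which.max(p)
  after <- which(p < p_set)
  after <- after[after > modal]
  if (length(after) == 0) return(rep(FALSE, n))
  v > breaks[after[1]]
}

#' Duty cycle: fraction of time each joint is in motion
#'
#' [detect_motion()] is applied independently to each of a joint's three
#' Euler-axis velocity channels and the masks are combined with a logical
#' disjunction; the duty cycle is the fraction of frames in motion.
#'
#' @inheritParams compute_extremity_velocity_stats
#' @return named numeric vector in `[0, 1]`, 15 values by default.
#' @export
compute_duty_cycle <- function(derived, config = family_config()) {
  v <- derived$joint_angular_velocity
  out <- vapply(config$duty_joints, function(joint) {
    cols <- paste0(joint, "_", c("X", "Y", "Z"), "_deg")
    check_channels(cols, colnames(v))
    mask <- detect_motion(v[, cols[1]], config$hist_bins, config$p_set) |
      detect_motion(v[, cols[2]], config$hist_bins, config$p_set) |
      detect_motion(v[, cols[3]], config$hist_bins, config$p_set)
    mean(mask)
  }, numeric(1))
  setNames(out, paste0("duty_", config$duty_joints))
}

#' Mean and variance of segment linear acceleration magnitudes
#'
#' @inheritParams compute_extremity_velocity_stats
#' @return named numeric vector, 9 values by default (m/s^2 and (m/s^2)^2).
#' @export
compute_segment_accel_stats <- function(derived, config = family_config()) {
  sk <- derived$skeleton
  assert_that(length(config$accel_entries) >= 1, "no acceleration entries configured")
  out <- vapply(config$accel_entries, function(entry) {
    seg <- entry[1]; stat <- entry[2]
    mag <- row_norms(derived$segment_linear_acceleration[, segment_cols_idx(seg, sk),
                                                         drop = FALSE])
    if (stat == "mean") mean(mag) else var(mag)
  }, numeric(1))
  setNames(out, vapply(config$accel_entries,
                       function(e) paste0("segacc_", e[1], "_", e[2]),
                       character(1)))
}

#' Extract the full ethomic fingerprint vector of a recording
#'
#' Smooths the recording (centered moving average, window 21), derives
#' velocity and acceleration streams, and computes all nine feature
#' families. Under the default configuration this yields exactly 87 named
#' scalar features with family sizes 3, 3, 8, 9, 17, 8, 15, 15, 9.
#'
#' @param recording a `kine_recording`.
#' @param config a [family_config()].
#' @param smooth apply the moving-average smoothing first (default `TRUE`).
#' @return named numeric vector of 87 features with attribute `families`.
#' @export
extract_fingerprints <- function(recording, config = family_config(),
                                 smooth = TRUE) {
  if (smooth) recording <- smooth_recording(recording, config$smooth_window)
  der <- differentiate(recording)
  parts <- list(
    workspace_volume = compute_workspace_volume(recording, config),
    hip_orbit_area = compute_hip_orbit_area(recording, config),
    extremity_velocity = compute_extremity_velocity_stats(der, config),
    avg_joint_velocity = compute_avg_joint_velocity(der, config),
    autocorr_fwhm = compute_autocorr_fwhm(der, config),
    logistic_scale = compute_logistic_scale(der, config),
    joint_velocity_correlations = compute_joint_correlations(der, config),
    duty_cycle = compute_duty_cycle(der, config),
    segment_acceleration = compute_segment_accel_stats(der, config))
  fp <- unlist(unname(parts))
  attr(fp, "families") <- vapply(parts, length, integer(1))
  fp
}

#' Extract fingerprints for every visit in a cohort
#'
#' @param manifest cohort manifest data.frame (see [read_manifest()]).
#' @param recordings optional named list of in-memory `kine_recording`s
#'   keyed by `visit_id`; when absent, recordings are loaded from
#'   `recording_path`.
#' @param config a [family_config()].
#' @return numeric matrix, one row per visit (rownames = `visit_id`), 87
#'   named feature columns.
#' @export
extract_cohort_fingerprints <- function(manifest, recordings = NULL,
                                        config = family_config()) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    vid <- manifest$visit_id[i]
    rec <- if (!is.null(recordings)) recordings[[vid]]
           else load_recording(manifest$recording_path[i], "csv",
                               subject_id = manifest$subject_id[i],
                               visit_id = vid)
    assert_that(!is.null(rec), "no recording for visit ", vid)
    extract_fingerprints(rec, config)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- manifest$visit_id
  m
}

#' Kruskal-Wallis screening of features between groups
#'
#' Applies a tie-corrected Kruskal-Wallis one-way ANOVA to every feature
#' column; with two groups the statistic has one degree of freedom. No
#' multiple-testing correction is applied by default (per-feature
#' significance is reported); Benjamini-Hochberg adjusted p values can be
#' requested.
#'
#' @param features visit x feature numeric matrix (named columns).
#' @param labels group label per visit (>= 2 groups, >= 2 observations per
#'   group).
#' @param adjust add a `p_adj` column with Benjamini-Hochberg adjustment.
#' @return data.frame with one row per feature: `feature`, `H`, `df`, `p`,
#'   and one `median_<group>` column per group.
#' @export
kruskal_wallis_screen <- function(features, labels, adjust = FALSE) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  assert_that(nlevels(labels) >= 2, "need >= 2 groups")
  assert_that(all(table(labels) >= 2), "need >= 2 observations per group")
  res <- lapply(colnames(features), function(f) {
    x <- features[, f]
    kt <- kruskal.test(x, labels)
    meds <- tapply(x, labels, median)
    out <- data.frame(feature = f, H = unname(kt$statistic),
                      df = unname(kt$parameter), p = kt$p.value)
    for (g in levels(labels)) out[[paste0("median_", g)]] <- unname(meds[[g]])
    out
  })
  out <- do.call(rbind, res)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
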