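#' Construct a kinematic recording
#'
#' A recording is one participant-visit time series: a `time x 66` matrix of
#' joint Euler angles (degrees, 22 joints x 3 axes) and a `time x 69` matrix
#' of segment positions (meters, 23 segments x 3 coordinates), sampled at a
#' fixed rate (60 Hz by default). Frame timestamps are implied by the 0-based
#' frame index: `t = frame / sample_rate`.
#'
#' Gaps (NA runs) up to `max_gap_s` seconds are repaired by linear
#' interpolation at construction; longer gaps are rejected.
#'
#' @param joint_angles numeric matrix, `time x 66`, columns named
#'   `<joint>_{X|Y|Z}_deg` in skeleton order.
#' @param segment_positions numeric matrix, `time x 69`, columns named
#'   `<segment>_{x|y|z}_m` in skeleton order.
#' @param subject_id,visit_id opaque identifiers.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param activity_labels optional per-frame character tag (e.g. "ADL").
#' @param skeleton a `kine_skeleton`; defaults to [default_skeleton()].
#' @param max_gap_s longest NA run (seconds) repaired by linear interpolation.
#' @return an object of class `kine_recording`.
#' @export
new_recording <- function(joint_angles, segment_positions,
                          subject_id = "S", visit_id = "V",
                          sample_rate = 60, activity_labels = NULL,
                          skeleton = default_skeleton(), max_gap_s = 0.5) {
  joint_angles <- as.matrix(joint_angles)
  segment_positions <- as.matrix(segment_positions)
  assert_that(sample_rate > 0, "`sample_rate` must be > 0")
  n <- nrow(joint_angles)
  assert_that(nrow(segment_positions) == n,
              "angle and position streams must share the frame count")
  assert_that(ncol(joint_angles) == 66L,
              "schema error: expected 66 joint-angle columns (22 joints x 3 axes), got ",
              ncol(joint_angles))
  assert_that(ncol(segment_positions) == 69L,
              "schema error: expected 69 segment-position columns (23 segments x 3), got ",
              ncol(segment_positions))
  if (is.null(colnames(joint_angles))) colnames(joint_angles) <- joint_angle_cols(skeleton)
  if (is.null(colnames(segment_positions))) colnames(segment_positions) <- segment_position_cols(skeleton)
  if (!is.null(activity_labels)) {
    assert_that(length(activity_labels) == n,
                "`activity_labels` must have one entry per frame")
  }
  joint_angles <- repair_gaps(joint_angles, sample_rate, max_gap_s)
  segment_positions <- repair_gaps(segment_positions, sample_rate, max_gap_s)
  rec <- list(subject_id = subject_id, visit_id = visit_id,
              sample_rate = sample_rate,
              joint_angles = joint_angles,
              segment_positions = segment_positions,
              activity_labels = activity_labels,
              skeleton = skeleton)
  class(rec) <- "kine_recording"
  rec
}

#' @export
print.kine_recording <- function(x, ...) {
  cat("<kine_recording> subject=", x$subject_id, " visit=", x$visit_id,
      " frames=", nrow(x$joint_angles), " @", x$sample_rate, "Hz\n", sep = "")
  invisible(x)
}

n_frames <- function(recording) nrow(recording$joint_angles)

# Linear interpolation of NA runs <= max_gap_s; anything longer (or NA at the
# stream ends) is a hard error -- we refuse to invent long stretches of data.
repair_gaps <- function(m, sample_rate, max_gap_s) {
  if (!anyNA(m)) {
    assert_that(all(is.finite(m)), "non-finite values in stream")
    return(m)
  }
  max_run <- floor(max_gap_s * sample_rate)
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (!anyNA(x)) next
    na <- is.na(x)
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- r$values & (r$lengths > max_run | starts == 1L | ends == n)
    if (any(bad)) {
      stop_arg("gap of ", max(r$lengths[r$values]), " frames in column '",
               colnames(m)[j] %||% j, "' exceeds the repairable maximum (",
               max_run, " frames = ", max_gap_s, " s) or touches a stream end")
    }
    m[, j] <- approx(which(!na), x[!na], xout = seq_len(n))$y
  }
  assert_that(all(is.finite(m)), "non-finite values remain after gap repair")
  m
}

#' Smooth a recording with a centered moving average
#'
#' Every angle and position channel is replaced by its centered moving
#' average (window 21 samples by default, i.e. 1/3 s at 60 Hz). Edges use a
#' symmetric shrinking window so the frame count is preserved.
#'
#' @param recording a `kine_recording`.
#' @param window odd integer window length in samples.
#' @return a smoothed `kine_recording`.
#' @export
smooth_recording <- function(recording, window = 21L) {
  assert_that(window %% 2 == 1, "`window` must be odd, got ", window)
  assert_that(window >= 1 && window <= n_frames(recording),
              "`window` must be in [1, frame count]")
  recording$joint_angles <- apply_cols(recording$joint_angles, moving_average, window)
  recording$segment_positions <- apply_cols(recording$segment_positions, moving_average, window)
  recording
}

apply_cols <- function(m, f, ...) {
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- f(m[, j], ...)
  out
}

#' Differentiate a recording into velocity and acceleration streams
#'
#' Central finite differences scaled by the sample rate at interior frames;
#' one-sided differences at the two boundary frames. Produces joint angular
#' velocities (deg/s), segment linear velocities (m/s) and segment linear
#' accelerations (m/s^2), all with the frame count of the source recording.
#'
#' @param recording a `kine_recording` with at least 3 frames.
#' @return an object of class `kine_derived` with fields
#'   `joint_angular_velocity`, `segment_linear_velocity`,
#'   `segment_linear_acceleration`, `sample_rate` and `skeleton`.
#' @export
differentiate <- function(recording) {
  assert_that(n_frames(recording) >= 3, "differentiation needs >= 3 frames")
  fs <- recording$sample_rate
  vel_ang <- diff_stream(recording$joint_angles, fs)
  vel_lin <- diff_stream(recording$segment_positions, fs)
  acc_lin <- diff_stream(vel_lin, fs)
  out <- list(joint_angular_velocity = vel_ang,
              segment_linear_velocity = vel_lin,
              segment_linear_acceleration = acc_lin,
              sample_rate = fs, skeleton = recording$skeleton)
  class(out) <- "kine_derived"
  out
}

diff_stream <- function(m, fs) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) * (fs / 2)
  d[1, ] <- (m[2, ] - m[1, ]) * fs
  d[n, ] <- (m[n, ] - m[n - 1, ]) * fs
  d
}
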