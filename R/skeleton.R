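#' The default 23-segment / 22-joint skeleton model
#'
#' Full-body inertial motion-capture suits reconstruct pose on a biomechanical
#' model with 23 body segments linked by 22 joints. Each joint carries three
#' Euler angles following the International Society of Biomechanics
#' convention: X = abduction/adduction, Y = internal/external rotation,
#' Z = flexion/extension. Segment positions are 3-D coordinates in meters;
#' joint angles are in degrees.
#'
#' The exact naming follows the vendor's documented segment list; any
#' consistent naming with the same counts and axis convention is accepted by
#' the loaders.
#'
#' @return an object of class `kine_skeleton` with fields `segment_names`
#'   (23), `joint_names` (22), `joint_axes` (X/Y/Z labels) and `parent_map`
#'   (joint -> proximal/distal segment).
#' @export
default_skeleton <- function() {
  segments <- c(
    "Pelvis", "L5", "L3", "T12", "T8", "Neck", "Head",
    "RightShoulder", "RightUpperArm", "RightForearm", "RightHand",
    "LeftShoulder", "LeftUpperArm", "LeftForearm", "LeftHand",
    "RightUpperLeg", "RightLowerLeg", "RightFoot", "RightToe",
    "LeftUpperLeg", "LeftLowerLeg", "LeftFoot", "LeftToe")
  joints <- c(
    "L5S1", "L4L3", "L1T12", "T9T8", "T1C7", "C1Head",
    "RightC7Shoulder", "RightShoulder", "RightElbow", "RightWrist",
    "LeftC7Shoulder", "LeftShoulder", "LeftElbow", "LeftWrist",
    "RightHip", "RightKnee", "RightAnkle", "RightBallFoot",
    "LeftHip", "LeftKnee", "LeftAnkle", "LeftBallFoot")
  parent_map <- list(
    L5S1 = c("Pelvis", "L5"), L4L3 = c("L5", "L3"), L1T12 = c("L3", "T12"),
    T9T8 = c("T12", "T8"), T1C7 = c("T8", "Neck"), C1Head = c("Neck", "Head"),
    RightC7Shoulder = c("T8", "RightShoulder"),
    RightShoulder = c("RightShoulder", "RightUpperArm"),
    RightElbow = c("RightUpperArm", "RightForearm"),
    RightWrist = c("RightForearm", "RightHand"),
    LeftC7Shoulder = c("T8", "LeftShoulder"),
    LeftShoulder = c("LeftShoulder", "LeftUpperArm"),
    LeftElbow = c("LeftUpperArm", "LeftForearm"),
    LeftWrist = c("LeftForearm", "LeftHand"),
    RightHip = c("Pelvis", "RightUpperLeg"),
    RightKnee = c("RightUpperLeg", "RightLowerLeg"),
    RightAnkle = c("RightLowerLeg", "RightFoot"),
    RightBallFoot = c("RightFoot", "RightToe"),
    LeftHip = c("Pelvis", "LeftUpperLeg"),
    LeftKnee = c("LeftUpperLeg", "LeftLowerLeg"),
    LeftAnkle = c("LeftLowerLeg", "LeftFoot"),
    LeftBallFoot = c("LeftFoot", "LeftToe"))
  sk <- list(
    segment_names = segments,
    joint_names = joints,
    joint_axes = c(X = "abduction/adduction",
                   Y = "internal/external rotation",
                   Z = "flexion/extension"),
    parent_map = parent_map)
  class(sk) <- "kine_skeleton"
  validate_skeleton(sk)
  sk
}

validate_skeleton <- function(sk) {
  assert_that(length(sk$segment_names) == 23L, "skeleton must have exactly 23 segments")
  assert_that(length(sk$joint_names) == 22L, "skeleton must have exactly 22 joints")
  assert_that(!anyDuplicated(sk$segment_names) && !anyDuplicated(sk$joint_names),
              "skeleton names must be unique")
  refs <- unlist(sk$parent_map, use.names = FALSE)
  assert_that(all(refs %in% sk$segment_names),
              "every joint must reference existing segments")
  invisible(sk)
}

# Column names of the 66 joint-angle channels: <joint>_{X,Y,Z}_deg
joint_angle_cols <- function(skeleton = default_skeleton()) {
  as.vector(t(outer(skeleton$joint_names, c("X", "Y", "Z"),
                    function(j, a) paste0(j, "_", a, "_deg"))))
}

# Column names of the 69 segment-position channels: <segment>_{x,y,z}_m
segment_position_cols <- function(skeleton = default_skeleton()) {
  as.vector(t(outer(skeleton$segment_names, c("x", "y", "z"),
                    function(s, a) paste0(s, "_", a, "_m"))))
}

# Axis triplet indices of one joint within the 66-column angle matrix
joint_cols_idx <- function(joint, skeleton = default_skeleton()) {
  j <- match(joint, skeleton$joint_names)
  assert_that(!is.na(j), "unknown joint: ", joint)
  (j - 1L) * 3L + 1:3
}

# Axis triplet indices of one segment within the 69-column position matrix
segment_cols_idx <- function(segment, skeleton = default_skeleton()) {
  s <- match(segment, skeleton$segment_names)
  assert_that(!is.na(s), "unknown segment: ", segment)
  (s - 1L) * 3L + 1:3
}

# Body-half segment subsets used by the workspace-volume fingerprint
upper_body_segments <- function() {
  c("L5", "L3", "T12", "T8", "Neck", "Head",
    "RightShoulder", "RightUpperArm", "RightForearm", "RightHand",
    "LeftShoulder", "LeftUpperArm", "LeftForearm", "LeftHand")
}

lower_body_segments <- function() {
  c("RightUpperLeg", "RightLowerLeg", "RightFoot", "RightToe",
    "LeftUpperLeg", "LeftLowerLeg", "LeftFoot", "LeftToe")
}

#' @export
print.kine_skeleton <- function(x, ...) {
  cat("<kine_skeleton> ", length(x$segment_names), " segments, ",
      length(x$joint_names), " joints\n", sep = "")
  cat("Euler axes: X=", x$joint_axes[["X"]], ", Y=", x$joint_axes[["Y"]],
      ", Z=", x$joint_axes[["Z"]], "\n", sep = "")
  invisible(x)
}
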