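# Fixtures are built in code: small deterministic recordings with injected
# channels, an MVNX-subset XML writer, and one lazily generated synthetic
# cohort shared across test files.

make_recording <- function(n, fs = 60, angles = NULL, positions = NULL, ...) {
  ang <- matrix(0, n, 66, dimnames = list(NULL, kinedmd:::joint_angle_cols()))
  pos <- matrix(0, n, 69, dimnames = list(NULL, kinedmd:::segment_position_cols()))
  if (!is.null(angles)) for (nm in names(angles)) ang[, nm] <- angles[[nm]]
  if (!is.null(positions)) for (nm in names(positions)) pos[, nm] <- positions[[nm]]
  new_recording(ang, pos, sample_rate = fs, ...)
}

# set every non-reference segment's position to the same 3-vector
# trajectory (the pelvis stays at the origin so positions are already
# pelvis-relative)
uniform_positions <- function(n, xyz_fn) {
  sk <- default_skeleton()
  out <- list()
  for (seg in setdiff(sk$segment_names, "Pelvis")) {
    tr <- xyz_fn(n)
    for (a in 1:3) {
      out[[paste0(seg, "_", c("x", "y", "z")[a], "_m")]] <- tr[, a]
    }
  }
  out
}

write_mvnx_fixture <- function(path, n_frames = 3, n_segments = 23,
                               n_joints = 22, frame_rate = 60) {
  sk <- default_skeleton()
  segs <- paste0('    <segment label="', sk$segment_names[seq_len(n_segments)],
                 '" id="', seq_len(n_segments), '"/>')
  joints <- paste0('    <joint label="', sk$joint_names[seq_len(n_joints)],
                   '" id="', seq_len(n_joints), '"/>')
  set.seed(99)
  frames <- vapply(seq_len(n_frames), function(i) {
    ja <- paste(sprintf("%.4f", rnorm(66)), collapse = " ")
    po <- paste(sprintf("%.4f", rnorm(69, sd = 0.1)), collapse = " ")
    paste0('    <frame time="', (i - 1) * 1000 / frame_rate,
           '" type="normal"><jointAngle>', ja,
           "</jointAngle><position>", po, "</position></frame>")
  }, character(1))
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           "<mvnx>", paste0(' <subject frameRate="', frame_rate, '">'),
           "  <segments>", segs, "  </segments>",
           "  <joints>", joints, "  </joints>",
           "  <frames>",
           '    <frame time="0" type="tpose"><jointAngle>0</jointAngle></frame>',
           frames,
           "  </frames>", " </subject>", "</mvnx>")
  writeLines(xml, path)
  path
}

.kine_test_cache <- new.env(parent = emptyenv())

# one moderately sized cohort (15 DMD / 15 HC, 45-s recordings) reused by
# the screening, direction and anti-leakage tests
shared_cohort <- function() {
  if (is.null(.kine_test_cache$cohort)) {
    cfg <- generator_config(n_dmd = 15L, n_hc = 15L, recording_duration_s = 45)
    coh <- generate_cohort(cfg, seed = 20260925)
    feats <- extract_cohort_fingerprints(coh$manifest, coh$recordings)
    .kine_test_cache$cohort <- list(manifest = coh$manifest, features = feats)
  }
  .kine_test_cache$cohort
}

shared_dmd_dataset <- function() {
  coh <- shared_cohort()
  keep <- coh$manifest$group == "DMD"
  as_cohort_dataset(coh$manifest[keep, , drop = FALSE],
                    coh$features[keep, , drop = FALSE])
}

# the control half: severity is identically 0, so fingerprints carry no
# common disease axis and subjects are exchangeable -- the clean setting
# for permutation (anti-leakage) checks
shared_hc_dataset <- function() {
  coh <- shared_cohort()
  keep <- coh$manifest$group == "HC"
  as_cohort_dataset(coh$manifest[keep, , drop = FALSE],
                    coh$features[keep, , drop = FALSE])
}

# permutation with no fixed points: every subject receives another's target
derange <- function(x) {
  repeat {
    p <- sample(x)
    if (!any(p == x)) return(setNames(p, x))
  }
}

# toy feature cohort for the prediction machinery (no kinematics involved)
toy_dataset <- function(n_sub = 15, visits = 2, p = 10, seed = 1,
                        target_fn = function(X)
                          2 * X[, 3] - 1.5 * X[, min(7, ncol(X))]) {
  set.seed(seed)
  meta <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n_sub)), each = visits),
    visit_id = sprintf("V%03d", seq_len(n_sub * visits)),
    group = "DMD",
    age_years = rep(runif(n_sub, 6, 15), each = visits) +
      rep(seq_len(visits) - 1, n_sub) * 0.5,
    visit_month = rep((seq_len(visits) - 1) * 6, n_sub),
    ambulatory = TRUE)
  X <- matrix(rnorm(n_sub * visits * p), n_sub * visits, p,
              dimnames = list(meta$visit_id, sprintf("f%02d", seq_len(p))))
  meta$target <- target_fn(X)
  as_cohort_dataset(meta, X)
}
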