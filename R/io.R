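#' Load a kinematic recording from disk
#'
#' Two on-disk dialects are supported:
#'
#' * `"csv"` — one header row; columns `time_s`, then the 66 joint-angle
#'   columns `<joint>_{X|Y|Z}_deg`, then the 69 segment-position columns
#'   `<segment>_{x|y|z}_m`; UTF-8, `.` decimal separator. An optional
#'   `activity` column carries per-frame session tags.
#' * `"mvnx_subset"` — an XML dialect carrying segment/joint name
#'   declarations plus per-frame `jointAngle` (66 floats, degrees) and
#'   `position` (69 floats, meters) payloads; all other sensor payloads are
#'   ignored.
#'
#' Gaps up to 0.5 s are linearly interpolated at load; longer gaps are
#' rejected.
#'
#' @param path file path.
#' @param format `"csv"` or `"mvnx_subset"`.
#' @param subject_id,visit_id identifiers attached to the recording (CSV
#'   carries none); defaults derive from the file name.
#' @param skeleton expected `kine_skeleton`.
#' @return a `kine_recording`.
#' @export
load_recording <- function(path, format = c("csv", "mvnx_subset"),
                           subject_id = NULL, visit_id = NULL,
                           skeleton = default_skeleton()) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: ", path)
  base <- sub("\\.[^.]+$", "", basename(path))
  subject_id <- subject_id %||% base
  visit_id <- visit_id %||% base
  switch(format,
         csv = read_recording_csv(path, subject_id, visit_id, skeleton),
         mvnx_subset = read_recording_mvnx(path, subject_id, visit_id, skeleton))
}

read_recording_csv <- function(path, subject_id, visit_id, skeleton) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  want_ang <- joint_angle_cols(skeleton)
  want_pos <- segment_position_cols(skeleton)
  assert_that("time_s" %in% names(dt), "parse error: missing column 'time_s'")
  missing <- setdiff(c(want_ang, want_pos), names(dt))
  if (length(missing)) {
    stop_arg("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  ts <- dt[["time_s"]]
  fs <- if (length(ts) >= 2) 1 / median(diff(ts)) else 60
  labels <- if ("activity" %in% names(dt)) as.character(dt[["activity"]]) else NULL
  new_recording(as.matrix(dt[want_ang]), as.matrix(dt[want_pos]),
                subject_id = subject_id, visit_id = visit_id,
                sample_rate = round(fs, 6), activity_labels = labels,
                skeleton = skeleton)
}

#' Write a recording in the CSV dialect
#'
#' Inverse of [load_recording()] with `format = "csv"`; numbers are written
#' with full (round-trippable) precision.
#'
#' @param recording a `kine_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- n_frames(recording)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sample_rate,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(recording$joint_angles),
              as.data.frame(recording$segment_positions))
  if (!is.null(recording$activity_labels)) df$activity <- recording$activity_labels
  data.table::fwrite(df, path)
  invisible(path)
}

read_recording_mvnx <- function(path, subject_id, visit_id, skeleton) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_arg("parse error in '", path, "': ",
                                               conditionMessage(e)))
  ns <- xml2::xml_ns_strip(doc)
  seg_nodes <- xml2::xml_find_all(doc, ".//segments/segment")
  joint_nodes <- xml2::xml_find_all(doc, ".//joints/joint")
  seg_names <- xml2::xml_attr(seg_nodes, "label")
  joint_names <- xml2::xml_attr(joint_nodes, "label")
  if (length(seg_names) != 23L) {
    stop_arg("schema error: expected 23 <segment> declarations, got ", length(seg_names))
  }
  if (length(joint_names) != 22L) {
    stop_arg("schema error: expected 22 <joint> declarations, got ", length(joint_names))
  }
  frames <- xml2::xml_find_all(doc, ".//frames/frame")
  # calibration frames (identity/tpose) carry a type attribute; keep normal frames
  type <- xml2::xml_attr(frames, "type")
  frames <- frames[is.na(type) | type == "normal"]
  assert_that(length(frames) >= 1, "parse error: no <frame> payloads")
  parse_payload <- function(frame, tag, want_len, i) {
    node <- xml2::xml_find_first(frame, tag)
    if (inherits(node, "xml_missing")) {
      stop_arg("parse error: frame ", i, " lacks <", tag, ">")
    }
    vals <- suppressWarnings(as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                                 "\\s+")[[1]]))
    if (length(vals) != want_len || anyNA(vals)) {
      stop_arg("parse error: frame ", i, " <", tag, "> expected ", want_len,
               " numeric values, got ", length(vals))
    }
    vals
  }
  ang <- t(vapply(seq_along(frames), function(i)
    parse_payload(frames[[i]], "jointAngle", 66L, i), numeric(66L)))
  pos <- t(vapply(seq_along(frames), function(i)
    parse_payload(frames[[i]], "position", 69L, i), numeric(69L)))
  rate_attr <- xml2::xml_attr(xml2::xml_find_first(doc, ".//subject"), "frameRate")
  fs <- if (is.na(rate_attr)) 60 else as.numeric(rate_attr)
  sk <- skeleton
  sk$segment_names <- seg_names
  sk$joint_names <- joint_names
  colnames(ang) <- joint_angle_cols(sk)
  colnames(pos) <- segment_position_cols(sk)
  new_recording(ang, pos, subject_id = subject_id, visit_id = visit_id,
                sample_rate = fs, skeleton = sk)
}

#' Read / write a cohort manifest
#'
#' The manifest is a CSV with one row per participant visit and columns
#' `subject_id, visit_id, group, age_years, visit_month, ambulatory, nsaa,
#' sixmwd_m, pul, myogrip_pct, recording_path`.
#'
#' @param path manifest CSV path.
#' @return a `data.frame` of visits.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), "manifest not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("subject_id", "visit_id", "group", "age_years", "visit_month",
            "ambulatory", "nsaa", "sixmwd_m", "pul", "myogrip_pct",
            "recording_path")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_arg("schema error: manifest missing column(s): ",
             paste(missing, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df$visit_id <- as.character(df$visit_id)
  df$ambulatory <- as.logical(df$ambulatory)
  df
}

#' @rdname read_manifest
#' @param manifest data.frame of visit rows.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path)
  invisible(path)
}
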