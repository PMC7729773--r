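# Posture features: segment vectors, deflection angles against the
# vertical, spine-to-waist ratio and torso length. All geometry is in
# image coordinates (origin top-left, y downward); the vertical reference
# is (0, -1), i.e. up-image, so an upright torso scores ~0 degrees.

# segment endpoints, proximal (upper) -> distal (lower), BODY_25 ids
.segments <- list(
  spine       = c(1L, 8L),
  left_thigh  = c(9L, 10L),
  right_thigh = c(12L, 13L),
  left_calf   = c(10L, 11L),
  right_calf  = c(13L, 14L))

#' Posture vector between two keypoints
#'
#' The vector (X_from - X_to, Y_from - Y_to), matching the spine-vector
#' convention (neck minus mid-hip). With segments ordered proximal above
#' distal, the result points up-image for an upright pose.
#'
#' @param frame a `skeleton_frame`.
#' @param from_id,to_id 0-based BODY_25 keypoint indices.
#' @return Numeric `c(dx, dy)` in pixels.
#' @export
posture_vector <- function(frame, from_id, to_id) {
  a <- keypoint(frame, from_id)
  b <- keypoint(frame, to_id)
  if (a[["conf"]] <= 0 || b[["conf"]] <= 0)
    stop("posture_vector: keypoint ", if (a[["conf"]] <= 0) from_id else to_id,
         " is undetected in frame ", frame$frame_index)
  c(a[["x"]] - b[["x"]], a[["y"]] - b[["y"]])
}

#' Deflection angle of a vector from the vertical
#'
#' Angle in degrees, in \[0, 180\], between `v` and the up-image vertical
#' reference (0, -1), computed from the normalised dot product. A vector
#' pointing straight up-image gives 0; straight down-image gives 180.
#'
#' @param v numeric `c(dx, dy)`, or an n x 2 matrix of vectors.
#' @return Angle(s) in degrees.
#' @export
deflection_angle <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 2L)
  n <- sqrt(v[, 1L]^2 + v[, 2L]^2)
  if (any(n == 0)) stop("deflection_angle: zero vector has no direction")
  # dot(v, (0,-1)) = -dy; clamp for acos roundoff at the poles
  ang <- acos(pmin(1, pmax(-1, -v[, 2L] / n))) * 180 / pi
  if (length(ang) == 1L) ang[[1L]] else ang
}

#' Spine-to-waist ratio
#'
#' |spine vector| / |waist width vector| (neck-to-mid-hip length over
#' hip-to-hip length). Under camera-facing falls the projected spine
#' foreshortens while the waist does not, so the ratio collapses below 1
#' even though the deflection angle stays small.
#'
#' @param frame a `skeleton_frame`.
#' @param min_waist_px floor for the waist norm; below it the frame
#'   should have been invalidated upstream.
#' @return Unitless positive ratio.
#' @export
spine_ratio <- function(frame, min_waist_px = 1.0) {
  sp <- posture_vector(frame, 1L, 8L)
  wa <- posture_vector(frame, 9L, 12L)
  wn <- sqrt(sum(wa^2))
  if (wn < min_waist_px)
    stop("spine_ratio: waist width ", format(wn), " px below floor ",
         min_waist_px, " (frame should be invalid)")
  sqrt(sum(sp^2)) / wn
}

#' Torso length H
#'
#' Euclidean distance between neck (keypoint 1) and mid-hip (keypoint 8),
#' in pixels. Used as the per-subject length scale normalising the
#' detector's compare and energy values.
#'
#' @param frame a `skeleton_frame`.
#' @return Length in pixels (0 for coincident points; callers must treat
#'   that frame as invalid).
#' @export
torso_length <- function(frame) {
  a <- keypoint(frame, 1L)
  b <- keypoint(frame, 8L)
  if (a[["conf"]] <= 0 || b[["conf"]] <= 0)
    stop("torso_length: neck or mid-hip undetected in frame ",
         frame$frame_index)
  sqrt((a[["x"]] - b[["x"]])^2 + (a[["y"]] - b[["y"]])^2)
}

#' Per-frame key posture features
#'
#' Bundles the five deflection angles (spine, both thighs, both calves),
#' the spine ratio and the torso length for one valid frame.
#'
#' @param frame a valid `skeleton_frame`.
#' @param min_waist_px waist-norm floor passed to [spine_ratio()].
#' @return One-row data.frame with columns `spine_angle`,
#'   `left_thigh_angle`, `right_thigh_angle`, `left_calf_angle`,
#'   `right_calf_angle` (degrees), `spine_ratio` and `torso_length_H`
#'   (pixels).
#' @export
extract_key_features <- function(frame, min_waist_px = 1.0) {
  vs <- t(vapply(.segments, function(s) posture_vector(frame, s[1L], s[2L]),
                 numeric(2)))
  ang <- deflection_angle(vs)
  names(ang) <- rownames(vs)
  data.frame(
    spine_angle       = ang[["spine"]],
    left_thigh_angle  = ang[["left_thigh"]],
    right_thigh_angle = ang[["right_thigh"]],
    left_calf_angle   = ang[["left_calf"]],
    right_calf_angle  = ang[["right_calf"]],
    spine_ratio       = spine_ratio(frame, min_waist_px),
    torso_length_H    = torso_length(frame))
}

#' Feature table for a whole sequence
#'
#' Runs validity checks and feature extraction over every frame; invalid
#' frames keep their row with `valid = FALSE` and NA features so frame
#' indexing stays aligned with the input stream.
#'
#' @param seq a `skeleton_sequence` (list of `skeleton_frame`s).
#' @param min_confidence,min_waist_px validity thresholds, see
#'   [validate_frame()].
#' @return data.frame with one row per frame: `frame`, `valid`, and the
#'   [extract_key_features()] columns.
#' @export
key_feature_table <- function(seq, min_confidence = 0.1, min_waist_px = 1.0) {
  na_row <- data.frame(spine_angle = NA_real_, left_thigh_angle = NA_real_,
                       right_thigh_angle = NA_real_, left_calf_angle = NA_real_,
                       right_calf_angle = NA_real_, spine_ratio = NA_real_,
                       torso_length_H = NA_real_)
  rows <- lapply(seq, function(fr) {
    v <- validate_frame(fr, min_confidence, min_waist_px)
    feats <- if (v$valid) extract_key_features(fr, min_waist_px) else na_row
    cbind(data.frame(frame = fr$frame_index, valid = v$valid), feats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-frame feature table to CSV
#'
#' @param features output of [key_feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
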