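#' @title BODY_25 keypoint model constants
#' @description Keypoint indices follow the OpenPose BODY_25 numbering
#'   (0-based): 1 = neck, 8 = mid-hip, 9/12 = left/right hip, 10/13 = knees,
#'   11/14 = ankles. Coordinates are image pixels, origin top-left, y
#'   increasing downward.
#' @name body25
NULL

#' Keypoint indices required for posture analysis
#'
#' The main-torso keypoints the pipeline depends on: neck, mid-hip, both
#' hips, knees and ankles (BODY_25 ids 1, 8, 9, 10, 11, 12, 13, 14).
#' @return Integer vector of 0-based BODY_25 indices.
#' @export
required_keypoints <- function() c(1L, 8L, 9L, 10L, 11L, 12L, 13L, 14L)

#' Construct a skeleton frame
#'
#' One detected person at one frame: a 25 x 3 matrix of keypoints in
#' BODY_25 order with columns `x`, `y` (pixels) and `conf` (detection
#' confidence in \[0, 1\]). An undetected keypoint is encoded as (0, 0, 0).
#'
#' @param keypoints numeric 25 x 3 matrix (or 75-long vector
#'   x0,y0,c0,...,x24,y24,c24).
#' @param frame_index nonnegative integer frame number.
#' @param person_id integer person index within the frame (0-based).
#' @return An object of class `skeleton_frame`.
#' @export
skeleton_frame <- function(keypoints, frame_index = 0L, person_id = 0L) {
  if (is.vector(keypoints)) {
    if (length(keypoints) != 75L)
      stop("keypoints vector must have 75 numbers (25 x,y,conf triplets), got ",
           length(keypoints))
    keypoints <- matrix(keypoints, ncol = 3L, byrow = TRUE)
  }
  keypoints <- as.matrix(keypoints)
  if (!all(dim(keypoints) == c(25L, 3L)))
    stop("keypoints must be a 25 x 3 matrix")
  if (anyNA(keypoints) || any(!is.finite(keypoints)))
    stop("keypoints must be finite")
  if (any(keypoints[, 3L] < 0 | keypoints[, 3L] > 1))
    stop("confidences must lie in [0, 1]")
  colnames(keypoints) <- c("x", "y", "conf")
  structure(
    list(frame_index = as.integer(frame_index),
         person_id = as.integer(person_id),
         keypoints = keypoints),
    class = "skeleton_frame")
}

#' @export
print.skeleton_frame <- function(x, ...) {
  det <- sum(x$keypoints[, "conf"] > 0)
  cat(sprintf("<skeleton_frame> frame %d, person %d, %d/25 keypoints detected\n",
              x$frame_index, x$person_id, det))
  invisible(x)
}

#' Extract one keypoint from a frame
#'
#' @param frame a `skeleton_frame`.
#' @param id 0-based BODY_25 keypoint index.
#' @return Named numeric vector `c(x, y, conf)`.
#' @export
keypoint <- function(frame, id) {
  stopifnot(id >= 0L, id <= 24L)
  frame$keypoints[id + 1L, ]
}

#' Mid-hip (keypoint 8) position
#' @param frame a `skeleton_frame`.
#' @return Numeric `c(x, y)`.
#' @export
midhip <- function(frame) unname(frame$keypoints[9L, c("x", "y")])

#' Read OpenPose BODY_25 JSON frames
#'
#' Consumes the OpenPose JSON dialect: each file holds a top-level
#' `"people"` list whose entries carry `"pose_keypoints_2d"`, a flat list
#' of 75 numbers (x0, y0, c0, ..., x24, y24, c24). An empty `"people"`
#' list is a legal frame with zero persons.
#'
#' @param source a directory of per-frame `*.json` files (sorted by the
#'   trailing number in the filename, else lexically), or a character
#'   vector of file paths, or a single file.
#' @return A list with one element per frame, each a list with
#'   `frame_index` and `persons` (a list of [skeleton_frame()]s, people
#'   order preserved).
#' @export
read_openpose_frames <- function(source) {
  files <- if (length(source) == 1L && dir.exists(source)) {
    f <- list.files(source, pattern = "\\.json$", full.names = TRUE)
    num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)\\D*\\.json$", "\\1",
                                           basename(f))))
    if (!anyNA(num)) f[order(num)] else sort(f)
  } else {
    as.character(source)
  }
  if (length(files) == 0L) stop("no .json frame files found in ", source)
  lapply(seq_along(files), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(files[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed JSON in frame file '", files[[i]], "': ",
                           conditionMessage(e), call. = FALSE))
    people <- obj[["people"]]
    if (is.null(people)) people <- list()
    persons <- lapply(seq_along(people), function(p) {
      kp <- unlist(people[[p]][["pose_keypoints_2d"]], use.names = FALSE)
      if (length(kp) != 75L)
        stop("frame file '", files[[i]], "', person ", p - 1L,
             ": pose_keypoints_2d has ", length(kp),
             " numbers, expected 75", call. = FALSE)
      skeleton_frame(kp, frame_index = i - 1L, person_id = p - 1L)
    })
    list(frame_index = i - 1L, persons = persons)
  })
}

#' Select the tracked subject among detected persons
#'
#' With no prior position, picks the person with the highest mean
#' confidence over the required torso keypoints; with a prior mid-hip
#' position, picks the person whose mid-hip is nearest to it. Ties break
#' to the lowest person index, so the choice is deterministic.
#'
#' @param persons list of [skeleton_frame()]s (may be empty).
#' @param previous_midhip optional numeric `c(x, y)` of the subject's
#'   mid-hip in an earlier frame.
#' @return A `skeleton_frame`, or `NULL` when `persons` is empty.
#' @export
select_subject <- function(persons, previous_midhip = NULL) {
  if (length(persons) == 0L) return(NULL)
  if (is.null(previous_midhip)) {
    score <- vapply(persons, function(p)
      mean(p$keypoints[required_keypoints() + 1L, "conf"]), numeric(1))
    persons[[which.max(score)]]
  } else {
    d <- vapply(persons, function(p)
      sum((midhip(p) - previous_midhip)^2), numeric(1))
    persons[[which.min(d)]]
  }
}

#' Track a single subject through a frame stream
#'
#' Applies [select_subject()] frame by frame with greedy nearest-mid-hip
#' tracking; frames with no detected person are dropped.
#'
#' @param frames output of [read_openpose_frames()] or
#'   [read_keypoint_csv()].
#' @return A list of `skeleton_frame`s (class `skeleton_sequence`).
#' @export
track_subject <- function(frames) {
  out <- list()
  prev <- NULL
  for (fr in frames) {
    p <- select_subject(fr$persons, prev)
    if (is.null(p)) next
    p$frame_index <- fr$frame_index
    prev <- midhip(p)
    out[[length(out) + 1L]] <- p
  }
  structure(out, class = "skeleton_sequence")
}

#' Frame validity for posture analysis
#'
#' A frame is usable when every required torso keypoint (see
#' [required_keypoints()]) reaches the confidence floor and the waist
#' width (distance between the two hips, keypoints 9 and 12) is at least
#' `min_waist_px`. The waist floor guards the spine-ratio denominator.
#'
#' @param frame a `skeleton_frame`.
#' @param min_confidence confidence floor, default 0.1.
#' @param min_waist_px minimum hip-to-hip distance in pixels, default 1.
#' @return List with `valid` (logical) and `missing_ids` (integer vector
#'   of required ids failing the confidence test).
#' @export
validate_frame <- function(frame, min_confidence = 0.1, min_waist_px = 1.0) {
  req <- required_keypoints()
  conf <- frame$keypoints[req + 1L, "conf"]
  missing <- req[conf < min_confidence]
  waist <- sqrt(sum((keypoint(frame, 9L)[c("x", "y")] -
                     keypoint(frame, 12L)[c("x", "y")])^2))
  list(valid = length(missing) == 0L && waist >= min_waist_px,
       missing_ids = missing)
}

#' Write a skeleton sequence as long-format CSV
#'
#' Internal fixture format: header `frame,person,kp,x,y,conf`, one row per
#' keypoint. Coordinates round-trip exactly (written at full precision).
#'
#' @param seq a `skeleton_sequence` (list of `skeleton_frame`s).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(seq, path) {
  rows <- lapply(seq, function(fr) {
    data.frame(frame = fr$frame_index, person = fr$person_id, kp = 0:24,
               x = fr$keypoints[, "x"], y = fr$keypoints[, "y"],
               conf = fr$keypoints[, "conf"])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the long-format keypoint CSV
#'
#' @param path file written by [write_keypoint_csv()] (columns
#'   `frame,person,kp,x,y,conf`).
#' @return Same structure as [read_openpose_frames()]: a list of frames,
#'   each with `frame_index` and a `persons` list.
#' @export
read_keypoint_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "person", "kp", "x", "y", "conf")
  if (!all(need %in% names(df)))
    stop("keypoint CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(sort(unique(df$frame)), function(fi) {
    sub <- df[df$frame == fi, ]
    persons <- lapply(sort(unique(sub$person)), function(pi) {
      kp <- sub[sub$person == pi, ]
      kp <- kp[order(kp$kp), ]
      if (nrow(kp) != 25L)
        stop("frame ", fi, ", person ", pi, ": expected 25 keypoint rows, got ",
             nrow(kp))
      skeleton_frame(cbind(kp$x, kp$y, kp$conf),
                     frame_index = fi, person_id = pi)
    })
    list(frame_index = fi, persons = persons)
  })
  out
}
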