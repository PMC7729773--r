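# Stage one: integrate the scattered key features into a tendency symbol
# (inclination) and a steady symbol (lower-body support), then divide
# frames into stable / fluctuating / disorder states.

#' Stage-one thresholds
#'
#' Decision thresholds of the state-division stage: `angle_lower_limit`
#' (ALL) and `angle_upper_limit` (AUL) bound the spine deflection angle,
#' `ratio_boundary` (RB) splits the spine ratio, and `angle_limit` (AL)
#' is the per-segment ceiling for the steady-symbol pair tests. All
#' angles in degrees. Boundary equality always falls to the middle /
#' unsteady level (comparisons are strict), so threshold sweeps are
#' deterministic.
#'
#' @param angle_lower_limit degrees, default 30.
#' @param angle_upper_limit degrees, default 50.
#' @param ratio_boundary unitless, default 1.0 (values near 1.2 are also
#'   defensible from the observed fall/ADL ratio distributions).
#' @param angle_limit degrees, default 30.
#' @return List of class `stage_one_thresholds`.
#' @export
stage_one_thresholds <- function(angle_lower_limit = 30,
                                 angle_upper_limit = 50,
                                 ratio_boundary = 1.0,
                                 angle_limit = 30) {
  stopifnot(angle_lower_limit > 0,
            angle_upper_limit > angle_lower_limit,
            ratio_boundary > 0, angle_limit > 0)
  structure(list(angle_lower_limit = angle_lower_limit,
                 angle_upper_limit = angle_upper_limit,
                 ratio_boundary = ratio_boundary,
                 angle_limit = angle_limit),
            class = "stage_one_thresholds")
}

#' Tendency symbol (T1/T2/T3)
#'
#' Three-level inclination label from the spine deflection angle and the
#' spine ratio: T1 (small inclination, e.g. walking) requires angle below
#' the lower limit AND ratio above the boundary; T3 (pronounced falling
#' tendency) fires when the angle exceeds the upper limit OR the ratio
#' drops below the boundary (the camera-facing foreshortening route);
#' everything else, including boundary equality, is T2.
#'
#' @param spine_angle degrees.
#' @param ratio unitless spine ratio.
#' @param th a [stage_one_thresholds()].
#' @return `"T1"`, `"T2"` or `"T3"` (vectorised over inputs).
#' @export
tendency_symbol <- function(spine_angle, ratio, th = stage_one_thresholds()) {
  ifelse(spine_angle < th$angle_lower_limit & ratio > th$ratio_boundary, "T1",
  ifelse(spine_angle > th$angle_upper_limit | ratio < th$ratio_boundary, "T3",
         "T2"))
}

#' Steady symbol (S1/S2) and pair count
#'
#' Four pair conditions, each requiring both of its two segment angles to
#' stay below the angle limit AL: spine+left thigh, spine+right thigh,
#' left calf+left thigh, right calf+right thigh. One true pair is enough
#' for a stable lower body (S1); none makes S2.
#'
#' @param spine_angle,left_thigh,right_thigh,left_calf,right_calf degrees.
#' @param th a [stage_one_thresholds()].
#' @return data.frame with columns `steady` (`"S1"`/`"S2"`) and
#'   `pair_count` (0--4), one row per input element.
#' @export
steady_symbol <- function(spine_angle, left_thigh, right_thigh,
                          left_calf, right_calf,
                          th = stage_one_thresholds()) {
  al <- th$angle_limit
  c1 <- spine_angle < al & left_thigh < al
  c2 <- spine_angle < al & right_thigh < al
  c3 <- left_calf < al & left_thigh < al
  c4 <- right_calf < al & right_thigh < al
  n <- c1 + c2 + c3 + c4
  data.frame(steady = ifelse(n >= 1L, "S1", "S2"), pair_count = as.integer(n))
}

#' Human state from the two symbols
#'
#' Stable iff (S1, T1); disorder iff (S2, T3); every other combination is
#' fluctuating. States carry scores 0, 1, 2 used by the detector's state
#' score.
#'
#' @param tendency `"T1"`/`"T2"`/`"T3"` (vectorised).
#' @param steady `"S1"`/`"S2"` (vectorised).
#' @return data.frame with columns `state`
#'   (`"STABLE"`/`"FLUCTUATING"`/`"DISORDER"`) and `score` (0/1/2).
#' @export
human_state <- function(tendency, steady) {
  state <- ifelse(steady == "S1" & tendency == "T1", "STABLE",
           ifelse(steady == "S2" & tendency == "T3", "DISORDER",
                  "FLUCTUATING"))
  data.frame(state = state,
             score = c(STABLE = 0L, FLUCTUATING = 1L, DISORDER = 2L)[state],
             row.names = NULL)
}

#' Per-frame state stream for a sequence
#'
#' Applies the full stage-one pipeline to a feature table. Invalid frames
#' do not advance the state machine: they carry the previous valid
#' frame's symbols and state forward; if no valid frame has been seen
#' yet, the state is FLUCTUATING (never silently stable).
#'
#' @param features output of [key_feature_table()].
#' @param th a [stage_one_thresholds()].
#' @return data.frame with one row per frame: `frame`, `valid`,
#'   `tendency`, `steady`, `pair_count`, `state`, `score`.
#' @export
state_stream <- function(features, th = stage_one_thresholds()) {
  n <- nrow(features)
  tendency <- character(n); steady <- character(n)
  pair <- integer(n); state <- character(n); score <- integer(n)
  prev <- list(tendency = "T2", steady = "S2", pair_count = 0L,
               state = "FLUCTUATING", score = 1L)
  for (i in seq_len(n)) {
    if (isTRUE(features$valid[i])) {
      tnd <- tendency_symbol(features$spine_angle[i], features$spine_ratio[i], th)
      std <- steady_symbol(features$spine_angle[i],
                           features$left_thigh_angle[i],
                           features$right_thigh_angle[i],
                           features$left_calf_angle[i],
                           features$right_calf_angle[i], th)
      hs <- human_state(tnd, std$steady)
      prev <- list(tendency = tnd, steady = std$steady,
                   pair_count = std$pair_count,
                   state = hs$state, score = hs$score)
    }
    tendency[i] <- prev$tendency; steady[i] <- prev$steady
    pair[i] <- prev$pair_count; state[i] <- prev$state; score[i] <- prev$score
  }
  data.frame(frame = features$frame, valid = features$valid,
             tendency = tendency, steady = steady, pair_count = pair,
             state = state, score = score)
}

#' Write a state stream to CSV
#' @param states output of [state_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_state_stream <- function(states, path) {
  utils::write.csv(states, path, row.names = FALSE)
  invisible(path)
}
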