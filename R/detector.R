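# Stage two: the time-continuous detector. A reference template of the
# last stable pose (mid-hip position + torso length) anchors the compare
# value; three consecutive unstable frames open a non-stationary
# residence period (NSRP); three consecutive stable frames abort it;
# once the feature window fills, the (gamma, epsilon, tau) vector is
# classified as fall vs ADL.

#' Detector configuration
#'
#' @param unstable_run consecutive unstable frames that open an NSRP
#'   (default 3).
#' @param stable_run consecutive STABLE frames that abort an open NSRP
#'   (default 3).
#' @param nsrp_window number of frames over which the NSRP feature vector
#'   is accumulated (default 10). Window lengths are in frames; the
#'   defaults correspond to 25 FPS footage.
#' @param lower_limb_ids keypoints entering the energy value (default
#'   knees and ankles, BODY_25 ids 10, 11, 13, 14).
#' @param include_trigger if `TRUE`, the trigger frames also contribute
#'   to gamma/epsilon/tau; by default the window is the `nsrp_window`
#'   frames following the trigger and the trigger contributes nothing.
#' @param soft_sign if `TRUE` (default) the compare value uses the
#'   softsign direction term x/(1+|x|); if `FALSE`, a strict sign().
#' @return List of class `detector_config`.
#' @export
detector_config <- function(unstable_run = 3L, stable_run = 3L,
                            nsrp_window = 10L,
                            lower_limb_ids = c(10L, 11L, 13L, 14L),
                            include_trigger = FALSE, soft_sign = TRUE) {
  stopifnot(unstable_run >= 1L, stable_run >= 1L, nsrp_window >= 1L,
            stable_run <= nsrp_window, length(lower_limb_ids) >= 1L)
  structure(list(unstable_run = as.integer(unstable_run),
                 stable_run = as.integer(stable_run),
                 nsrp_window = as.integer(nsrp_window),
                 lower_limb_ids = as.integer(lower_limb_ids),
                 include_trigger = isTRUE(include_trigger),
                 soft_sign = isTRUE(soft_sign)),
            class = "detector_config")
}

#' Softsign function
#'
#' x / (1 + |x|): a smooth sign in (-1, 1). With pixel-scale arguments it
#' saturates quickly, acting as a direction indicator for the vertical
#' centroid displacement.
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
softsign <- function(x) x / (1 + abs(x))

#' Build/refresh the reference template
#'
#' The template (Px, Py, H) records the mid-hip position and torso length
#' at the most recent STABLE frame; it is the anchor against which
#' centroid motion inside an NSRP is measured.
#'
#' @param frame a valid `skeleton_frame`.
#' @param state the frame's human state; must be `"STABLE"`.
#' @return List of class `reference_template` with `Px`, `Py`, `H`.
#' @export
update_template <- function(frame, state = "STABLE") {
  if (!identical(state, "STABLE"))
    stop("update_template: the reference template may only be refreshed at a ",
         "STABLE frame (got ", state, ")")
  h <- torso_length(frame)
  if (h <= 0) stop("update_template: degenerate torso (H = 0)")
  mh <- midhip(frame)
  structure(list(Px = mh[[1L]], Py = mh[[2L]], H = h),
            class = "reference_template")
}

#' Per-frame centroid increment mu
#'
#' mu = softsign(Py - y8) * ||(Px,Py) - (x8,y8)|| / H: the mid-hip
#' displacement from the template, normalised by the template torso
#' length, signed by vertical direction. Negative when the centroid has
#' moved down-image (toward the floor); by convention mu is 0 at STABLE
#' frames.
#'
#' @param xi a `reference_template`.
#' @param frame a valid `skeleton_frame`.
#' @param soft_sign use softsign (default) or strict sign for the
#'   direction term.
#' @return Unitless signed scalar.
#' @export
centroid_increment <- function(xi, frame, soft_sign = TRUE) {
  if (is.null(xi) || !inherits(xi, "reference_template"))
    stop("centroid_increment: reference template is not set")
  mh <- midhip(frame)
  d <- sqrt((xi$Px - mh[[1L]])^2 + (xi$Py - mh[[2L]])^2)
  dirarg <- xi$Py - mh[[2L]]   # negative when mid-hip moved down-image
  dir <- if (soft_sign) softsign(dirarg) else sign(dirarg)
  dir * d / xi$H
}

#' Compare value gamma
#'
#' Sum of the per-frame centroid increments mu over an NSRP; the empty
#' sum is 0.
#' @param mu_values numeric vector.
#' @return Scalar gamma.
#' @export
compare_value <- function(mu_values) sum(mu_values)

#' Energy value epsilon
#'
#' Lower-limb vertical dispersion over an NSRP: for each lower-limb
#' keypoint t, the mean absolute deviation of its y coordinate from its
#' NSRP mean, summed over frames and keypoints and normalised by the
#' template torso length H. Zero iff every lower-limb keypoint's y is
#' constant.
#'
#' @param frames list of valid `skeleton_frame`s in the NSRP.
#' @param xi the `reference_template` (its `H` is the normaliser).
#' @param cfg a [detector_config()] (for `lower_limb_ids`).
#' @return Nonnegative scalar epsilon.
#' @export
energy_value <- function(frames, xi, cfg = detector_config()) {
  if (length(frames) == 0L) stop("energy_value: empty frame list")
  ys <- vapply(frames, function(fr) fr$keypoints[cfg$lower_limb_ids + 1L, "y"],
               numeric(length(cfg$lower_limb_ids)))
  ys <- matrix(ys, nrow = length(cfg$lower_limb_ids))  # keypoints x frames
  sum(abs(ys - rowMeans(ys))) / xi$H
}

#' State score tau
#'
#' Cumulative human-state score over an NSRP (stable 0, fluctuating 1,
#' disorder 2); bounded by 2 x number of frames.
#' @param states character vector of states, or a [state_stream()] slice.
#' @return Integer tau.
#' @export
state_score <- function(states) {
  if (is.data.frame(states)) states <- states$state
  sum(c(STABLE = 0L, FLUCTUATING = 1L, DISORDER = 2L)[states])
}

#' Run the time-continuous fall detector over a sequence
#'
#' Scans a time-ordered stream of frames and their stage-one states.
#' STABLE frames refresh the reference template and reset the trigger
#' counter; after `unstable_run` consecutive unstable frames an NSRP
#' opens. Inside it, `stable_run` consecutive STABLE frames abort with no
#' event (refreshing the template); if `nsrp_window` frames elapse
#' without an abort, one feature vector D = (gamma, epsilon, tau) is
#' computed over the window, classified once, and emitted as an event.
#' The template is frozen during an NSRP; after an event it waits for the
#' next STABLE frame. Invalid frames (states already carried forward by
#' [state_stream()]) advance the window but contribute nothing to gamma
#' or epsilon. If an NSRP opens before any STABLE frame has been seen, a
#' provisional template is taken from the first valid frame of the NSRP.
#'
#' @param seq a `skeleton_sequence`.
#' @param states matching [state_stream()] data.frame (same length/order).
#' @param model optional trained [fall_classifier()]; when `NULL`,
#'   events are emitted with `is_fall = NA`.
#' @param cfg a [detector_config()].
#' @return data.frame of events: `start_frame`, `end_frame` (the trigger
#'   and window span, in the sequence's frame indices), `gamma`,
#'   `epsilon`, `tau`, `is_fall`.
#' @export
run_detector <- function(seq, states, model = NULL, cfg = detector_config()) {
  stopifnot(length(seq) == nrow(states))
  n <- length(seq)
  events <- list()
  xi <- NULL
  unstable <- 0L
  in_nsrp <- FALSE
  trigger_idx <- integer(0)
  window_idx <- integer(0)
  stable_in <- 0L

  close_nsrp <- function() {
    in_nsrp <<- FALSE; trigger_idx <<- integer(0)
    window_idx <<- integer(0); stable_in <<- 0L; unstable <<- 0L
  }

  emit <- function() {
    feat_idx <- if (cfg$include_trigger) c(trigger_idx, window_idx) else window_idx
    xi_use <- xi
    if (is.null(xi_use)) {
      # no stable frame ever seen: provisional anchor from the first
      # valid frame of the NSRP
      for (j in c(trigger_idx, window_idx)) {
        if (isTRUE(states$valid[j])) {
          mh <- midhip(seq[[j]])
          xi_use <- structure(list(Px = mh[[1L]], Py = mh[[2L]],
                                   H = max(torso_length(seq[[j]]), 1e-8)),
                              class = "reference_template")
          break
        }
      }
    }
    mu <- vapply(feat_idx, function(j) {
      if (!isTRUE(states$valid[j]) || states$state[j] == "STABLE" ||
          is.null(xi_use)) 0
      else centroid_increment(xi_use, seq[[j]], cfg$soft_sign)
    }, numeric(1))
    valid_idx <- feat_idx[vapply(feat_idx, function(j)
      isTRUE(states$valid[j]), logical(1))]
    eps <- if (length(valid_idx) == 0L || is.null(xi_use)) 0
           else energy_value(seq[valid_idx], xi_use, cfg)
    tau <- state_score(states$state[feat_idx])
    d <- data.frame(gamma = compare_value(mu), epsilon = eps, tau = tau)
    isf <- NA
    if (!is.null(model)) {
      isf <- tryCatch(predict(model, d) == "FALL",
                      error = function(e)
                        stop("classifier failed on event spanning frames ",
                             states$frame[trigger_idx[1L]], "-",
                             states$frame[window_idx[length(window_idx)]],
                             ": ", conditionMessage(e), call. = FALSE))
    }
    events[[length(events) + 1L]] <<- data.frame(
      start_frame = states$frame[trigger_idx[1L]],
      end_frame = states$frame[window_idx[length(window_idx)]],
      gamma = d$gamma, epsilon = d$epsilon, tau = tau, is_fall = isf)
  }

  for (i in seq_len(n)) {
    st <- states$state[i]
    if (!in_nsrp) {
      if (st == "STABLE") {
        if (isTRUE(states$valid[i])) xi <- update_template(seq[[i]], "STABLE")
        unstable <- 0L
      } else {
        unstable <- unstable + 1L
        if (unstable == cfg$unstable_run) {
          in_nsrp <- TRUE
          trigger_idx <- (i - cfg$unstable_run + 1L):i
          window_idx <- integer(0)
          stable_in <- 0L
        }
      }
    } else {
      window_idx <- c(window_idx, i)
      stable_in <- if (st == "STABLE") stable_in + 1L else 0L
      if (stable_in == cfg$stable_run) {
        # sustained recovery: no event, template refreshed at this
        # stable frame, resume scanning
        if (isTRUE(states$valid[i])) xi <- update_template(seq[[i]], "STABLE")
        close_nsrp()
      } else if (length(window_idx) == cfg$nsrp_window) {
        emit()
        close_nsrp()
      }
    }
  }
  if (length(events) == 0L)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      gamma = numeric(0), epsilon = numeric(0),
                      tau = integer(0), is_fall = logical(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Write detector events as JSON lines
#'
#' One JSON object per event with fields `start_frame`, `end_frame`,
#' `gamma`, `epsilon`, `tau`, `is_fall`.
#' @param events output of [run_detector()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events)))
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
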