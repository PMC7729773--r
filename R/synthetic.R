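# Seeded stick-figure motion generator. Sequences are built from joint
# angle trajectories on a fixed-length skeleton under orthographic
# projection: enough kinematic structure to exercise every posture
# feature and the full two-stage detector, with Gaussian keypoint jitter
# and dropout emulating pose-estimator noise. Angle targets per action:
#
#   WALK          spine < 12.5 deg (postural stability limit), legs swing
#                 gently; the subject never leaves the stable state.
#   SIT_STAND     spine ramps into 30-50 deg, thighs past 60 deg, hip
#                 descends ~0.35 torso, then recovers: a confusing ADL.
#   SQUAT         spine stays < 30 deg but thighs pass 80 deg, hip
#                 descends ~0.30 torso: confusing ADL.
#   BEND          spine 60-80 deg with both legs < 15 deg: confusing ADL.
#   LATERAL_FALL  all five segment angles ramp past 50 deg within 15
#                 frames while the mid-hip descends >= 0.85 torso.
#   FORWARD_FALL  camera-facing collapse: the projected spine length
#                 shrinks so the spine ratio falls from 2.5 below 1.0
#                 while angles stay < 30 deg; the body then drops ~0.7
#                 torso.

#' Action specification for the motion generator
#'
#' @param action one of `"WALK"`, `"SIT_STAND"`, `"SQUAT"`, `"BEND"`,
#'   `"LATERAL_FALL"`, `"FORWARD_FALL"`.
#' @param n_frames sequence length; fall actions need at least 13 frames
#'   (detector trigger + feature window).
#' @param torso_length_px neck-to-mid-hip length, default 100 px.
#' @param hip_width_px hip-to-hip distance, default 40 px.
#' @param jitter_sd_px Gaussian noise sd added to every coordinate,
#'   default 1 px.
#' @param dropout_prob per-keypoint probability of being zeroed
#'   (undetected), default 0.
#' @param seed integer seed.
#' @return List of class `action_spec`.
#' @export
action_spec <- function(action, n_frames = 40L, torso_length_px = 100,
                        hip_width_px = 40, jitter_sd_px = 1.0,
                        dropout_prob = 0, seed = 1L) {
  action <- match.arg(action, c("WALK", "SIT_STAND", "SQUAT", "BEND",
                                "LATERAL_FALL", "FORWARD_FALL"))
  n_frames <- as.integer(n_frames)
  if (action %in% c("LATERAL_FALL", "FORWARD_FALL") && n_frames < 13L)
    stop("fall actions need n_frames >= 13 (trigger + feature window), got ",
         n_frames)
  if (action %in% c("SIT_STAND", "SQUAT", "BEND") && n_frames < 8L)
    stop("transient actions need n_frames >= 8, got ", n_frames)
  if (n_frames < 1L) stop("n_frames must be positive")
  stopifnot(torso_length_px > 0, hip_width_px > 0, jitter_sd_px >= 0,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(action = action, n_frames = n_frames,
                 torso_length_px = torso_length_px,
                 hip_width_px = hip_width_px,
                 jitter_sd_px = jitter_sd_px, dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "action_spec")
}

.is_fall_action <- function(action) action %in% c("LATERAL_FALL", "FORWARD_FALL")

# Per-frame pose schedule: signed segment angles (degrees from vertical,
# sign = lateral direction), projected spine scale, and mid-hip path.
.pose_schedule <- function(spec) {
  n <- spec$n_frames
  torso <- spec$torso_length_px
  t <- seq_len(n)
  cx0 <- 160; cy0 <- 120
  base <- data.frame(cx = cx0, cy = cy0, spine = 5, scale = 1,
                     thigh_l = 5, thigh_r = -5, calf_l = 5, calf_r = -5)
  ramp <- function(from, to, len) if (len <= 0) numeric(0) else
    from + (to - from) * seq_len(len) / len
  # symmetric transient: lead | down | hold | up | tail
  transient <- function(peak_spine, peak_thigh, peak_calf, drop) {
    lead <- max(2L, (n - 24L) %/% 2L)
    down <- up <- min(8L, max(1L, (n - 4L) %/% 3L))
    hold <- max(1L, n - 2L * lead - down - up)
    tail <- n - lead - down - hold - up
    if (tail < 0L) { hold <- max(1L, hold + tail); tail <- n - lead - down - hold - up }
    seg <- function(lo_s, hi_s) c(rep(lo_s, lead), ramp(lo_s, hi_s, down),
                                  rep(hi_s, hold), ramp(hi_s, lo_s, up),
                                  rep(lo_s, tail))
    p <- base[rep(1L, n), ]
    p$spine <- seg(5, peak_spine)
    p$thigh_l <- seg(5, peak_thigh); p$thigh_r <- -seg(5, peak_thigh)
    p$calf_l <- seg(5, peak_calf);   p$calf_r <- -seg(5, peak_calf)
    p$cy <- cy0 + seg(0, drop * torso)
    p
  }
  p <- switch(spec$action,
    WALK = {
      ph <- 2 * pi * t / 16
      data.frame(cx = cx0 + 2 * t, cy = cy0 + 2 * sin(ph),
                 spine = 3 + 6 * sin(ph + 0.5), scale = 1,
                 thigh_l = 14 * sin(ph), thigh_r = -14 * sin(ph),
                 calf_l = 8 * sin(ph + pi / 4), calf_r = -8 * sin(ph + pi / 4))
    },
    SIT_STAND = transient(40, 70, 15, 0.35),
    SQUAT     = transient(20, 85, 35, 0.30),
    BEND      = {
      p <- transient(70, 8, 8, 0.08)
      p$thigh_l <- 8; p$thigh_r <- -8; p$calf_l <- 8; p$calf_r <- -8
      p
    },
    LATERAL_FALL = {
      lead <- max(0L, n - 23L); rl <- 10L; hold <- n - lead - rl
      ang <- c(rep(NA, lead), 10 + 68 * seq_len(rl) / rl,
               80 + 2 * ((seq_len(hold) %% 2) - 0.5))
      frac <- c(rep(0, lead), (seq_len(rl) / rl)^2, rep(1, hold))
      p <- base[rep(1L, n), ]
      if (lead > 0) {
        ph <- 2 * pi * seq_len(lead) / 16
        p$spine[1:lead] <- 4 + 2 * sin(ph)
        p$thigh_l[1:lead] <- 8 * sin(ph); p$thigh_r[1:lead] <- -8 * sin(ph)
      }
      unst <- (lead + 1L):n
      p$spine[unst] <- ang[unst]
      p$thigh_l[unst] <- ang[unst]; p$thigh_r[unst] <- ang[unst] * 0.95
      p$calf_l[unst] <- ang[unst] * 0.9; p$calf_r[unst] <- ang[unst] * 0.92
      p$cy <- cy0 + 0.85 * torso * frac
      p$cx <- cx0 + 0.3 * torso * frac
      p
    },
    FORWARD_FALL = {
      lead <- max(0L, n - 25L); rl <- 10L; hold <- n - lead - rl
      # projected spine shrinks first (pitch toward the camera), then the
      # body drops; the ratio crosses 1.0 around ramp frame 4
      shrink <- c(rep(1, lead), ramp(1, 0.38, 4L), ramp(0.375, 0.35, 6L),
                  rep(0.35, hold))
      dropfrac <- c(rep(0, lead + 4L), (seq_len(6L) / 6)^2, rep(1, hold))
      p <- base[rep(1L, n), ]
      p$scale <- shrink
      p$spine <- 8
      p$thigh_l <- c(rep(5, lead), ramp(5, 16, rl), rep(16, hold))
      p$thigh_r <- -p$thigh_l
      p$calf_l <- 8; p$calf_r <- -8
      p$cy <- cy0 + 0.70 * torso * dropfrac
      p
    })
  p
}

# Build one 25-keypoint frame from a pose row (before jitter/dropout).
.pose_to_keypoints <- function(pose, spec) {
  torso <- spec$torso_length_px
  hw <- spec$hip_width_px / 2
  thigh <- 0.55 * torso
  calf <- 0.50 * torso
  rad <- pi / 180
  kp <- matrix(0, 25L, 3L, dimnames = list(NULL, c("x", "y", "conf")))
  put <- function(id, x, y, conf = 0.9) kp[id + 1L, ] <<- c(x, y, conf)
  p8 <- c(pose$cx, pose$cy)
  u <- c(sin(pose$spine * rad), -cos(pose$spine * rad))   # up the spine
  p1 <- p8 + torso * pose$scale * u
  put(8L, p8[1], p8[2]); put(1L, p1[1], p1[2])
  put(9L, p8[1] - hw, p8[2]); put(12L, p8[1] + hw, p8[2])
  down <- function(origin, len, ang) origin + len * c(sin(ang * rad),
                                                      cos(ang * rad))
  p10 <- down(c(p8[1] - hw, p8[2]), thigh, pose$thigh_l)
  p11 <- down(p10, calf, pose$calf_l)
  p13 <- down(c(p8[1] + hw, p8[2]), thigh, pose$thigh_r)
  p14 <- down(p13, calf, pose$calf_r)
  put(10L, p10[1], p10[2]); put(11L, p11[1], p11[2])
  put(13L, p13[1], p13[2]); put(14L, p14[1], p14[2])
  # head, shoulders, arms and feet: cosmetic but keeps the BODY_25 frame
  # looking like real pose-estimator output
  nose <- p1 + 0.30 * torso * u
  put(0L, nose[1], nose[2], 0.85)
  put(15L, nose[1] - 4, nose[2] - 3, 0.8); put(16L, nose[1] + 4, nose[2] - 3, 0.8)
  put(17L, nose[1] - 8, nose[2], 0.7);     put(18L, nose[1] + 8, nose[2], 0.7)
  perp <- c(cos(pose$spine * rad), sin(pose$spine * rad))
  p2 <- p1 - 0.22 * torso * perp; p5 <- p1 + 0.22 * torso * perp
  put(2L, p2[1], p2[2], 0.85); put(5L, p5[1], p5[2], 0.85)
  put(3L, p2[1], p2[2] + 0.30 * torso, 0.8)
  put(4L, p2[1], p2[2] + 0.58 * torso, 0.75)
  put(6L, p5[1], p5[2] + 0.30 * torso, 0.8)
  put(7L, p5[1], p5[2] + 0.58 * torso, 0.75)
  put(19L, p11[1] + 5, p11[2] + 5, 0.7); put(20L, p11[1] + 10, p11[2] + 5, 0.7)
  put(21L, p11[1] - 3, p11[2] + 6, 0.7)
  put(22L, p14[1] + 5, p14[2] + 5, 0.7); put(23L, p14[1] + 10, p14[2] + 5, 0.7)
  put(24L, p14[1] - 3, p14[2] + 6, 0.7)
  kp
}

#' Generate one labelled synthetic action sequence
#'
#' Deterministic given the spec's seed: the noiseless pose schedule obeys
#' the per-action kinematic contracts (see the module header), then
#' jitter and dropout are applied per coordinate / keypoint.
#'
#' @param spec an [action_spec()].
#' @return List of class `labeled_sequence`: `frames` (a
#'   `skeleton_sequence`), `label` (`"FALL"` or `"ADL"`), `action` (the
#'   spec).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "action_spec"))
  set.seed(spec$seed)
  sched <- .pose_schedule(spec)
  frames <- lapply(seq_len(spec$n_frames), function(i) {
    kp <- .pose_to_keypoints(sched[i, ], spec)
    if (spec$jitter_sd_px > 0)
      kp[, 1:2] <- kp[, 1:2] + stats::rnorm(50L, sd = spec$jitter_sd_px)
    if (spec$dropout_prob > 0) {
      drop <- stats::runif(25L) < spec$dropout_prob
      kp[drop, ] <- 0
    }
    skeleton_frame(kp, frame_index = i - 1L, person_id = 0L)
  })
  structure(list(frames = structure(frames, class = "skeleton_sequence"),
                 label = if (.is_fall_action(spec$action)) "FALL" else "ADL",
                 action = spec),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat(sprintf("<labeled_sequence> %s (%s), %d frames, seed %d\n",
              x$action$action, x$label, x$action$n_frames, x$action$seed))
  invisible(x)
}

#' Generate a labelled corpus and its NSRP feature table
#'
#' Generates `n_per_action[[a]]` sequences per action with seeds derived
#' from `seed`, then runs the full stage-one + stage-two pipeline on each
#' and harvests the NSRP feature vectors as labelled classifier samples
#' (sequences that never open an NSRP, e.g. walks, contribute none).
#'
#' @param n_per_action named integer vector, e.g.
#'   `c(LATERAL_FALL = 20, SIT_STAND = 20)`.
#' @param seed master seed; per-sequence seeds are derived from it.
#' @param n_frames,jitter_sd_px,dropout_prob passed to [action_spec()].
#' @param th stage-one thresholds.
#' @param cfg detector configuration.
#' @return List with `sequences` (list of `labeled_sequence`) and
#'   `samples` (data.frame `gamma`, `epsilon`, `tau`, `label`, `action`,
#'   `sequence`).
#' @export
generate_corpus <- function(n_per_action, seed = 1L, n_frames = 40L,
                            jitter_sd_px = 1.0, dropout_prob = 0,
                            th = stage_one_thresholds(),
                            cfg = detector_config()) {
  stopifnot(length(names(n_per_action)) == length(n_per_action),
            all(n_per_action >= 0))
  sequences <- list()
  samples <- list()
  k <- 0L
  for (a in names(n_per_action)) {
    for (j in seq_len(n_per_action[[a]])) {
      k <- k + 1L
      sub_seed <- as.integer((as.numeric(seed) * 10007 + k) %% 2147483647)
      sp <- action_spec(a, n_frames = n_frames,
                        jitter_sd_px = jitter_sd_px,
                        dropout_prob = dropout_prob, seed = sub_seed)
      ls <- generate_sequence(sp)
      sequences[[k]] <- ls
      feats <- key_feature_table(ls$frames)
      states <- state_stream(feats, th)
      ev <- run_detector(ls$frames, states, model = NULL, cfg = cfg)
      if (nrow(ev) > 0L)
        samples[[length(samples) + 1L]] <- data.frame(
          gamma = ev$gamma, epsilon = ev$epsilon, tau = ev$tau,
          label = ls$label, action = a, sequence = k)
    }
  }
  samples <- if (length(samples)) do.call(rbind, samples) else
    data.frame(gamma = numeric(0), epsilon = numeric(0), tau = integer(0),
               label = character(0), action = character(0),
               sequence = integer(0))
  rownames(samples) <- NULL
  list(sequences = sequences, samples = samples)
}

#' Write a sequence as per-frame OpenPose JSON files
#'
#' One `frame_NNNNNN_keypoints.json` per frame in the OpenPose BODY_25
#' dialect (`"people"` / `"pose_keypoints_2d"`), readable back with
#' [read_openpose_frames()].
#'
#' @param seq a `skeleton_sequence`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_openpose_frames <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fr in seq) {
    flat <- as.numeric(t(fr$keypoints))
    obj <- list(version = 1.3,
                people = list(list(person_id = list(-1L),
                                   pose_keypoints_2d = flat)))
    path <- file.path(dir, sprintf("frame_%06d_keypoints.json",
                                   fr$frame_index))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
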