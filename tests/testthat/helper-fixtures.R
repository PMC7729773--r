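# Frame builders used across the suite. Geometry is written out from
# first principles here (independent of the package's generator): a
# standing stick figure at a given mid-hip with given segment angles.

# 25x3 keypoint matrix for a pose; angles in signed degrees from the
# vertical, positive leaning right in image coordinates.
pose_keypoints <- function(cx = 160, cy = 120, spine = 0, thigh_l = 0,
                           thigh_r = 0, calf_l = 0, calf_r = 0,
                           torso = 100, hip_w = 40, spine_scale = 1,
                           conf = 0.9) {
  r <- pi / 180
  kp <- matrix(0, 25, 3)
  p8 <- c(cx, cy)
  p1 <- p8 + torso * spine_scale * c(sin(spine * r), -cos(spine * r))
  p9 <- p8 + c(-hip_w / 2, 0); p12 <- p8 + c(hip_w / 2, 0)
  p10 <- p9 + 55 * c(sin(thigh_l * r), cos(thigh_l * r))
  p11 <- p10 + 50 * c(sin(calf_l * r), cos(calf_l * r))
  p13 <- p12 + 55 * c(sin(thigh_r * r), cos(thigh_r * r))
  p14 <- p13 + 50 * c(sin(calf_r * r), cos(calf_r * r))
  for (id_pt in list(list(1, p1), list(8, p8), list(9, p9), list(12, p12),
                     list(10, p10), list(11, p11), list(13, p13),
                     list(14, p14)))
    kp[id_pt[[1]] + 1, ] <- c(id_pt[[2]], conf)
  kp
}

make_frame <- function(..., frame_index = 0L) {
  skeleton_frame(pose_keypoints(...), frame_index = frame_index)
}

# sequence of standing frames with mid-hip following (xs, ys)
standing_sequence <- function(xs, ys, ...) {
  frames <- lapply(seq_along(xs), function(i)
    make_frame(cx = xs[i], cy = ys[i], ..., frame_index = i - 1L))
  structure(frames, class = "skeleton_sequence")
}

# a minimal state_stream-shaped data.frame from a state vector
states_df <- function(states, valid = rep(TRUE, length(states))) {
  score <- c(STABLE = 0L, FLUCTUATING = 1L, DISORDER = 2L)[states]
  data.frame(frame = seq_along(states) - 1L, valid = valid,
             tendency = "T2", steady = "S2", pair_count = 0L,
             state = states, score = unname(score))
}

# random (frames, states) stream for detector equivalence testing:
# mid-hip wanders, ~10% of frames are flagged invalid, states follow a
# sticky Markov chain over STABLE/FLUCTUATING/DISORDER
random_stream <- function(n, seed) {
  set.seed(seed)
  xs <- cumsum(rnorm(n, 0, 3)) + 160
  ys <- cumsum(rnorm(n, 0.5, 4)) + 120
  seq <- standing_sequence(xs, ys)
  st <- character(n)
  st[1] <- sample(c("STABLE", "FLUCTUATING", "DISORDER"), 1)
  for (i in 2:n)
    st[i] <- if (runif(1) < 0.6) st[i - 1] else
      sample(c("STABLE", "FLUCTUATING", "DISORDER"), 1)
  valid <- runif(n) > 0.1
  list(seq = seq, states = states_df(st, valid))
}
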