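# Independent oracles: deliberately naive re-derivations of each
# operation, kept structurally separate from the package implementation.

# angle between v and the up-image vertical via arctangent (the package
# uses the normalised dot product)
oracle_angle <- function(vx, vy) atan2(abs(vx), -vy) * 180 / pi

# literal transcription of the three stage-one level-judgment rules
oracle_state <- function(spine, thigh_l, thigh_r, calf_l, calf_r, ratio,
                         ALL = 30, AUL = 50, RB = 1.0, AL = 30) {
  if (spine < ALL && ratio > RB) tend <- "T1"
  else if (spine > AUL || ratio < RB) tend <- "T3"
  else tend <- "T2"
  case1 <- spine < AL && thigh_l < AL
  case2 <- spine < AL && thigh_r < AL
  case3 <- calf_l < AL && thigh_l < AL
  case4 <- calf_r < AL && thigh_r < AL
  steady <- if (case1 || case2 || case3 || case4) "S1" else "S2"
  if (steady == "S1" && tend == "T1") "STABLE"
  else if (steady == "S2" && tend == "T3") "DISORDER"
  else "FLUCTUATING"
}

# from-first-principles recount of the 2x2 detection metrics
oracle_metrics <- function(tp, fp, fn, tn) {
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = tp / (tp + fp),
       recall = tp / (tp + fn),
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# Literal, unoptimised transcription of the time-continuous detection
# loop: scan for the unstable trigger run, then walk the window frame by
# frame, aborting on a sustained stable run or emitting one feature
# vector when the window fills. Feature arithmetic is written out
# directly from the defining formulas.
oracle_detect <- function(seq, states, cfg = detector_config()) {
  n <- nrow(states)
  yat <- function(i, id) seq[[i]]$keypoints[id + 1, "y"]
  mh <- function(i) seq[[i]]$keypoints[9, c("x", "y")]
  tl <- function(i) {
    a <- seq[[i]]$keypoints[2, 1:2]; b <- seq[[i]]$keypoints[9, 1:2]
    sqrt(sum((a - b)^2))
  }
  events <- NULL
  xi <- NULL
  i <- 1
  repeat {
    # --- scan phase ---
    run <- 0; start <- NA
    while (i <= n) {
      if (states$state[i] == "STABLE") {
        if (states$valid[i]) xi <- c(mh(i), tl(i))
        run <- 0
      } else {
        run <- run + 1
        if (run == cfg$unstable_run) { start <- i - cfg$unstable_run + 1 }
      }
      i <- i + 1
      if (!is.na(start)) break
    }
    if (is.na(start)) break
    trigger <- start:(start + cfg$unstable_run - 1)
    # --- window phase ---
    win <- integer(0); srun <- 0; done <- FALSE
    while (i <= n && !done) {
      win <- c(win, i)
      srun <- if (states$state[i] == "STABLE") srun + 1 else 0
      if (srun == cfg$stable_run) {
        if (states$valid[i]) xi <- c(mh(i), tl(i))
        done <- TRUE                      # aborted, no event
      } else if (length(win) == cfg$nsrp_window) {
        feat <- if (cfg$include_trigger) c(trigger, win) else win
        xi_use <- xi
        if (is.null(xi_use)) {
          for (j in c(trigger, win)) if (states$valid[j]) {
            xi_use <- c(mh(j), max(tl(j), 1e-8)); break
          }
        }
        gamma <- 0
        for (j in feat) {
          if (!states$valid[j] || states$state[j] == "STABLE" ||
              is.null(xi_use)) next
          dx <- xi_use[1] - mh(j)[1]; dy <- xi_use[2] - mh(j)[2]
          s <- if (cfg$soft_sign) dy / (1 + abs(dy)) else sign(dy)
          gamma <- gamma + s * sqrt(dx^2 + dy^2) / xi_use[3]
        }
        vj <- feat[vapply(feat, function(j) isTRUE(states$valid[j]),
                          logical(1))]
        eps <- 0
        if (length(vj) > 0 && !is.null(xi_use)) {
          for (id in cfg$lower_limb_ids) {
            ybar <- mean(vapply(vj, yat, numeric(1), id = id))
            for (j in vj) eps <- eps + abs(yat(j, id) - ybar) / xi_use[3]
          }
        }
        tau <- 0
        for (j in feat)
          tau <- tau + switch(states$state[j], STABLE = 0, FLUCTUATING = 1,
                              DISORDER = 2)
        events <- rbind(events, data.frame(
          start_frame = states$frame[trigger[1]],
          end_frame = states$frame[win[length(win)]],
          gamma = unname(gamma), epsilon = unname(eps), tau = tau,
          is_fall = NA))
        done <- TRUE
      }
      i <- i + 1
    }
    if (i > n && !done) break
  }
  if (is.null(events))
    data.frame(start_frame = integer(0), end_frame = integer(0),
               gamma = numeric(0), epsilon = numeric(0), tau = integer(0),
               is_fall = logical(0))
  else { rownames(events) <- NULL; events }
}
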