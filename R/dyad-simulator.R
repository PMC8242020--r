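# Closed-loop dyad simulator: two parameterised actors drive the task engine
# frame by frame; gaze and EEG are generated with the statistical structure
# the downstream analyses assume. The generator is an explicit stand-in for
# human co-actors -- its outputs reproduce the qualitative contrasts of the
# task (skill asymmetry, offset alignment under shared control, gaze lead),
# not any particular human dataset.

#' Actor policy parameters
#'
#' A simulated co-actor is a proportional controller: after a lognormal
#' action-onset latency it steers the cursor it can see straight toward the
#' target with gain-limited deflection and Gaussian directional noise, and
#' releases the stick once the seen cursor has dwelled in the target for the
#' required hold time.
#'
#' @param rt_mean_ms,rt_sd_ms mean and SD of the per-trial onset latency
#'   (lognormal), ms. Nominal means lie in the 200-800 ms response window.
#' @param motor_noise_sd per-frame directional noise, degrees of heading.
#' @param gain proportional gain: deflection = min(1, gain * distance-to-
#'   target in deg).
#' @param aim_noise_sd per-attempt aiming error, deg: the actor steers
#'   toward a Gaussian-perturbed aim point, re-aiming every
#'   `aim_interval_ms` while the seen cursor is outside the target. Misses
#'   (and the late, variable offsets of error trials) emerge from this.
#' @param aim_interval_ms time between corrective re-aims.
#' @param joint_slowing multiplicative slowing of the corrective re-aim
#'   interval on joint-control trials (coordinating corrections through a
#'   shared cursor is slower than correcting one's own).
#' @param joint_rt_slowing multiplicative slowing of the onset latency on
#'   joint-control trials; joint responses start moderately later than solo
#'   ones (on the order of 10-20%).
#' @param giveup_sd variability of the disengagement time. Actors know the
#'   completion deadline (1500 ms after onset) and stop trying around it on
#'   failed trials, at `onset + 1500 * (1 + N(0, giveup_sd))` -- so on error
#'   trials the two co-actors release the stick at different, uncorrelated
#'   times.
#' @param release_ms time over which deflection decays to zero once the
#'   offset policy triggers.
#' @param skill_label `"HP"` or `"LP"` (annotation only; performance is
#'   emergent).
#' @return An `actor_params` list.
#' @export
actor_params <- function(rt_mean_ms = 450, rt_sd_ms = 80,
                         motor_noise_sd = 12, gain = 1.2,
                         aim_noise_sd = 1.0, aim_interval_ms = 500,
                         joint_slowing = 2.4, joint_rt_slowing = 1.12,
                         giveup_sd = 0.25, release_ms = 80,
                         skill_label = "HP") {
  stopifnot(rt_mean_ms > 0, rt_sd_ms >= 0, motor_noise_sd >= 0, gain > 0,
            aim_noise_sd >= 0, aim_interval_ms > 0, joint_slowing >= 1,
            joint_rt_slowing >= 1, giveup_sd >= 0)
  structure(list(rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 motor_noise_sd = motor_noise_sd, gain = gain,
                 aim_noise_sd = aim_noise_sd,
                 aim_interval_ms = aim_interval_ms,
                 joint_slowing = joint_slowing,
                 joint_rt_slowing = joint_rt_slowing,
                 giveup_sd = giveup_sd,
                 release_ms = release_ms, skill_label = skill_label),
            class = "actor_params")
}

#' Default HP/LP actor pair
#'
#' Defaults calibrated so that the two actors' solo visible accuracies
#' bracket the typical higher-/lower-performing range of the task
#' (roughly 65-80% correct) with realistic RT/MT distributions.
#' @return List of two [actor_params()].
#' @export
default_actors <- function() {
  list(actor_params(rt_mean_ms = 420, rt_sd_ms = 60, motor_noise_sd = 10,
                    gain = 1.2, aim_noise_sd = 0.9, skill_label = "HP"),
       actor_params(rt_mean_ms = 490, rt_sd_ms = 90, motor_noise_sd = 22,
                    gain = 1.0, aim_noise_sd = 1.15, skill_label = "LP"))
}

#' Gaze generator parameters
#'
#' Gaze rests at fixation with isotropic jitter, saccades toward the target
#' at a latency tied to the actor's action onset (negative lead = gaze moves
#' before the cursor does), lands with Gaussian error and keeps jittering
#' around the target. Blinks arrive as a Poisson process and zero the pupil.
#'
#' @param fix_jitter_sd fixation jitter SD, deg.
#' @param saccade_lead_ms saccade time relative to the actor's action onset,
#'   ms (negative = gaze leads the cursor).
#' @param landing_sd landing error SD, deg.
#' @param blink_rate_hz blink rate, per second.
#' @param blink_dur_ms blink duration, ms.
#' @param pupil_base,pupil_sd pupil area baseline and noise SD (a.u.).
#' @param rate_hz gaze sampling rate (120 Hz tracker).
#' @return A `gaze_model` list.
#' @export
gaze_model <- function(fix_jitter_sd = 0.5, saccade_lead_ms = -150,
                       landing_sd = 0.8, blink_rate_hz = 0.1,
                       blink_dur_ms = 150, pupil_base = 1000,
                       pupil_sd = 15, rate_hz = 120) {
  structure(as.list(environment()), class = "gaze_model")
}

# one actor's commanded (x, y) deflection for one frame; `aim_pos` is the
# actor's (possibly misaimed) steering goal for the current attempt
simulate_actor_frame <- function(t_ms, rt_ms, released, release_t_ms,
                                 params, seen_pos, aim_pos, const) {
  if (t_ms < rt_ms) return(c(0, 0))
  if (released) {
    frac <- 1 - (t_ms - release_t_ms) / params$release_ms
    if (frac <= 0) return(c(0, 0))
  } else frac <- 1
  dir <- aim_pos - seen_pos
  dist <- sqrt(sum(dir^2))
  if (dist == 0) return(c(0, 0))
  ang <- atan2(dir[2], dir[1]) +
    stats::rnorm(1, 0, params$motor_noise_sd * pi / 180)
  mag <- min(1, params$gain * dist) * frac
  mag * c(cos(ang), sin(ang))
}

#' Simulate a full dyad session
#'
#' Runs the closed loop for every trial of a design. On every trial, three
#' cursor trajectories are produced with identical game logic: the joint
#' (gated-mean) cursor and both actors' solo cursors. On joint-control
#' trials the joint cursor is the visible one and the solo cursors are the
#' invisible counterfactuals; on solo-control trials the two solo cursors
#' are visible and the joint cursor is the invisible counterfactual.
#'
#' The `coupling` mode sets what each actor sees (and therefore steers by)
#' on joint-control trials: `"closed_loop_shared"` -- the common joint
#' cursor, so releases are triggered by the same dwell event;
#' `"independent"` -- each actor's own solo cursor, removing the shared
#' feedback loop while keeping the averaged joint cursor defined. Solo
#' trials are always independent.
#'
#' @param design a [generate_design()] table (any size).
#' @param actors list of two [actor_params()].
#' @param coupling `"closed_loop_shared"` or `"independent"`.
#' @param forward an [eeg_forward_model()] or `NULL` to skip EEG synthesis.
#' @param gaze a [gaze_model()] or `NULL` to skip gaze.
#' @param seed integer seed; (design, params, seed) fully determine every
#'   output array.
#' @param const task constants.
#' @return A `pair_session` list: `design`, `outcomes` (one row per trial x
#'   cursor owner), `events` (per-trial controller onset/offset times per
#'   actor plus the joint-cursor offset, ms relative to the spatial cue),
#'   `traces` (per trial: two n x 2 controller matrices), `trajectories`
#'   (per trial: `joint`, `solo1`, `solo2` position matrices), `gaze`
#'   (per trial: two gaze data.frames), `eeg` (list of two
#'   `eeg_recording`s or `NULL`), `trial_info` (recording-time marker
#'   table), `seed`, `coupling`.
#' @export
simulate_pair_session <- function(design,
                                  actors = default_actors(),
                                  coupling = c("closed_loop_shared",
                                               "independent"),
                                  forward = NULL,
                                  gaze = gaze_model(),
                                  seed = 1,
                                  const = task_constants()) {
  coupling <- match.arg(coupling)
  stopifnot(length(actors) == 2L)
  set.seed(as.integer(seed))
  n_trials <- nrow(design)
  tpos <- target_positions(const)
  frame_ms <- 1000 / const$frame_hz
  n_frames <- round(const$action_ms / frame_ms)
  dwell_ms <- const$dwell_ms

  lnorm_par <- function(m, s) {
    if (s == 0) return(c(log(m), 0))
    c(log(m^2 / sqrt(s^2 + m^2)), sqrt(log(1 + s^2 / m^2)))
  }
  rts <- matrix(sapply(actors, function(a) {
    p <- lnorm_par(a$rt_mean_ms, a$rt_sd_ms)
    if (p[2] == 0) rep(a$rt_mean_ms, n_trials)
    else stats::rlnorm(n_trials, p[1], p[2])
  }), nrow = n_trials)

  traces <- trajectories <- gaze_out <- vector("list", n_trials)
  outcomes <- events <- vector("list", n_trials)
  start_ms <- 0
  trial_info <- vector("list", n_trials)

  for (tr in seq_len(n_trials)) {
    spec <- design[tr, ]
    tl <- generate_timeline(spec$delay_ms)
    target <- tpos[spec$target_index, ]
    shared_view <- spec$control == "joint" && coupling == "closed_loop_shared"

    inp <- list(matrix(0, n_frames, 2), matrix(0, n_frames, 2))
    pos_joint <- pos_solo1 <- pos_solo2 <- matrix(0, n_frames + 1L, 2)
    released <- c(FALSE, FALSE); release_t <- c(NA_real_, NA_real_)
    dwell <- c(0, 0)
    aims <- lapply(actors, function(a)
      target + stats::rnorm(2, 0, a$aim_noise_sd))
    # coordination cost of joint control: slightly slower onsets, markedly
    # sparser corrections
    joint_trial_flag <- spec$control == "joint"
    rt_tr <- rts[tr, ] * (if (joint_trial_flag)
      vapply(actors, `[[`, 0, "joint_rt_slowing") else c(1, 1))
    aim_iv <- vapply(actors, `[[`, 0, "aim_interval_ms") *
      (if (joint_trial_flag) vapply(actors, `[[`, 0, "joint_slowing")
       else c(1, 1))
    aim_t <- rt_tr                          # attempt clock starts at onset
    # disengagement: on failed trials each actor quits near the completion
    # deadline, at an individually variable time
    giveup_t <- rt_tr + const$mt_max_ms *
      (1 + vapply(actors, function(a) stats::rnorm(1, 0, a$giveup_sd), 0))
    # the closed loop is iterated with inlined scalar physics (identical to
    # step_cursor, which stays the reference implementation and is asserted
    # against in the tests)
    gate <- const$gate_frac
    step_deg <- const$px_per_frame / const$px_per_deg
    bound <- const$display_half_deg
    clamp2 <- function(p) {
      p[p > bound] <- bound; p[p < -bound] <- -bound; p
    }
    for (f in seq_len(n_frames)) {
      t_ms <- (f - 1L) * frame_ms
      s1 <- if (shared_view) pos_joint[f, ] else pos_solo1[f, ]
      s2 <- if (shared_view) pos_joint[f, ] else pos_solo2[f, ]
      for (i in 1:2) {
        seen_i <- if (i == 1L) s1 else s2
        inside <- FALSE
        if (!released[i]) {
          dx <- seen_i[1] - target[1]; dy <- seen_i[2] - target[2]
          inside <- (dx * dx + dy * dy) <= const$target_radius^2
          dwell[i] <- if (inside) dwell[i] + frame_ms else 0
          # release on success, or disengage on a failing trial -- never
          # while the cursor is inside the target accumulating dwell
          if (dwell[i] >= dwell_ms || (!inside && t_ms >= giveup_t[i])) {
            released[i] <- TRUE; release_t[i] <- t_ms
          }
          # corrective re-aim while the attempt is clearly failing
          if (!inside && t_ms >= rt_tr[i] &&
              t_ms - aim_t[i] >= aim_iv[i]) {
            aims[[i]] <- target + stats::rnorm(2, 0, actors[[i]]$aim_noise_sd)
            aim_t[i] <- t_ms
          }
        }
        inp[[i]][f, ] <- simulate_actor_frame(
          t_ms, rt_tr[i], released[i], release_t[i],
          actors[[i]], seen_i, aims[[i]], const)
      }
      i1 <- inp[[1L]][f, ]; i2 <- inp[[2L]][f, ]
      m1 <- sqrt(i1[1]^2 + i1[2]^2) > gate
      m2 <- sqrt(i2[1]^2 + i2[2]^2) > gate
      vj <- if (m1 && m2) (i1 + i2) * (0.5 * step_deg) else c(0, 0)
      v1 <- if (m1) i1 * step_deg else c(0, 0)
      v2 <- if (m2) i2 * step_deg else c(0, 0)
      pos_joint[f + 1L, ] <- clamp2(pos_joint[f, ] + vj)
      pos_solo1[f + 1L, ] <- clamp2(pos_solo1[f, ] + v1)
      pos_solo2[f + 1L, ] <- clamp2(pos_solo2[f, ] + v2)
    }
    traces[[tr]] <- inp
    trajectories[[tr]] <- list(joint = pos_joint, solo1 = pos_solo1,
                               solo2 = pos_solo2)

    joint_trial <- spec$control == "joint"
    sc <- lapply(list(joint = pos_joint, solo1 = pos_solo1, solo2 = pos_solo2),
                 score_trial, target_centre = target, const = const)
    outcomes[[tr]] <- do.call(rbind, Map(function(nm, s) {
      cbind(data.frame(trial = spec$trial, control = spec$control, owner = nm,
                       visible = if (joint_trial) nm == "joint"
                                 else nm != "joint",
                       stringsAsFactors = FALSE), s)
    }, names(sc), sc))

    # controller events (10% rule) and the joint-cursor offset
    ev <- lapply(1:2, function(i)
      detect_onset_offset(displacement_series(inp[[i]]),
                          100 * const$gate_frac, const$frame_hz))
    jstep <- rowSums(abs(diff(pos_joint))) > 0
    joint_off <- if (any(jstep))
      (max(which(jstep)) - 1L) * frame_ms else NA_real_
    events[[tr]] <- data.frame(
      trial = spec$trial, control = spec$control,
      onset1_ms = ev[[1]]$onset_ms, offset1_ms = ev[[1]]$offset_ms,
      onset2_ms = ev[[2]]$onset_ms, offset2_ms = ev[[2]]$offset_ms,
      joint_offset_ms = joint_off)

    if (!is.null(gaze)) {
      gaze_out[[tr]] <- lapply(1:2, function(i)
        simulate_gaze_trial(tl, target, rts[tr, i], gaze))
    }

    trial_info[[tr]] <- data.frame(
      trial = spec$trial, control = spec$control,
      target_freq_hz = spec$target_freq_hz,
      distractor_freq_hz = spec$distractor_freq_hz,
      start_ms = start_ms,
      precue_ms = start_ms + tl$onset[["precue"]],
      cue_ms = start_ms + tl$onset[["control_cue"]],
      spatial_ms = start_ms + tl$spatial_cue_ms,
      total_ms = tl$total_ms)
    start_ms <- start_ms + tl$total_ms
  }

  outcomes <- do.call(rbind, outcomes); rownames(outcomes) <- NULL
  events <- do.call(rbind, events); rownames(events) <- NULL
  trial_info <- do.call(rbind, trial_info)

  eeg <- NULL
  if (!is.null(forward)) {
    # each participant's offset potential is generated by their own action:
    # it locks to their own controller offset in both conditions. Under
    # shared control those offsets are tightly aligned within the pair on
    # successful trials (common dwell trigger) and drift apart on failed
    # ones -- the alignment, not the insertion rule, carries the condition
    # difference.
    eeg <- lapply(1:2, function(i) {
      own_off <- if (i == 1L) events$offset1_ms else events$offset2_ms
      ti <- trial_info
      ti$offset_ms <- ti$spatial_ms + own_off
      synthesize_eeg(ti, forward, seed = as.integer(seed) + i,
                     participant = i, pair = 1L)
    })
  }

  structure(list(design = design, outcomes = outcomes, events = events,
                 traces = traces, trajectories = trajectories,
                 gaze = gaze_out, eeg = eeg, trial_info = trial_info,
                 seed = seed, coupling = coupling, const = const,
                 actors = actors),
            class = "pair_session")
}

#' @export
print.pair_session <- function(x, ...) {
  acc <- function(v) {
    o <- x$outcomes[x$outcomes$visible == v, ]
    100 * mean(o$outcome == "correct")
  }
  cat(sprintf(
    "Pair session: %d trials (%s coupling), visible accuracy %.1f%%, invisible %.1f%%%s\n",
    nrow(x$design), x$coupling, acc(TRUE), acc(FALSE),
    if (is.null(x$eeg)) "" else sprintf(", EEG at %g Hz", x$eeg[[1]]$rate_hz)))
  invisible(x)
}

# gaze for one participant on one trial, sampled across the whole trial
simulate_gaze_trial <- function(tl, target, rt_ms, gm) {
  n <- round(tl$total_ms / 1000 * gm$rate_hz)
  t_ms <- (seq_len(n) - 1L) / gm$rate_hz * 1000
  sacc_ms <- tl$spatial_cue_ms + rt_ms + gm$saccade_lead_ms
  at_target <- t_ms >= sacc_ms
  gx <- stats::rnorm(n, 0, gm$fix_jitter_sd)
  gy <- stats::rnorm(n, 0, gm$fix_jitter_sd)
  if (any(at_target)) {
    land <- target + stats::rnorm(2, 0, gm$landing_sd)
    gx[at_target] <- land[1] + stats::rnorm(sum(at_target), 0, gm$fix_jitter_sd)
    gy[at_target] <- land[2] + stats::rnorm(sum(at_target), 0, gm$fix_jitter_sd)
  }
  pupil <- gm$pupil_base + stats::rnorm(n, 0, gm$pupil_sd)
  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, gm$blink_rate_hz * tl$total_ms / 1000)
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, 0, tl$total_ms - gm$blink_dur_ms)
    for (s in starts) {
      idx <- t_ms >= s & t_ms <= s + gm$blink_dur_ms
      pupil[idx] <- 0; valid[idx] <- FALSE
    }
  }
  data.frame(t_ms = t_ms, x = gx, y = gy, pupil = pupil, valid = valid)
}
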