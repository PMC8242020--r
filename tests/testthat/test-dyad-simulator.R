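# Closed-loop dyad simulator: determinism, coupling manipulation, forward
# model additivity, and the gaze-lead property.

test_that("simulation is fully determined by (design, params, seed)", {
  des <- generate_design(1, 16, seed = 5)
  s1 <- simulate_pair_session(des, forward = NULL, gaze = NULL, seed = 9)
  s2 <- simulate_pair_session(des, forward = NULL, gaze = NULL, seed = 9)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$outcomes, s2$outcomes)
  s3 <- simulate_pair_session(des, forward = NULL, gaze = NULL, seed = 10)
  expect_false(identical(s1$traces, s3$traces))
})

test_that("identical noise-free actors under shared control act as one", {
  a <- actor_params(rt_mean_ms = 400, rt_sd_ms = 0, motor_noise_sd = 0,
                    aim_noise_sd = 0)
  des <- generate_design(1, 16, seed = 2)
  s <- simulate_pair_session(des, actors = list(a, a), forward = NULL,
                             gaze = NULL, seed = 3)
  for (tr in seq_len(4)) {
    expect_equal(s$traces[[tr]][[1]], s$traces[[tr]][[2]])
    r <- trial_displacement_correlation(
      displacement_series(s$traces[[tr]][[1]]),
      displacement_series(s$traces[[tr]][[2]]))
    expect_equal(r$r, 1)
    # equal inputs: the joint cursor retraces the solo cursors
    expect_equal(s$trajectories[[tr]]$joint, s$trajectories[[tr]]$solo1)
  }
})

test_that("shared control couples action offsets; independent control does not", {
  des <- generate_design(4, 48, seed = 6)   # 192 trials, 96 joint
  sh <- simulate_pair_session(des, coupling = "closed_loop_shared",
                              forward = NULL, gaze = NULL, seed = 21)
  ind <- simulate_pair_session(des, coupling = "independent",
                               forward = NULL, gaze = NULL, seed = 21)
  j <- sh$events$control == "joint"
  r_sh <- across_trial_event_correlation(sh$events$offset1_ms[j],
                                         sh$events$offset2_ms[j])
  r_ind <- across_trial_event_correlation(ind$events$offset1_ms[j],
                                          ind$events$offset2_ms[j])
  expect_gt(r_sh$r, 0.5)
  ct <- stats::cor.test(sh$events$offset1_ms[j], sh$events$offset2_ms[j])
  expect_lt(ct$p.value, 0.01)
  expect_lt(abs(r_ind$r), 0.25)
  expect_gt(r_sh$r, r_ind$r)
})

test_that("the EEG forward model is additive and marker-locked", {
  des <- generate_design(1, 16, seed = 4)
  sess <- simulate_pair_session(des, forward = NULL, gaze = NULL, seed = 4)
  ti <- sess$trial_info
  ti$offset_ms <- ti$spatial_ms + ifelse(ti$control == "joint",
                                         sess$events$joint_offset_ms,
                                         sess$events$offset1_ms)
  fw <- eeg_forward_model(rate_hz = 128)
  comps <- c("noise", "cue_ssvep", "tag_ssvep", "onset_erp", "offset_erp")
  full <- synthesize_eeg(ti, fw, seed = 31)
  parts <- lapply(comps, function(k)
    synthesize_eeg(ti, fw, seed = 31, include = k)$data)
  expect_equal(Reduce(`+`, parts), full$data, tolerance = 1e-12)

  # all amplitudes zero -> the noise process alone, mean ~ 0
  fw0 <- eeg_forward_model(rate_hz = 128,
                           cue_ssvep = NULL, tag_ssvep = NULL,
                           onset_erp = NULL, offset_erp = NULL)
  noise_only <- synthesize_eeg(ti, fw0, seed = 31)
  expect_lt(abs(mean(noise_only$data)), 0.5)
  expect_equal(noise_only$data,
               synthesize_eeg(ti, fw, seed = 31, include = "noise")$data)

  # markers outside the recording span are refused
  bad <- ti
  bad$offset_ms[1] <- 1e9
  expect_error(synthesize_eeg(bad, fw, seed = 1), "outside")
})

test_that("a pure phase-locked tag reads out at its set amplitude", {
  # single trial, no noise: 7 Hz cue tag at 2 uV; an integer-cycle window
  # starting at cue onset recovers 2 uV at the 7 Hz bin at the map's peak
  des <- generate_design(1, 16, seed = 8)[1, , drop = FALSE]
  des$trial <- 1L
  sess <- simulate_pair_session(des, forward = NULL, gaze = NULL, seed = 8)
  ti <- sess$trial_info
  ti$offset_ms <- NA_real_
  fw <- eeg_forward_model(rate_hz = 256, noise_uv = 0)
  rec <- synthesize_eeg(ti, fw, seed = 1, include = "cue_ssvep")
  ep <- epoch_eeg(rec, "control_cue_onset", window_s = c(0, 1))
  oz <- match("Oz", rec$labels)
  amp_set <- fw$cue_ssvep$amp_uv *
    (if (des$control == "joint") fw$cue_ssvep$joint_gain else 1)
  sp <- fft_amplitude(ep$data[1, oz, 1:256], 256)
  expect_equal(spectrum_at(sp, 7), amp_set, tolerance = 0.02)
  # occipital gain map peaks at Oz and is max-normalised
  g <- gain_map("Oz")
  expect_equal(unname(g["Oz"]), 1)
  expect_true(all(g >= 0 & g <= 1))
  expect_lt(g["Fpz"], 0.1)
})

test_that("gaze leads the cursor to the target", {
  fx <- fixtures()
  sess <- fx$session
  tpos <- target_positions()
  gaze_first <- cursor_first <- c()
  for (tr in seq_len(nrow(sess$design))) {
    oc <- sess$outcomes[sess$outcomes$trial == tr, ]
    vis_owner <- if (sess$design$control[tr] == "joint") "joint" else "solo1"
    if (oc$outcome[oc$owner == vis_owner] != "correct") next
    tl <- generate_timeline(sess$design$delay_ms[tr])
    target <- tpos[sess$design$target_index[tr], ]
    g <- sess$gaze[[tr]][[1]]
    gd <- sqrt((g$x - target[1])^2 + (g$y - target[2])^2)
    gt <- g$t_ms - tl$spatial_cue_ms
    tj <- sess$trajectories[[tr]][[vis_owner]]
    cd <- sqrt((tj[, 1] - target[1])^2 + (tj[, 2] - target[2])^2)
    ct <- (seq_len(nrow(tj)) - 1L) * 1000 / 144
    if (!any(gd < 2.5 & gt > 0) || !any(cd < 2.5)) next
    gaze_first <- c(gaze_first, min(gt[gd < 2.5 & gt > 0]))
    cursor_first <- c(cursor_first, min(ct[cd < 2.5]))
  }
  expect_gt(length(gaze_first), 3)
  expect_lt(median(gaze_first), median(cursor_first))
})
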