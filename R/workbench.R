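# Orchestration: declarative configuration, the end-to-end synthetic dyad
# pipeline (simulate -> preprocess -> behaviour -> neural -> inter-brain ->
# stats), report generation, and canned fixtures for the test suite.

#' Pipeline configuration
#'
#' All tunable defaults of the end-to-end pipeline in one declarative list.
#' Unknown keys are rejected. `load_config()` reads a YAML file and merges
#' it over the defaults; every run archives its resolved configuration
#' beside its outputs.
#'
#' @param ... name-value overrides of the defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_pairs = 20,              # simulated pairs
    blocks = 3,                # blocks per session
    block_size = 16,           # trials per block (multiple of 16)
    seed = 1,
    coupling = "closed_loop_shared",
    eeg_rate_hz = 256,         # native synthesis rate; SSVEP analyses run here
    corr_rate_hz = 64,         # analysis rate for inter-brain correlation
    epoch_window_s = c(-2.5, 3.0),
    cue_window_s = c(0, 1.424),
    offset_window_s = c(-0.5, 1.0),
    coupling_window_ms = 500,
    step_samples = 1,
    alpha_coupling = 1e-4,
    n_perm = 1000,
    artefact_uv = 100,
    simulate_eeg = TRUE,
    simulate_gaze = TRUE
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  if (cfg$block_size %% 16 != 0) stop("block_size must be a multiple of 16")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# split a full-session coupling computation into per-condition mean maps
# (maps only -- the per-trial array is kept once, on the parent object)
coupling_condition_maps <- function(cmap, labels) {
  out <- list()
  for (cond in unique(labels)) {
    sel <- cmap$included & labels == cond
    m <- apply(cmap$per_trial[sel, , , drop = FALSE], c(2L, 3L), mean,
               na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[[cond]] <- list(map = m, included = sel,
                        times_s = cmap$times_s, labels = cmap$labels)
  }
  out
}

# process one simulated pair end to end; returns the per-pair artefacts the
# group-level statistics need (raw EEG is dropped on exit)
process_pair <- function(pair_id, cfg, forward, actors, gaze_mod) {
  des <- generate_design(cfg$blocks, cfg$block_size,
                         seed = cfg$seed * 1000L + pair_id)
  sess <- simulate_pair_session(
    des, actors = actors, coupling = cfg$coupling,
    forward = if (cfg$simulate_eeg) forward else NULL,
    gaze = if (cfg$simulate_gaze) gaze_mod else NULL,
    seed = cfg$seed * 1000L + pair_id)

  out <- list(pair = pair_id, outcomes = cbind(pair = pair_id, sess$outcomes),
              events = cbind(pair = pair_id, sess$events))

  # behavioural coupling: displacement correlation per trial
  disp_r <- vapply(seq_len(nrow(des)), function(tr) {
    trial_displacement_correlation(
      displacement_series(sess$traces[[tr]][[1]]),
      displacement_series(sess$traces[[tr]][[2]]))$r
  }, numeric(1))
  out$trial_behaviour <- data.frame(
    pair = pair_id, trial = des$trial, control = des$control,
    displacement_r = disp_r,
    offset_abs_diff_ms = abs(sess$events$offset1_ms - sess$events$offset2_ms))

  # per-trial kinematics and accuracy of the visible cursor(s)
  vis <- sess$outcomes[sess$outcomes$visible, ]
  kin <- do.call(rbind, lapply(seq_len(nrow(des)), function(tr) {
    target <- target_positions(sess$const)[des$target_index[tr], ]
    rows <- vis[vis$trial == des$trial[tr], ]
    vals <- vapply(rows$owner, function(ow) {
      tj <- sess$trajectories[[tr]][[ow]]
      c(curv = curvature(tj)$mean_k,
        endpt = endpoint_displacement(tj, target))
    }, numeric(2))
    data.frame(trial = des$trial[tr], control = des$control[tr],
               curvature = mean(vals["curv", ], na.rm = TRUE),
               endpoint_deg = mean(vals["endpt", ]),
               accuracy = mean(rows$outcome == "correct"))
  }))
  out$trial_behaviour <- merge(out$trial_behaviour, kin,
                               by = c("trial", "control"))
  # keep rows in trial order: downstream arrays (per-trial coupling) are
  # indexed by trial position
  out$trial_behaviour <- out$trial_behaviour[order(out$trial_behaviour$trial), ]

  if (cfg$simulate_eeg) {
    recs <- lapply(sess$eeg, filter_eeg)
    cond <- data.frame(trial = des$trial, control = des$control)

    # SSVEP: control-cue epochs at the native rate
    cue_ep <- lapply(recs, epoch_eeg, event = "control_cue_onset",
                     window_s = cfg$cue_window_s, conditions = cond)
    cue_ep <- lapply(cue_ep, reject_artefact_trials, cfg$artefact_uv)
    out$cue_erp <- lapply(cue_ep, function(e) list(
      joint = average_erp(e, e$conditions$control == "joint"),
      solo = average_erp(e, e$conditions$control == "solo")))

    # offset-locked ERPs (own offsets on solo, common joint-cursor offset)
    out$offset_erp <- lapply(1:2, function(i) {
      own <- if (i == 1) sess$events$offset1_ms else sess$events$offset2_ms
      rel <- ifelse(des$control == "joint", sess$events$joint_offset_ms, own)
      abs_ms <- sess$trial_info$spatial_ms + rel
      list(joint = offset_locked_erp(recs[[i]],
                                     abs_ms[des$control == "joint"],
                                     cfg$offset_window_s),
           solo = offset_locked_erp(recs[[i]],
                                    abs_ms[des$control == "solo"],
                                    cfg$offset_window_s))
    })

    # inter-brain coupling at the correlation analysis rate
    eps64 <- lapply(recs, function(r) {
      r64 <- resample_eeg(r, cfg$corr_rate_hz)
      e <- epoch_eeg(r64, "spatial_cue_onset", cfg$epoch_window_s,
                     conditions = cond)
      reject_artefact_trials(e, cfg$artefact_uv)
    })
    cmap <- sliding_interbrain_correlation(eps64[[1]], eps64[[2]],
                                           cfg$coupling_window_ms,
                                           cfg$step_samples)
    # truncated edge windows are flagged by the correlation stage and
    # excluded from inference
    full <- !cmap$truncated
    cmap$per_trial <- cmap$per_trial[, , full, drop = FALSE]
    cmap$map <- cmap$map[, full, drop = FALSE]
    cmap$times_s <- cmap$times_s[full]
    cmap$truncated <- cmap$truncated[full]
    out$coupling <- list(per_trial = cmap$per_trial,
                         included = cmap$included,
                         labels = des$control,
                         times_s = cmap$times_s,
                         electrode_labels = cmap$labels)
    out$condition_maps <- coupling_condition_maps(cmap, des$control)
  }

  if (cfg$simulate_gaze) {
    # gaze/cursor distance-to-target profiles on normalised action time
    prof <- list()
    for (tr in seq_len(nrow(des))) {
      vis_owner <- if (des$control[tr] == "joint") "joint" else "solo1"
      oc <- sess$outcomes[sess$outcomes$trial == des$trial[tr] &
                          sess$outcomes$owner == vis_owner, ]
      if (oc$outcome != "correct") next
      tl <- generate_timeline(des$delay_ms[tr])
      g <- clean_gaze(sess$gaze[[tr]][[1]])
      target <- target_positions(sess$const)[des$target_index[tr], ]
      prof[[length(prof) + 1L]] <- gaze_cursor_timing(
        g, sess$trajectories[[tr]][[vis_owner]], target,
        oc$rt_ms, oc$completion_ms, tl$spatial_cue_ms)
    }
    if (length(prof)) {
      pr <- do.call(rbind, prof)
      out$gaze_profile <- stats::aggregate(
        cbind(gaze_deg, cursor_deg) ~ pct, data = pr, FUN = mean)
    }
  }
  out
}

#' Run the end-to-end synthetic dyad pipeline
#'
#' Simulates `n_pairs` dyad sessions and carries them through the full
#' analysis chain: preprocessing, behavioural metrics and coupling, SSVEP
#' and offset-locked ERPs, sliding-window inter-brain correlation with the
#' joint-minus-solo permutation contrast and peak slice, and the
#' single-trial correlation/regression statistics. Stages run per pair and
#' are cached to `out_dir/cache` when an output directory is given, so an
#' interrupted run resumes from the completed pairs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; receives summary CSVs, a JSON
#'   report, the resolved configuration (YAML) and a plain-text log.
#' @param resume reuse cached per-pair artefacts found in `out_dir/cache`.
#' @param forward,actors,gaze generator models (defaults:
#'   [eeg_forward_model()] at the configured rate, [default_actors()],
#'   [gaze_model()]).
#' @return A `dyad_pipeline` list: `behaviour` (per-trial and summary
#'   tables), `coupling` (grand-mean maps, permutation result, peak slice),
#'   `neural` (grand-mean cue spectra, offset ERP, delta-band peak),
#'   `stats` (ANOVAs, single-trial correlations and regression), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         resume = FALSE, forward = NULL, actors = NULL,
                         gaze = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(forward)) forward <- eeg_forward_model(rate_hz = config$eeg_rate_hz)
  if (is.null(actors)) actors <- default_actors()
  if (is.null(gaze)) gaze <- gaze_model()
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
    invisible(NULL)
  }
  cache_dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cache_dir <- file.path(out_dir, "cache")
    dir.create(cache_dir, showWarnings = FALSE)
  }

  pairs <- vector("list", config$n_pairs)
  for (p in seq_len(config$n_pairs)) {
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("pair_%02d.rds", p)) else NULL
    if (resume && !is.null(cache_file) && file.exists(cache_file)) {
      pairs[[p]] <- readRDS(cache_file)
      logf("pair %d: loaded from cache", p)
      next
    }
    pairs[[p]] <- process_pair(p, config, forward, actors, gaze)
    if (!is.null(cache_file)) saveRDS(pairs[[p]], cache_file)
    logf("pair %d: simulated and processed (%d trials)", p,
         config$blocks * config$block_size)
    gc(FALSE)
  }

  outcomes <- do.call(rbind, lapply(pairs, `[[`, "outcomes"))
  trial_behaviour <- do.call(rbind, lapply(pairs, `[[`, "trial_behaviour"))

  # behavioural summaries and ANOVA-style tables
  acc_cells <- do.call(rbind, lapply(pairs, function(pp) {
    oc <- pp$outcomes
    agg <- stats::aggregate(outcome ~ control + visible, data = oc,
                            FUN = function(v) 100 * mean(v == "correct"))
    names(agg)[3] <- "accuracy_pct"
    cbind(pair = pp$pair, agg)
  }))
  behaviour <- list(outcomes = outcomes, trial = trial_behaviour,
                    accuracy_cells = acc_cells)
  stats_out <- list()
  # group-level ANOVAs need several pairs; tiny exploratory runs skip them
  stats_out$accuracy_anova <- tryCatch(
    rm_anova(acc_cells, "accuracy_pct", "pair", c("visible", "control")),
    error = function(e) NULL)
  disp_cells <- stats::aggregate(displacement_r ~ pair + control,
                                 data = trial_behaviour, FUN = mean,
                                 na.rm = TRUE)
  stats_out$displacement_anova <- tryCatch(
    rm_anova(disp_cells, "displacement_r", "pair", "control"),
    error = function(e) NULL)

  neural <- coupling <- NULL
  if (config$simulate_eeg) {
    # grand-mean control-cue ERP per condition, across pairs and participants
    mean_erps <- function(field, cond) {
      es <- unlist(lapply(pairs, function(pp)
        lapply(pp[[field]], function(x) x[[cond]])), recursive = FALSE)
      dat <- Reduce(`+`, lapply(es, `[[`, "data")) / length(es)
      e <- es[[1]]
      e$data <- dat
      e$n_trials <- sum(vapply(es, `[[`, 0, "n_trials"))
      e
    }
    cue_joint <- mean_erps("cue_erp", "joint")
    cue_solo <- mean_erps("cue_erp", "solo")
    occ <- match(c("O1", "Oz", "O2"), cue_joint$labels)
    sp_joint <- fft_amplitude(cue_joint$data, cue_joint$rate_hz)
    sp_solo <- fft_amplitude(cue_solo$data, cue_solo$rate_hz)
    cue7 <- c(joint = mean(vapply(occ, function(ch)
                spectrum_at(sp_joint, 7, ch), numeric(1))),
              solo = mean(vapply(occ, function(ch)
                spectrum_at(sp_solo, 7, ch), numeric(1))))

    off_joint <- mean_erps("offset_erp", "joint")
    off_solo <- mean_erps("offset_erp", "solo")
    cz <- match("Cz", off_joint$labels)
    tfr <- morlet_tfr(off_joint$data[cz, ], off_joint$rate_hz,
                      freqs_hz = seq(0.5, 20, by = 0.5))
    prof <- apply(tfr$amplitude[1, , ], 1L, max)
    neural <- list(cue_erp = list(joint = cue_joint, solo = cue_solo),
                   cue_ssvep_7hz_uv = cue7,
                   offset_erp = list(joint = off_joint, solo = off_solo),
                   offset_tfr_freqs = tfr$freq_hz,
                   offset_tfr_profile = prof,
                   offset_delta_peak_hz = tfr$freq_hz[which.max(prof)])

    # inter-brain coupling: grand means, permutation contrast, peak slice
    grand <- function(cond) {
      maps <- lapply(pairs, function(pp) pp$condition_maps[[cond]]$map)
      Reduce(`+`, maps) / length(maps)
    }
    map_joint <- grand("joint"); map_solo <- grand("solo")
    per_pair <- lapply(pairs, function(pp)
      list(per_trial = pp$coupling$per_trial[pp$coupling$included, , ,
                                             drop = FALSE],
           labels = pp$coupling$labels[pp$coupling$included]))
    perm <- coupling_permutation_test(
      per_pair, alpha = config$alpha_coupling, n_perm = config$n_perm,
      seed = config$seed, times_s = pairs[[1]]$coupling$times_s,
      labels = pairs[[1]]$coupling$electrode_labels)
    peak <- find_peak_slice(perm$observed, perm$mask, perm$times_s,
                            perm$labels)
    logf("coupling peak: %s at %.0f ms (%ssignificant)", peak$electrode,
         1000 * peak$latency_s, if (peak$significant) "" else "not ")

    # single-trial statistics at the peak slice
    st <- do.call(rbind, lapply(pairs, function(pp) {
      v <- pp$coupling$per_trial[, peak$channel, peak$centre_index]
      v[!pp$coupling$included] <- NA
      tb <- pp$trial_behaviour
      data.frame(pair = pp$pair, trial = tb$trial, condition = tb$control,
                 coupling = v, accuracy = tb$accuracy,
                 endpoint_deg = tb$endpoint_deg,
                 behav_coupling_ms = tb$offset_abs_diff_ms,
                 curvature = tb$curvature)
    }))
    st_corr <- lapply(c(endpoint = "endpoint_deg",
                        behavioural_coupling = "behav_coupling_ms",
                        accuracy = "accuracy"),
                      function(m) tryCatch(
                        single_trial_coupling_correlations(st, m,
                                                           min_trials = 5L),
                        error = function(e) NULL))
    regressors <- c("accuracy", "endpoint_deg", "behav_coupling_ms")
    st_joint <- st[st$condition == "joint", ]
    st_reg <- tryCatch(
      single_trial_regression(st_joint, regressors, alpha = 0.05),
      error = function(e) NULL)
    coupling <- list(map_joint = map_joint, map_solo = map_solo,
                     contrast = map_joint - map_solo,
                     times_s = perm$times_s, labels = perm$labels,
                     permutation = perm, peak = peak,
                     single_trial = st, correlations = st_corr,
                     regression = st_reg)
  }

  gaze_profile <- NULL
  profs <- lapply(pairs, `[[`, "gaze_profile")
  profs <- profs[!vapply(profs, is.null, logical(1))]
  if (length(profs)) {
    pr <- do.call(rbind, profs)
    gaze_profile <- stats::aggregate(cbind(gaze_deg, cursor_deg) ~ pct,
                                     data = pr, FUN = mean)
  }

  result <- structure(
    list(behaviour = behaviour, coupling = coupling, neural = neural,
         gaze_profile = gaze_profile, stats = stats_out,
         config = config, log = log_lines),
    class = "dyad_pipeline")

  if (!is.null(out_dir)) {
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    utils::write.csv(trial_behaviour,
                     file.path(out_dir, "trial_behaviour.csv"),
                     row.names = FALSE)
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(acc_cells, file.path(out_dir, "accuracy_cells.csv"),
                     row.names = FALSE)
    report <- pipeline_report(result)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  result
}

#' Headline numbers of a pipeline run
#'
#' Collects the run's main computed quantities (accuracies, coupling peak,
#' SSVEP amplitudes, delta peak, regression coefficients) into a flat list
#' suitable for a JSON report.
#'
#' @param x a `dyad_pipeline`.
#' @return Named list of scalars.
#' @export
pipeline_report <- function(x) {
  oc <- x$behaviour$outcomes
  rep <- list(
    n_pairs = x$config$n_pairs,
    n_trials_per_pair = x$config$blocks * x$config$block_size,
    visible_accuracy_pct = 100 * mean(oc$outcome[oc$visible] == "correct"),
    invisible_accuracy_pct = 100 * mean(oc$outcome[!oc$visible] == "correct"),
    seed = x$config$seed)
  tb <- x$behaviour$trial
  rep$displacement_r_joint <- mean(tb$displacement_r[tb$control == "joint"],
                                   na.rm = TRUE)
  rep$displacement_r_solo <- mean(tb$displacement_r[tb$control == "solo"],
                                  na.rm = TRUE)
  if (!is.null(x$coupling)) {
    rep$peak_electrode <- x$coupling$peak$electrode
    rep$peak_latency_ms <- 1000 * x$coupling$peak$latency_s
    rep$peak_contrast_r <- x$coupling$peak$value
    rep$peak_significant <- x$coupling$peak$significant
    rep$n_significant_cells <- sum(x$coupling$permutation$mask)
  }
  if (!is.null(x$neural)) {
    rep$cue_ssvep_7hz_joint_uv <- unname(x$neural$cue_ssvep_7hz_uv["joint"])
    rep$cue_ssvep_7hz_solo_uv <- unname(x$neural$cue_ssvep_7hz_uv["solo"])
    rep$offset_delta_peak_hz <- x$neural$offset_delta_peak_hz
  }
  if (!is.null(x$gaze_profile)) {
    at50 <- x$gaze_profile[x$gaze_profile$pct == 50, ]
    rep$gaze_dist_at_50pct_deg <- at50$gaze_deg
    rep$cursor_dist_at_50pct_deg <- at50$cursor_deg
  }
  rep
}

#' @export
print.dyad_pipeline <- function(x, ...) {
  r <- pipeline_report(x)
  cat(sprintf("Dyad pipeline: %d pairs x %d trials\n", r$n_pairs,
              r$n_trials_per_pair))
  cat(sprintf("  accuracy: visible %.1f%%, invisible %.1f%%\n",
              r$visible_accuracy_pct, r$invisible_accuracy_pct))
  if (!is.null(x$coupling))
    cat(sprintf("  coupling peak: %s, %.0f ms, joint-solo r = %.3f (%s)\n",
                r$peak_electrode, r$peak_latency_ms, r$peak_contrast_r,
                if (r$peak_significant) "significant" else "n.s."))
  invisible(x)
}

# straight-to-target trajectory with a chosen onset; used by fixtures
canned_trajectory <- function(kind = c("correct", "too_fast", "too_slow",
                                       "missed"),
                              const = task_constants()) {
  kind <- match.arg(kind)
  frame_ms <- 1000 / const$frame_hz
  n <- round(const$action_ms / frame_ms)
  target <- c(const$eccentricity, 0)
  onset_ms <- switch(kind, correct = 400, too_fast = 100, too_slow = 900,
                     missed = 400)
  pos <- matrix(0, n + 1L, 2)
  speed <- const$px_per_frame / const$px_per_deg
  for (f in seq_len(n)) {
    t_ms <- (f - 1L) * frame_ms
    if (t_ms < onset_ms) { pos[f + 1L, ] <- pos[f, ]; next }
    if (kind == "missed") {
      ang <- 2 * pi * (t_ms - onset_ms) / 2000
      pos[f + 1L, ] <- c(4 - 4 * cos(ang), 4 * sin(ang))
    } else {
      d <- target - pos[f, ]
      dist <- sqrt(sum(d^2))
      pos[f + 1L, ] <- if (dist <= speed) target else pos[f, ] + d / dist * speed
    }
  }
  pos
}

#' Deterministic fixtures for the test suite
#'
#' A small canned pair session (1 block of 16 trials, EEG at a light rate)
#' plus four constructed trajectories, one per outcome class, scored with
#' the game logic.
#'
#' @param seed integer seed.
#' @param eeg include EEG synthesis (default TRUE).
#' @return List `session` (a `pair_session`), `trajectories` (named list of
#'   canned trajectories), `outcomes` (their scores), `target` (the canned
#'   target centre).
#' @export
make_fixtures <- function(seed = 42, eeg = TRUE) {
  const <- task_constants()
  design <- generate_design(1, 16, seed = seed)
  fw <- if (eeg) eeg_forward_model(rate_hz = 128) else NULL
  session <- simulate_pair_session(design, forward = fw, seed = seed,
                                   const = const)
  kinds <- c("correct", "too_fast", "too_slow", "missed")
  trajs <- lapply(stats::setNames(kinds, kinds), canned_trajectory,
                  const = const)
  target <- c(const$eccentricity, 0)
  outcomes <- do.call(rbind, lapply(kinds, function(k)
    cbind(kind = k, score_trial(trajs[[k]], target, const))))
  list(session = session, trajectories = trajs, outcomes = outcomes,
       target = target)
}
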