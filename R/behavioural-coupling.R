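# Interpersonal behavioural coupling: within-trial controller displacement
# correlation, across-trial onset/offset correlation, inter-cursor distance,
# inter-gaze distance, and gaze-versus-cursor relative timing.

# zero-lag Pearson r with the package's missing-value convention
coupling_value <- function(a, b, min_n = 2L) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min_n)
    return(list(r = NA_real_, n = sum(ok), reason = "insufficient pairs"))
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, n = length(a), reason = "zero variance"))
  list(r = stats::cor(a, b), n = length(a), reason = NA_character_)
}

#' Within-trial controller displacement correlation
#'
#' Zero-lag Pearson correlation between the two co-actors' controller
#' displacement time series over one trial's frames. A zero-variance series
#' yields a missing value with a reason, never 0. By default the full action
#' window (including pre-onset zeros) enters the correlation;
#' `movement_only = TRUE` restricts to the union of the two actors'
#' supra-threshold movement intervals.
#'
#' @param a,b displacement series ([displacement_series()]) on the same
#'   frame base.
#' @param movement_only restrict to the union of movement intervals.
#' @param threshold_pct movement threshold used when `movement_only`.
#' @return List `r`, `n`, `reason`.
#' @export
#' @examples
#' trial_displacement_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))$r   # 0.6
trial_displacement_correlation <- function(a, b, movement_only = FALSE,
                                           threshold_pct = 10) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (movement_only) {
    keep <- a > threshold_pct | b > threshold_pct
    a <- a[keep]; b <- b[keep]
  }
  coupling_value(a, b)
}

#' Across-trial onset/offset correlation
#'
#' Pearson correlation across trials between the two co-actors' per-trial
#' event times (action onsets or offsets). Trials with a missing event for
#' either actor are excluded pairwise; fewer than 3 complete pairs yields a
#' missing value.
#'
#' @param events_a,events_b per-trial event times, ms.
#' @return List `r`, `n`, `reason`.
#' @export
across_trial_event_correlation <- function(events_a, events_b) {
  if (length(events_a) != length(events_b))
    stop("event vectors must have equal length")
  coupling_value(events_a, events_b, min_n = 3L)
}

#' Maximum inter-cursor distance
#'
#' Maximum over frames of the Euclidean distance between two cursor
#' trajectories -- an index of visual similarity (visible solo cursors on
#' solo trials) or motoric similarity (invisible solo cursors on joint
#' trials). Symmetric in actor order and non-negative.
#'
#' @param traj_a,traj_b n x 2 position matrices on the same frame base.
#' @return Maximum distance, degrees.
#' @export
max_inter_cursor_distance <- function(traj_a, traj_b) {
  traj_a <- as.matrix(traj_a); traj_b <- as.matrix(traj_b)
  if (nrow(traj_a) != nrow(traj_b)) stop("trajectories must have equal length")
  max(sqrt(rowSums((traj_a - traj_b)^2)))
}

#' Inter-gaze distance within an epoch
#'
#' Mean Euclidean distance between the co-actors' gaze positions over the
#' jointly valid samples of an epoch around the spatial cue (pre-action
#' -2.5-0.0 s, action 0.0-2.5 s). Fewer than 10% jointly valid samples in
#' the epoch gives a missing value; masked samples are never interpolated.
#'
#' @param g1,g2 cleaned gaze traces (data.frames with `t_ms`, `x`, `y`,
#'   `valid`) on a common time base.
#' @param epoch `"pre_action"` or `"action"`.
#' @param spatial_cue_ms time of the spatial cue on the traces' time base.
#' @return List `distance_deg`, `n`, `reason`.
#' @export
inter_gaze_distance <- function(g1, g2, epoch = c("pre_action", "action"),
                                spatial_cue_ms) {
  epoch <- match.arg(epoch)
  win <- if (epoch == "pre_action") c(-2500, 0) else c(0, 2500)
  sel <- g1$t_ms - spatial_cue_ms >= win[1] & g1$t_ms - spatial_cue_ms < win[2]
  ok <- sel & g1$valid & g2$valid
  if (sum(ok) < 0.10 * sum(sel))
    return(list(distance_deg = NA_real_, n = sum(ok),
                reason = "insufficient valid samples"))
  d <- sqrt((g1$x[ok] - g2$x[ok])^2 + (g1$y[ok] - g2$y[ok])^2)
  list(distance_deg = mean(d), n = sum(ok), reason = NA_character_)
}

#' Gaze and cursor distance-to-target on normalised action time
#'
#' For a correct trial, the distance of gaze and cursor from the target
#' centre, resampled onto 0-100% of the trial's movement time (action onset
#' to completion). Interpolation is linear onto a common percentage grid so
#' profiles can be averaged across trials of different MT.
#'
#' @param g cleaned gaze trace (`t_ms` relative to trial start).
#' @param traj cursor position matrix over the action window (row 1 at the
#'   spatial cue).
#' @param target_centre (x, y), degrees.
#' @param onset_ms,completion_ms action onset and completion, ms after the
#'   spatial cue.
#' @param spatial_cue_ms spatial-cue time on the gaze trace's time base.
#' @param grid percentage grid (default 0-100 in steps of 2).
#' @param frame_hz cursor frame rate.
#' @return data.frame `pct`, `gaze_deg`, `cursor_deg`.
#' @export
gaze_cursor_timing <- function(g, traj, target_centre, onset_ms,
                               completion_ms, spatial_cue_ms,
                               grid = seq(0, 100, by = 2), frame_hz = 144) {
  stopifnot(completion_ms > onset_ms)
  mt_t <- onset_ms + (completion_ms - onset_ms) * grid / 100
  traj <- as.matrix(traj)
  t_traj <- (seq_len(nrow(traj)) - 1L) * 1000 / frame_hz
  cd <- sqrt((traj[, 1] - target_centre[1])^2 +
             (traj[, 2] - target_centre[2])^2)
  cursor_deg <- stats::approx(t_traj, cd, xout = mt_t, rule = 2)$y
  gt <- g$t_ms - spatial_cue_ms
  gd <- sqrt((g$x - target_centre[1])^2 + (g$y - target_centre[2])^2)
  okg <- g$valid
  gaze_deg <- stats::approx(gt[okg], gd[okg], xout = mt_t, rule = 2)$y
  data.frame(pct = grid, gaze_deg = gaze_deg, cursor_deg = cursor_deg)
}
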