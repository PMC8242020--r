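# Task engine: session design, trial timeline, cursor control law, scoring.
#
# Geometry convention: origin at display centre, x rightward, y upward,
# units degrees of visual angle unless a name says px. The pixel/degree
# conversion is a single constant chosen so that full thumb-stick deflection
# (7.5 px per frame at 144 frames/s = 1080 px/s) equals the stated maximum
# cursor speed of 29.9 deg/s: 1080 / 29.9 = 36.12 px/deg.

#' Task constants
#'
#' The fixed task parameters: display frame rate, cursor speed constant,
#' controller gate, target geometry, and response windows. Returned as a list
#' so analysis code can override individual values (e.g. a different
#' pixel-per-degree calibration) without touching the engine.
#'
#' @param ... name-value overrides of the defaults.
#' @return Named list of task constants.
#' @export
#' @examples
#' task_constants()$px_per_deg     # 36.12
#' task_constants(dwell_ms = 300)$dwell_ms
task_constants <- function(...) {
  const <- list(
    frame_hz       = 144,      # display / controller sampling rate
    px_per_frame   = 7.5,      # cursor px per frame at full deflection
    px_per_deg     = 36.12,    # so 7.5 * 144 / 36.12 = 29.9 deg/s at max
    gate_frac      = 0.10,     # controller action threshold (10% of max)
    eccentricity   = 8.0,      # target centre eccentricity, deg
    target_radius  = 1.0,      # target annulus half-extent (2.0 x 2.0 deg)
    rt_min_ms      = 200,      # action initiation window
    rt_max_ms      = 800,
    mt_max_ms      = 1500,     # time allowed to complete after onset
    dwell_ms       = 200,      # required hold inside the target
    action_ms      = 2500,     # full action window after the spatial cue
    display_half_deg = 14.0    # clamp bound for cursor positions
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(const))
    if (length(bad)) stop("unknown task constant(s): ", paste(bad, collapse = ", "))
    const[names(ov)] <- ov
  }
  const
}

#' Peripheral target positions
#'
#' The eight peripheral placeholder locations at 8 deg eccentricity, indexed
#' 1-8 anticlockwise from the rightward horizontal. Opposite indices
#' (i, i + 4) form the four target/distractor pairs, 180 degrees apart.
#'
#' @param const task constants, see [task_constants()].
#' @return 8 x 2 matrix of (x, y) positions in degrees.
#' @export
target_positions <- function(const = task_constants()) {
  ang <- (0:7) * pi / 4
  cbind(x = const$eccentricity * cos(ang),
        y = const$eccentricity * sin(ang))
}

#' Generate a counterbalanced session design
#'
#' Builds the ordered trial table for one dyad session. Within every block the
#' design fully crosses control (solo, joint) x target-position pair (4) x
#' tag-frequency assignment (17 or 19 Hz on the target), i.e. 16 cells; the
#' block size must be a multiple of 16. Across the repetitions of a cell
#' within a block, which end of the position pair carries the target
#' alternates, so targets visit all eight locations. Presentation order
#' within each block is a seeded random permutation (one master seed,
#' per-block derived streams), and the pre-action variable delay is drawn
#' uniformly from 500-1000 ms per trial.
#'
#' @param blocks number of blocks (default 15).
#' @param block_size trials per block (default 64; must be divisible by 16).
#' @param seed integer master seed; identical seeds give identical designs.
#' @return A `session_design`: data.frame with one row per trial and columns
#'   `block`, `trial`, `control`, `target_index`, `distractor_index`,
#'   `target_freq_hz`, `distractor_freq_hz`, `cue_colour`, `delay_ms`.
#' @export
#' @examples
#' d <- generate_design(15, 64, seed = 1)
#' nrow(d)                          # 960
#' sum(d$control == "joint")        # 480
generate_design <- function(blocks = 15, block_size = 64, seed = 1) {
  if (block_size %% 16L != 0L)
    stop("block_size must be divisible by 16 (the full factorial cell count)")
  stopifnot(blocks >= 1)
  cells <- expand.grid(control = c("solo", "joint"),
                       pair_index = 1:4,
                       target_freq_hz = c(17, 19),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  reps <- block_size %/% 16L
  set.seed(as.integer(seed))
  block_seeds <- sample.int(.Machine$integer.max - 1L, blocks)
  res <- vector("list", blocks)
  for (b in seq_len(blocks)) {
    set.seed(block_seeds[b])
    tab <- cells[rep(seq_len(16L), times = reps), , drop = FALSE]
    # alternate which end of the position pair is the target across reps
    tab$rep <- rep(seq_len(reps), each = 16L)
    tab$target_index <- tab$pair_index + ifelse(tab$rep %% 2L == 0L, 4L, 0L)
    ord <- sample.int(nrow(tab))
    tab <- tab[ord, , drop = FALSE]
    tab$block <- b
    tab$delay_ms <- stats::runif(nrow(tab), 500, 1000)
    res[[b]] <- tab
  }
  d <- do.call(rbind, res)
  d$distractor_index <- ((d$target_index + 3L) %% 8L) + 1L  # 180 deg opposite
  d$distractor_freq_hz <- ifelse(d$target_freq_hz == 17, 19, 17)
  d$cue_colour <- ifelse(d$control == "joint", "green", "red")
  d$trial <- seq_len(nrow(d))
  d <- d[, c("block", "trial", "control", "target_index", "distractor_index",
             "target_freq_hz", "distractor_freq_hz", "cue_colour", "delay_ms")]
  rownames(d) <- NULL
  structure(d, class = c("session_design", "data.frame"),
            blocks = blocks, block_size = block_size, seed = seed)
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("Session design: %d blocks x %d trials = %d trials (%d solo, %d joint)\n",
              attr(x, "blocks"), attr(x, "block_size"), nrow(x),
              sum(x$control == "solo"), sum(x$control == "joint")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Trial timeline
#'
#' Epoch boundaries of one trial, in ms from trial start: rest (1000),
#' pre-cue placeholder (576), control cue (1424), variable delay (500-1000),
#' action window (2500), feedback (500). Total duration is 6500-7000 ms
#' depending on the delay.
#'
#' @param delay_ms variable delay between control cue offset and the spatial
#'   cue, in `[500, 1000]` ms.
#' @return A `trial_timeline` list with `durations` (named vector), `onset`
#'   (named vector of epoch onsets, ms from trial start) and `total_ms`.
#' @export
#' @examples
#' generate_timeline(500)$total_ms    # 6500
#' generate_timeline(1000)$total_ms   # 7000
generate_timeline <- function(delay_ms) {
  if (!is.numeric(delay_ms) || length(delay_ms) != 1L ||
      delay_ms < 500 || delay_ms > 1000)
    stop("delay_ms must be a single value in [500, 1000]")
  durations <- c(rest = 1000, precue = 576, control_cue = 1424,
                 delay = delay_ms, action = 2500, feedback = 500)
  onset <- cumsum(c(0, durations[-length(durations)]))
  names(onset) <- names(durations)
  structure(list(durations = durations, onset = onset,
                 spatial_cue_ms = unname(onset["action"]),
                 total_ms = sum(durations)),
            class = "trial_timeline")
}

#' @export
print.trial_timeline <- function(x, ...) {
  cat(sprintf("Trial timeline, total %.0f ms (spatial cue at %.0f ms)\n",
              x$total_ms, x$spatial_cue_ms))
  print(x$durations)
  invisible(x)
}

#' Cursor control law
#'
#' Converts per-frame controller axis displacements into cursor velocity.
#' Solo control: velocity is the input scaled by 7.5 px/frame provided the
#' displacement magnitude sqrt(x^2 + y^2) exceeds the 10% gate; smaller
#' displacements give exactly zero velocity. Joint control: if *both*
#' co-actors exceed the gate, velocity is the per-axis mean of the two raw
#' inputs scaled by 7.5; if either is below the gate, velocity is zero
#' (both co-actors must exert force concurrently).
#'
#' @param inputs for `mode = "solo"`, an n x 2 matrix of (x, y) displacements
#'   in `[-1, 1]`; for `mode = "joint"`, a list of two such matrices.
#' @param mode `"solo"` or `"joint"`.
#' @param const task constants.
#' @return n x 2 matrix of per-frame cursor velocities in px/frame.
#' @export
#' @examples
#' step_cursor(cbind(1, 0), "solo")                          # (7.5, 0)
#' step_cursor(list(cbind(0.5, 0), cbind(0.3, 0)), "joint")  # (3.0, 0)
step_cursor <- function(inputs, mode = c("solo", "joint"),
                        const = task_constants()) {
  mode <- match.arg(mode)
  as_mat <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop("controller input must have two columns (x, y)")
    if (any(abs(m) > 1 + 1e-12)) stop("axis displacements must lie in [-1, 1]")
    m
  }
  if (mode == "solo") {
    if (is.list(inputs) && !is.data.frame(inputs)) {
      if (length(inputs) != 1L) stop("solo mode takes exactly one input trace")
      inputs <- inputs[[1L]]
    }
    m <- as_mat(inputs)
    mag <- sqrt(rowSums(m^2))
    v <- m * const$px_per_frame
    v[mag <= const$gate_frac, ] <- 0
    return(v)
  }
  if (!is.list(inputs) || length(inputs) != 2L)
    stop("joint mode requires a list of two input traces")
  a <- as_mat(inputs[[1L]]); b <- as_mat(inputs[[2L]])
  if (nrow(a) != nrow(b)) stop("joint input traces must have equal length")
  both <- sqrt(rowSums(a^2)) > const$gate_frac &
          sqrt(rowSums(b^2)) > const$gate_frac
  v <- (a + b) / 2 * const$px_per_frame
  v[!both, ] <- 0
  v
}

#' Integrate a velocity series into a cursor trajectory
#'
#' Cumulative sum of per-frame velocities from a start position, converted to
#' degrees and clamped to the display bounds. Per-frame step magnitude is
#' bounded by 7.5 px by the control law.
#'
#' @param vel_px n x 2 velocity matrix in px/frame ([step_cursor()] output).
#' @param start (x, y) start position in degrees (default fixation, 0, 0).
#' @param const task constants.
#' @return (n + 1) x 2 matrix of positions in degrees, first row = start.
#' @export
integrate_trajectory <- function(vel_px, start = c(0, 0),
                                 const = task_constants()) {
  step_deg <- vel_px / const$px_per_deg
  pos <- rbind(start, sweep(apply(step_deg, 2L, cumsum), 2L, start, `+`))
  pos <- pmin(pmax(pos, -const$display_half_deg), const$display_half_deg)
  dimnames(pos) <- list(NULL, c("x", "y"))
  pos
}

#' Score one trial with the game logic
#'
#' Applies the experiment's scoring rules to a cursor trajectory over the
#' action window. Action onset (RT) is the first frame with non-zero cursor
#' velocity (the controller 10% gate is what zeroes velocity, so this is the
#' controller-onset frame seen through the cursor). The action is complete at
#' the onset of the first target-entry interval whose dwell reaches 200 ms
#' (first-entered-and-remained convention); MT runs from action onset to that
#' entry frame. Outcomes: `too_fast` (RT < 200 ms), `too_slow` (RT > 800 ms),
#' `missed` (no qualifying dwell within the allowed 1500 ms), else `correct`.
#' Identical logic applies to visible and invisible cursors.
#'
#' @param traj (n + 1) x 2 position matrix in degrees over the action window
#'   (first row at spatial-cue onset).
#' @param target_centre (x, y) target centre in degrees.
#' @param const task constants.
#' @return A one-row data.frame: `outcome`, `rt_ms`, `mt_ms`,
#'   `completion_ms` (RT + MT, correct trials only), `offset locked` fields
#'   are left to the behavioural-metrics layer.
#' @export
score_trial <- function(traj, target_centre, const = task_constants()) {
  traj <- as.matrix(traj)
  n_frames <- nrow(traj) - 1L
  frame_ms <- 1000 / const$frame_hz
  step <- diff(traj)
  moving <- rowSums(abs(step)) > 0
  onset_frame <- if (any(moving)) which(moving)[1L] else NA_integer_
  rt_ms <- if (is.na(onset_frame)) NA_real_ else (onset_frame - 1L) * frame_ms

  res <- function(outcome, rt = rt_ms, mt = NA_real_)
    data.frame(outcome = outcome, rt_ms = rt, mt_ms = mt,
               completion_ms = if (outcome == "correct") rt + mt else NA_real_,
               stringsAsFactors = FALSE)

  if (is.na(onset_frame)) return(res("missed", rt = NA_real_))
  if (rt_ms < const$rt_min_ms) return(res("too_fast"))
  if (rt_ms > const$rt_max_ms) return(res("too_slow"))

  d <- sqrt((traj[, 1] - target_centre[1])^2 + (traj[, 2] - target_centre[2])^2)
  inside <- d <= const$target_radius
  # a run of k sample rows spans (k - 1) frame intervals
  dwell_rows <- ceiling(const$dwell_ms / frame_ms) + 1L
  r <- rle(inside)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  cand <- which(r$values & r$lengths >= dwell_rows)
  for (k in cand) {
    entry_ms <- (starts[k] - 1L) * frame_ms     # row i is at (i - 1) * frame_ms
    mt_ms <- entry_ms - rt_ms
    if (mt_ms >= 0 && mt_ms <= const$mt_max_ms)
      return(res("correct", mt = mt_ms))
  }
  res("missed")
}
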