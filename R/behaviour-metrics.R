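# Per-trial behavioural measures: controller displacement, action onset and
# offset, trajectory curvature, endpoint displacement, performance summaries
# and HP/LP (higher-/lower-performing) co-actor sorting.

#' Controller displacement series
#'
#' Euclidean displacement of the thumb stick from its home position,
#' expressed in percent of maximum: 100 * sqrt(x^2 + y^2), clipped at 100.
#'
#' @param trace n x 2 matrix of per-frame axis displacements in `[-1, 1]`.
#' @return Numeric vector of per-frame displacement magnitudes in `[0, 100]`.
#' @export
#' @examples
#' displacement_series(cbind(0.3, 0.4))   # 50
displacement_series <- function(trace) {
  trace <- as.matrix(trace)
  pmin(100, 100 * sqrt(rowSums(trace^2)))
}

#' Detect action onset and offset
#'
#' Onset is the first frame whose displacement exceeds the threshold
#' (default 10% of maximum, the action gate); offset is the last such frame.
#' Returns `NA` for both when no frame exceeds the threshold.
#'
#' @param series displacement series in percent ([displacement_series()]).
#' @param threshold_pct gate threshold, percent (default 10).
#' @param frame_hz frame rate used to convert frames to ms.
#' @return List with `onset_frame`, `offset_frame` (1-based frame indices)
#'   and `onset_ms`, `offset_ms` (times of those frames, 0 ms = first frame).
#' @export
#' @examples
#' detect_onset_offset(c(0, 5, 12, 40, 12, 5, 0))  # onset frame 3, offset 4
detect_onset_offset <- function(series, threshold_pct = 10, frame_hz = 144) {
  supra <- which(series > threshold_pct)
  if (!length(supra))
    return(list(onset_frame = NA_integer_, offset_frame = NA_integer_,
                onset_ms = NA_real_, offset_ms = NA_real_))
  frame_ms <- 1000 / frame_hz
  list(onset_frame = supra[1L], offset_frame = supra[length(supra)],
       onset_ms = (supra[1L] - 1L) * frame_ms,
       offset_ms = (supra[length(supra)] - 1L) * frame_ms)
}

#' Menger (circle-fit) trajectory curvature
#'
#' Per-frame curvature of a 2-D trajectory, computed at each interior frame
#' as the inverse radius of the circle through the frame and its two
#' neighbours (Menger curvature, k = 4 * Area / (|ab| |bc| |ac|)). The
#' curvature vector points from the middle point toward the circumcentre;
#' its signed x/y projections are returned as components, with magnitude
#' k = sqrt(kx^2 + ky^2). Units are 1/deg when positions are in degrees.
#' Degenerate triples (repeated points, i.e. a stationary cursor) get `NA`
#' and are excluded from the trial mean; collinear triples have k = 0.
#'
#' @param traj n x 2 position matrix (n >= 3).
#' @return List with `kx`, `ky`, `k` (length n vectors, `NA` at endpoints and
#'   degenerate frames) and `mean_k`, the trial-mean curvature across valid
#'   interior frames (`NA` if fewer than one valid frame).
#' @export
#' @examples
#' th <- seq(0, pi, length.out = 20)
#' curvature(cbind(2 * cos(th), 2 * sin(th)))$mean_k   # 0.5 (radius 2)
curvature <- function(traj) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  if (n < 3L) stop("curvature needs at least 3 frames")
  a <- traj[1:(n - 2L), , drop = FALSE]
  b <- traj[2:(n - 1L), , drop = FALSE]
  cc <- traj[3:n, , drop = FALSE]
  ab <- sqrt(rowSums((b - a)^2))
  bc <- sqrt(rowSums((cc - b)^2))
  ac <- sqrt(rowSums((cc - a)^2))
  cross <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  area2 <- abs(cross)                      # 2 * triangle area
  degen <- ab == 0 | bc == 0 | ac == 0
  k <- ifelse(degen, NA_real_, 2 * area2 / (ab * bc * ac))
  # circumcentre direction from the middle point (normal direction)
  ux <- cc[, 1] - a[, 1]; uy <- cc[, 2] - a[, 2]
  un <- sqrt(ux^2 + uy^2)
  # normal to the chord a-c, oriented toward the arc's concave side
  nx <- -uy / un * sign(cross); ny <- ux / un * sign(cross)
  kx <- k * nx; ky <- k * ny
  pad <- function(v) c(NA_real_, v, NA_real_)
  k <- pad(k); kx <- pad(kx); ky <- pad(ky)
  valid <- !is.na(k)
  list(kx = kx, ky = ky, k = k,
       mean_k = if (any(valid)) mean(k[valid]) else NA_real_)
}

#' Endpoint displacement
#'
#' Euclidean distance between the cursor position on the final trial frame
#' and the target centre, in degrees. Path-independent by construction.
#'
#' @param traj n x 2 position matrix in degrees.
#' @param target_centre (x, y) target centre in degrees.
#' @return Distance in degrees.
#' @export
endpoint_displacement <- function(traj, target_centre) {
  traj <- as.matrix(traj)
  p <- traj[nrow(traj), ]
  sqrt(sum((p - target_centre)^2))
}

#' Summarise performance and assign HP/LP co-actors
#'
#' Aggregates trial outcomes into per-participant (cursor owner) summaries --
#' accuracy (% correct of scorable trials), mean RT and MT over correct
#' trials, anticipation rate (% trials with RT < 200 ms) -- and sorts the two
#' solo actors into higher- (HP) and lower-performing (LP) per metric.
#' `level = "experiment"` assigns HP/LP once per metric from the solo-trial
#' aggregate (higher accuracy is better; lower RT, MT and anticipation are
#' better), with ties broken toward the lower participant index.
#' `level = "trial"` sorts the two solo values within every trial (used for
#' continuous metrics such as curvature and endpoint displacement, where the
#' experiment-level split is not meaningful trial by trial).
#'
#' @param outcomes data.frame with columns `trial`, `owner` (`"solo1"`,
#'   `"solo2"`, `"joint"`), `visible` (logical), `control`, `outcome`,
#'   `rt_ms`, `mt_ms`; extra metric columns are carried along for
#'   trial-level sorting.
#' @param level `"experiment"` or `"trial"`.
#' @param metric for `level = "trial"`: name of the numeric column to sort.
#' @return For `"experiment"`: list with `summary` (per owner x visibility)
#'   and `hp_lp`, a data.frame mapping each metric to the HP and LP solo
#'   owner. For `"trial"`: data.frame with per-trial `hp_value`, `lp_value`.
#' @export
summarize_performance <- function(outcomes, level = c("experiment", "trial"),
                                  metric = NULL) {
  level <- match.arg(level)
  need <- c("trial", "owner", "visible", "outcome")
  if (!all(need %in% names(outcomes)))
    stop("outcomes must have columns: ", paste(need, collapse = ", "))
  if (level == "trial") {
    if (is.null(metric) || !metric %in% names(outcomes))
      stop("trial-level sorting needs an existing metric column")
    solo <- outcomes[outcomes$owner %in% c("solo1", "solo2"), ]
    sp <- split(solo[[metric]], solo$trial)
    keep <- vapply(sp, function(v) sum(!is.na(v)) == 2L, logical(1))
    sp <- sp[keep]
    out <- data.frame(trial = as.integer(names(sp)),
                      hp_value = vapply(sp, min, numeric(1)),
                      lp_value = vapply(sp, max, numeric(1)))
    rownames(out) <- NULL
    return(out[order(out$trial), ])
  }
  agg <- function(df) {
    correct <- df$outcome == "correct"
    data.frame(
      n = nrow(df),
      accuracy_pct = 100 * mean(correct),
      rt_ms = mean(df$rt_ms[correct]),
      mt_ms = mean(df$mt_ms[correct]),
      anticipation_pct = 100 * mean(!is.na(df$rt_ms) & df$rt_ms < 200)
    )
  }
  key <- interaction(outcomes$owner, outcomes$visible, drop = TRUE)
  summ <- do.call(rbind, lapply(split(outcomes, key), agg))
  summ <- cbind(do.call(rbind, strsplit(rownames(summ), ".", fixed = TRUE)), summ)
  names(summ)[1:2] <- c("owner", "visible")
  summ$visible <- as.logical(summ$visible)
  rownames(summ) <- NULL
  # HP/LP from visible solo trials
  solo <- summ[summ$owner %in% c("solo1", "solo2") & summ$visible, ]
  metrics <- c(accuracy_pct = +1, rt_ms = -1, mt_ms = -1, anticipation_pct = -1)
  hp_lp <- do.call(rbind, lapply(names(metrics), function(m) {
    v <- metrics[[m]] * solo[[m]][match(c("solo1", "solo2"), solo$owner)]
    hp <- if (isTRUE(v[2] > v[1])) "solo2" else "solo1"  # tie -> lower index
    data.frame(metric = m, hp = hp, lp = setdiff(c("solo1", "solo2"), hp))
  }))
  list(summary = summ, hp_lp = hp_lp)
}
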