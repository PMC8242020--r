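# Sliding-window lag-zero inter-brain correlation: the pipeline's core
# statistic. For every trial, electrode and window position, the Pearson
# correlation between the two participants' same-electrode EEG segments is
# computed; the condition map is the mean over trials, and the per-trial
# values are retained for the single-trial statistics.

# rolling window sums via cumulative sums; bounds lo..hi inclusive (1-based)
.win_sum <- function(cs, lo, hi) cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]

#' Sliding-window inter-brain correlation
#'
#' Lag-zero Pearson correlation between the two participants' EEG in a
#' window slid along the trial (default 500 ms length, one-sample step at
#' the analysis rate, i.e. 15.6 ms at 64 Hz). Windows are centred on their
#' reported timepoint; edge windows are truncated down to no less than half
#' the window length and flagged. A trial invalid for either participant is
#' excluded for both. Zero-variance segments give missing cells, excluded
#' from the across-trial mean.
#'
#' @param e1,e2 `epoch_set`s for the two participants, trial-aligned, same
#'   rate and window.
#' @param window_ms window length, ms (default 500).
#' @param step_samples step between window centres, samples (default 1).
#' @return A `coupling_map`: list `map` (channels x centres, mean r over
#'   included trials), `per_trial` (trials x channels x centres), `times_s`
#'   (window-centre times on the epoch time base), `truncated` (logical per
#'   centre), `labels`, `included` (logical per trial), `window_ms`,
#'   `rate_hz`.
#' @export
sliding_interbrain_correlation <- function(e1, e2, window_ms = 500,
                                           step_samples = 1L) {
  stopifnot(inherits(e1, "epoch_set"), inherits(e2, "epoch_set"))
  if (e1$rate_hz != e2$rate_hz || !all(dim(e1$data) == dim(e2$data)))
    stop("epoch sets must be trial-aligned with equal rate and window")
  fs <- e1$rate_hz
  n_t <- dim(e1$data)[1]; n_ch <- dim(e1$data)[2]; n_s <- dim(e1$data)[3]
  w <- round(window_ms / 1000 * fs)
  half_lo <- floor(w / 2); half_hi <- ceiling(w / 2) - 1L
  centres <- seq.int(1L, n_s, by = step_samples)
  lo <- pmax(1L, centres - half_lo)
  hi <- pmin(n_s, centres + half_hi)
  len <- hi - lo + 1L
  keep <- len >= ceiling(w / 2)
  centres <- centres[keep]; lo <- lo[keep]; hi <- hi[keep]; len <- len[keep]
  truncated <- len < w
  included <- e1$valid & e2$valid

  per_trial <- array(NA_real_, c(n_t, n_ch, length(centres)))
  for (t in which(included)) {
    x <- e1$data[t, , , drop = TRUE]; y <- e2$data[t, , , drop = TRUE]
    z <- cbind(0, t(apply(rbind(x, y, x * y, x^2, y^2), 1L, cumsum)))
    csx  <- z[seq_len(n_ch), , drop = FALSE]
    csy  <- z[n_ch + seq_len(n_ch), , drop = FALSE]
    csxy <- z[2L * n_ch + seq_len(n_ch), , drop = FALSE]
    csx2 <- z[3L * n_ch + seq_len(n_ch), , drop = FALSE]
    csy2 <- z[4L * n_ch + seq_len(n_ch), , drop = FALSE]
    nmat <- matrix(len, n_ch, length(centres), byrow = TRUE)
    sx <- .win_sum(csx, lo, hi);  sy <- .win_sum(csy, lo, hi)
    sxy <- .win_sum(csxy, lo, hi)
    vx <- nmat * .win_sum(csx2, lo, hi) - sx^2
    vy <- nmat * .win_sum(csy2, lo, hi) - sy^2
    num <- nmat * sxy - sx * sy
    den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
    r <- ifelse(vx <= 1e-12 | vy <= 1e-12, NA_real_, num / den)
    per_trial[t, , ] <- pmin(1, pmax(-1, r))
  }
  map <- apply(per_trial[included, , , drop = FALSE], c(2L, 3L), mean,
               na.rm = TRUE)
  map[is.nan(map)] <- NA_real_
  structure(list(map = map, per_trial = per_trial,
                 times_s = e1$times[centres], truncated = truncated,
                 labels = e1$labels, included = included,
                 window_ms = window_ms, rate_hz = fs,
                 reference = e1$reference),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  cat(sprintf(
    "Coupling map: %d channels x %d windows (%g ms window at %g Hz), %d trials, mean r %.3f\n",
    nrow(x$map), ncol(x$map), x$window_ms, x$rate_hz, sum(x$included),
    mean(x$map, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.coupling_map <- function(x, ...) {
  graphics::image(x$times_s, seq_len(nrow(x$map)), t(x$map),
                  xlab = "time (s)", ylab = "electrode",
                  main = "Inter-brain coupling (mean r)", ...)
  invisible(x)
}

#' Condition contrast of two coupling maps
#'
#' Cellwise difference `map_a - map_b` (e.g. joint minus solo) on identical
#' grids. Thresholding is done by the permutation engine
#' ([permutation_contrast()]); see [coupling_permutation_test()] for the
#' full pipeline across pairs.
#'
#' @param map_a,map_b `coupling_map`s on identical grids.
#' @return List `contrast` (channels x centres), `times_s`, `labels`.
#' @export
condition_contrast <- function(map_a, map_b) {
  if (!all(dim(map_a$map) == dim(map_b$map)) ||
      !isTRUE(all.equal(map_a$times_s, map_b$times_s)))
    stop("coupling maps are on different grids")
  list(contrast = map_a$map - map_b$map, times_s = map_a$times_s,
       labels = map_a$labels)
}

#' Joint-minus-solo permutation test on coupling maps across pairs
#'
#' For each pair, per-trial coupling maps are averaged within shuffled
#' condition labels (shuffling the trial labels within the pair keeps the
#' two participants' simultaneity but breaks the condition assignment), the
#' grand mean joint-minus-solo contrast is recomputed across pairs, and all
#' datapoints of all permutations are pooled into the null distribution.
#' Cells of the observed grand-mean contrast beyond the two-tailed alpha
#' quantiles are flagged significant.
#'
#' @param per_pair list over pairs; each element a list with `per_trial`
#'   (trials x channels x centres array from
#'   [sliding_interbrain_correlation()]) and `labels` (per-trial condition,
#'   `"solo"`/`"joint"`).
#' @param alpha two-tailed threshold (default 1e-4).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param times_s,labels grid annotation carried to the result.
#' @return A `permutation_result` (see [permutation_contrast()]) whose
#'   `observed` is the channels x centres grand-mean contrast, plus the grid
#'   annotation.
#' @export
coupling_permutation_test <- function(per_pair, alpha = 1e-4, n_perm = 1000,
                                      seed = 1, times_s = NULL,
                                      labels = NULL) {
  flat <- lapply(per_pair, function(p) {
    d <- dim(p$per_trial)
    m <- matrix(aperm(p$per_trial, c(2L, 3L, 1L)), d[2] * d[3], d[1])
    list(values = m, labels = p$labels, dim = d[2:3])
  })
  res <- permutation_contrast(lapply(flat, `[[`, "values"),
                              lapply(flat, `[[`, "labels"),
                              levels = c("solo", "joint"),
                              alpha = alpha, n_perm = n_perm, seed = seed)
  d <- flat[[1]]$dim
  res$observed <- matrix(res$observed, d[1], d[2])
  res$mask <- matrix(res$mask, d[1], d[2])
  res$times_s <- times_s
  res$labels <- labels
  res
}

#' Peak spatiotemporal slice of a contrast map
#'
#' The significant cell with the largest contrast; ties break first by
#' earlier time, then by montage order. With no significant cell the global
#' maximum is returned, flagged.
#'
#' @param contrast channels x centres contrast matrix.
#' @param mask logical significance matrix of the same shape (optional).
#' @param times_s window-centre times; @param labels electrode labels.
#' @return List `electrode`, `channel`, `latency_s`, `centre_index`,
#'   `value`, `significant`.
#' @export
find_peak_slice <- function(contrast, mask = NULL, times_s = NULL,
                            labels = NULL) {
  cand <- if (!is.null(mask) && any(mask, na.rm = TRUE)) mask else
    matrix(TRUE, nrow(contrast), ncol(contrast))
  significant <- !is.null(mask) && any(mask, na.rm = TRUE)
  v <- contrast
  v[!cand | is.na(cand)] <- -Inf
  best <- max(v)
  hits <- which(v == best, arr.ind = TRUE)
  # ties: earlier time first, then montage (row) order
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  ch <- hits[1, 1]; ti <- hits[1, 2]
  list(electrode = if (!is.null(labels)) labels[ch] else NA_character_,
       channel = unname(ch),
       latency_s = if (!is.null(times_s)) times_s[ti] else NA_real_,
       centre_index = unname(ti), value = contrast[ch, ti],
       significant = significant)
}

#' Per-trial coupling values at a slice
#'
#' Extracts each trial's coupling value at one (electrode, window) cell;
#' averaging these regenerates the map value at that cell.
#'
#' @param cmap a `coupling_map`; @param channel channel index or label;
#' @param centre_index window-centre index.
#' @return Numeric vector, one value per included trial (`NA` elsewhere).
#' @export
peak_slice_values <- function(cmap, channel, centre_index) {
  ch <- if (is.character(channel)) match(channel, cmap$labels) else channel
  v <- cmap$per_trial[, ch, centre_index]
  v[!cmap$included] <- NA_real_
  v
}
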