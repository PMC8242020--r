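# EEG conditioning: zero-phase band-limiting, epoching, artefact flagging,
# anti-aliased resampling; gaze cleaning (blink and pupil-transient masking).

#' Band-limit an EEG recording
#'
#' High-pass (0.5 Hz), low-pass (45 Hz) and notch (50 Hz, 2 Hz width,
#' implemented as a 49-51 Hz band-stop) filtering with 4th-order Butterworth
#' responses applied at zero phase, so event timing is preserved. The
#' default `"fft"` method multiplies the (reflection-padded) spectrum by the
#' squared Butterworth magnitude response -- the amplitude response of a
#' forward-backward pass, applied to all channels in one transform;
#' `"filtfilt"` runs the classic per-channel forward-backward recursion.
#' Markers are untouched.
#'
#' @param rec an `eeg_recording`.
#' @param hp_hz,lp_hz,notch_hz filter edges; set an element to `NULL` to
#'   skip that stage. `notch_hz` is a length-2 band.
#' @param method `"fft"` or `"filtfilt"`.
#' @return The filtered `eeg_recording`.
#' @export
filter_eeg <- function(rec, hp_hz = 0.5, lp_hz = 45, notch_hz = c(49, 51),
                       method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$rate_hz
  if (!is.null(lp_hz) && fs <= 2 * lp_hz)
    stop("sampling rate must exceed twice the low-pass edge")
  nyq <- fs / 2
  filts <- c(
    if (!is.null(hp_hz)) list(signal::butter(4, hp_hz / nyq, type = "high")),
    if (!is.null(lp_hz)) list(signal::butter(4, lp_hz / nyq, type = "low")),
    if (!is.null(notch_hz) && notch_hz[2] < nyq)
      list(signal::butter(4, notch_hz / nyq, type = "stop")))
  if (!length(filts)) return(rec)
  x <- rec$data
  if (method == "filtfilt") {
    for (f in filts)
      x <- apply(x, 2L, function(ch) signal::filtfilt(f, ch))
  } else {
    n <- nrow(x)
    pad <- min(n, round(3 * fs))               # reflection pad, 3 s
    xp <- rbind(x[pad:1, , drop = FALSE], x,
                x[n:(n - pad + 1L), , drop = FALSE])
    m <- stats::nextn(nrow(xp))
    xp <- rbind(xp, matrix(0, m - nrow(xp), ncol(x)))
    w <- 2 * pi * (seq_len(m) - 1L) / m        # digital frequency grid
    gain <- rep(1, m)
    for (f in filts) {
      z <- exp(-1i * outer(w, seq_along(f$b) - 1L))
      h <- (z %*% f$b) / (z %*% f$a)
      gain <- gain * Mod(drop(h))^2            # |H|^2 = forward-backward
    }
    xf <- Re(stats::mvfft(stats::mvfft(xp) * gain, inverse = TRUE)) / m
    x <- xf[pad + seq_len(n), , drop = FALSE]
  }
  rec$data <- x
  rec
}

#' Cut trial epochs from a recording
#'
#' Slices the recording around every marker with the given label into a
#' trials x channels x samples array. Epochs extending beyond the recording
#' are zero-padded and flagged invalid.
#'
#' @param rec an `eeg_recording`.
#' @param event marker label used as the time reference
#'   (default `"spatial_cue_onset"`).
#' @param window_s length-2 window around the event, seconds.
#' @param conditions optional data.frame keyed by `trial` with condition
#'   labels to attach.
#' @return An `epoch_set`: list with `data` (trials x channels x samples),
#'   `times` (s, relative to the event), `rate_hz`, `labels`, `valid`
#'   (logical per trial, never silently dropped), `conditions`, `reference`.
#' @export
epoch_eeg <- function(rec, event = "spatial_cue_onset",
                      window_s = c(-2.5, 3.0), conditions = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  mk <- rec$markers[rec$markers$label == event, ]
  if (!nrow(mk)) stop("no markers with label ", event)
  fs <- rec$rate_hz
  i0 <- round(window_s[1] * fs); i1 <- round(window_s[2] * fs)
  times <- (i0:i1) / fs
  n_s <- length(times)
  n_t <- nrow(mk)
  dat <- array(0, c(n_t, ncol(rec$data), n_s))
  valid <- rep(TRUE, n_t)
  for (t in seq_len(n_t)) {
    idx <- mk$sample[t] + (i0:i1)
    ok <- idx >= 1L & idx <= nrow(rec$data)
    if (!all(ok)) valid[t] <- FALSE
    dat[t, , which(ok)] <- t(rec$data[idx[ok], , drop = FALSE])
  }
  if (!is.null(conditions))
    conditions <- conditions[match(mk$trial, conditions$trial), , drop = FALSE]
  structure(list(data = dat, times = times, rate_hz = fs,
                 labels = rec$labels, valid = valid, trial = mk$trial,
                 conditions = conditions, reference = event),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "Epoch set: %d trials x %d channels x %d samples at %g Hz (%.2f to %.2f s re %s), %d valid\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate_hz,
    min(x$times), max(x$times), x$reference, sum(x$valid)))
  invisible(x)
}

#' Flag artefact trials
#'
#' Flags any trial whose within-epoch voltage fluctuation exceeds the
#' threshold on any channel. "Fluctuation" defaults to the within-epoch
#' peak-to-peak range per channel; `mode = "absolute"` uses the maximum
#' absolute value instead. Flagged trials keep their data (`valid = FALSE`),
#' they are never dropped.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold, uV (default 100).
#' @param mode `"peak_to_peak"` or `"absolute"`.
#' @return The `epoch_set` with its `valid` flags updated (a trial already
#'   invalid stays invalid).
#' @export
reject_artefact_trials <- function(epochs, threshold_uv = 100,
                                   mode = c("peak_to_peak", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "epoch_set"), all(is.finite(epochs$data)))
  stat <- apply(epochs$data, c(1L, 2L), function(v)
    if (mode == "peak_to_peak") diff(range(v)) else max(abs(v)))
  bad <- apply(stat > threshold_uv, 1L, any)
  epochs$valid <- epochs$valid & !bad
  epochs
}

# sinc (brick-wall FFT) anti-alias filter followed by spline interpolation
# onto the new sample grid; exact in amplitude for content below the target
# Nyquist, which a short polyphase filter is not
.resample_channels <- function(x, native, target) {
  n <- nrow(x)
  pad <- min(n - 1L, round(native))               # ~1 s reflection pad
  xp <- rbind(x[pad:1, , drop = FALSE], x,
              x[n:(n - pad + 1L), , drop = FALSE])
  m <- stats::nextn(nrow(xp))
  xp <- rbind(xp, matrix(0, m - nrow(xp), ncol(x)))
  X <- stats::mvfft(xp)
  k <- seq_len(m) - 1L
  f <- ifelse(k <= m / 2, k, k - m) * native / m
  X[abs(f) >= target / 2, ] <- 0
  xf <- Re(stats::mvfft(X, inverse = TRUE))[pad + seq_len(n), ,
                                            drop = FALSE] / m
  t_old <- (seq_len(n) - 1L) / native
  n_new <- floor((n - 1L) * target / native) + 1L
  t_new <- (seq_len(n_new) - 1L) / target
  vapply(seq_len(ncol(x)), function(ch)
    stats::spline(t_old, xf[, ch], xout = t_new)$y, numeric(n_new))
}

#' Downsample EEG
#'
#' Anti-aliased resampling to a lower analysis rate -- 256 Hz for SSVEP
#' analyses, 64 Hz for correlational analyses. The anti-alias stage is an
#' exact (brick-wall) spectral filter at the target Nyquist frequency, after
#' which the band-limited series is interpolated onto the new sample grid;
#' in-band amplitudes are preserved essentially exactly. Marker sample
#' indices are remapped proportionally. Upsampling is refused.
#'
#' @param x an `eeg_recording` or `epoch_set`.
#' @param target_hz target rate, must be below the native rate.
#' @return Same class as `x`, at `target_hz`.
#' @export
resample_eeg <- function(x, target_hz) {
  UseMethod("resample_eeg")
}

#' @export
resample_eeg.eeg_recording <- function(x, target_hz) {
  if (target_hz >= x$rate_hz) stop("upsampling is out of scope")
  x$data <- .resample_channels(x$data, x$rate_hz, target_hz)
  x$markers$sample <- pmax(1L, pmin(nrow(x$data),
    round((x$markers$sample - 1L) * target_hz / x$rate_hz) + 1L))
  x$rate_hz <- target_hz
  x
}

#' @export
resample_eeg.epoch_set <- function(x, target_hz) {
  if (target_hz >= x$rate_hz) stop("upsampling is out of scope")
  n_new <- floor((dim(x$data)[3] - 1L) * target_hz / x$rate_hz) + 1L
  out <- array(0, c(dim(x$data)[1], dim(x$data)[2], n_new))
  for (t in seq_len(dim(x$data)[1]))
    out[t, , ] <- t(.resample_channels(t(x$data[t, , , drop = TRUE]),
                                       x$rate_hz, target_hz))
  x$data <- out
  x$times <- x$times[1] + (seq_len(n_new) - 1L) / target_hz
  x$rate_hz <- target_hz
  x
}

#' Clean a gaze trace
#'
#' Masks samples within +/-200 ms of detected blinks (runs of at least 3
#' invalid or zero-pupil samples) and samples whose pupil-area first
#' difference exceeds the recording's 99.99th percentile (a rapid-increase
#' criterion). Masked samples are flagged, never interpolated. With a
#' constant pupil all first differences tie at zero and the quantile rule
#' masks nothing (strict exceedance).
#'
#' @param trace data.frame with `t_ms`, `x`, `y`, `pupil`, `valid`.
#' @param blink_pad_ms half-width of the blink exclusion window (default 200).
#' @param pupil_q pupil-difference percentile (default 0.9999).
#' @return The trace with its `valid` column updated.
#' @export
clean_gaze <- function(trace, blink_pad_ms = 200, pupil_q = 0.9999) {
  stopifnot(all(c("t_ms", "pupil", "valid") %in% names(trace)))
  bad <- !trace$valid | trace$pupil <= 0
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  mask <- rep(FALSE, nrow(trace))
  for (k in which(r$values & r$lengths >= 3L)) {
    t0 <- trace$t_ms[starts[k]] - blink_pad_ms
    t1 <- trace$t_ms[ends[k]] + blink_pad_ms
    mask <- mask | (trace$t_ms >= t0 & trace$t_ms <= t1)
  }
  dp <- c(0, diff(trace$pupil))
  thr <- stats::quantile(dp, pupil_q, names = FALSE)
  mask <- mask | dp > thr
  trace$valid <- trace$valid & !mask
  trace
}
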