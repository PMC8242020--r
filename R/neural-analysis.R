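# Stimulus-driven and event-locked neural measures: trial-averaged ERPs,
# single-sided FFT amplitude spectra (SSVEP read-out), complex Morlet
# time-frequency amplitude maps, and action-offset-locked ERPs.

#' Trial-averaged ERP
#'
#' Arithmetic mean over valid trials of an epoch set, optionally restricted
#' by a condition filter. Phase-locked activity survives averaging;
#' non-phase-locked activity cancels.
#'
#' @param epochs an `epoch_set`.
#' @param select optional logical vector over trials (combined with the
#'   validity flags).
#' @return An `erp`: list `data` (channels x samples), `times`, `rate_hz`,
#'   `labels`, `n_trials`.
#' @export
average_erp <- function(epochs, select = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- epochs$valid
  if (!is.null(select)) keep <- keep & select
  if (!any(keep)) stop("no valid trials to average")
  dat <- apply(epochs$data[keep, , , drop = FALSE], c(2L, 3L), mean)
  structure(list(data = dat, times = epochs$times, rate_hz = epochs$rate_hz,
                 labels = epochs$labels, n_trials = sum(keep)),
            class = "erp")
}

#' Single-sided FFT amplitude spectrum
#'
#' Amplitude spectrum with the 2/N single-sided convention: a noise-free
#' sinusoid of amplitude A occupying an integer number of cycles of the
#' window reads out as A at its frequency bin. Input is a channels x samples
#' matrix (e.g. an ERP, or one epoch window).
#'
#' @param x channels x samples numeric matrix, or a numeric vector (treated
#'   as one channel).
#' @param rate_hz sampling rate.
#' @return A `spectrum_result`: list `freq_hz` (resolution rate/N),
#'   `amplitude` (channels x frequencies, uV), `n`.
#' @export
#' @examples
#' fs <- 256; t <- (0:(fs - 1)) / fs
#' sp <- fft_amplitude(sin(2 * pi * 17 * t), fs)
#' sp$amplitude[1, sp$freq_hz == 17]    # 1
fft_amplitude <- function(x, rate_hz) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  nf <- floor(n / 2) + 1L
  amp <- t(apply(x, 1L, function(ch) {
    a <- Mod(stats::fft(ch))[seq_len(nf)] * 2 / n
    a[1] <- a[1] / 2                       # DC is not doubled
    if (n %% 2 == 0) a[nf] <- a[nf] / 2    # nor Nyquist
    a
  }))
  structure(list(freq_hz = (seq_len(nf) - 1L) * rate_hz / n,
                 amplitude = amp, n = n),
            class = "spectrum_result")
}

#' Read an amplitude at (or nearest to) a frequency
#'
#' @param sp a `spectrum_result`; @param freq_hz requested frequency (must
#'   not exceed Nyquist); @param channel channel row (default 1).
#' @return Amplitude at the nearest bin, uV.
#' @export
spectrum_at <- function(sp, freq_hz, channel = 1L) {
  if (freq_hz > max(sp$freq_hz)) stop("frequency beyond Nyquist")
  sp$amplitude[channel, which.min(abs(sp$freq_hz - freq_hz))]
}

#' Complex Morlet wavelet time-frequency amplitude
#'
#' Convolution with complex Morlet wavelets parameterised, as in the common
#' EEG toolbox convention, by a central frequency and the temporal FWHM at
#' that frequency (defaults 1 Hz / 3 s); the Gaussian envelope scales
#' inversely with frequency. The wavelet is normalised so that a sinusoid of
#' amplitude A yields ridge amplitude A. Edge samples where the wavelet
#' support (+/-3 SD) exceeds the epoch are flagged.
#'
#' @param x channels x samples matrix (e.g. an ERP) or a vector.
#' @param rate_hz sampling rate.
#' @param freqs_hz frequency grid, strictly inside (0, Nyquist).
#' @param f0_hz,fwhm_t_s central frequency and temporal FWHM defining the
#'   wavelet family.
#' @return A `tfr_map`: list `amplitude` (channels x freqs x samples, uV),
#'   `freq_hz`, `times_s`, `edge` (freqs x samples logical).
#' @export
morlet_tfr <- function(x, rate_hz, freqs_hz, f0_hz = 1, fwhm_t_s = 3) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (any(freqs_hz <= 0) || any(freqs_hz >= rate_hz / 2))
    stop("frequency grid must lie strictly inside (0, Nyquist)")
  n <- ncol(x); nch <- nrow(x)
  sigma_c <- fwhm_t_s / (2 * sqrt(2 * log(2)))   # FWHM -> SD at f0
  amp <- array(NA_real_, c(nch, length(freqs_hz), n))
  edge <- matrix(FALSE, length(freqs_hz), n)
  for (j in seq_along(freqs_hz)) {
    f <- freqs_hz[j]
    sigma_t <- sigma_c * f0_hz / f
    half <- ceiling(3 * sigma_t * rate_hz)
    tt <- (-half:half) / rate_hz
    env <- exp(-tt^2 / (2 * sigma_t^2))
    w <- exp(2i * pi * f * tt) * env / sum(env)  # unit response to exp(2i pi f t)
    lw <- length(w)
    nfft <- stats::nextn(n + lw - 1L)
    wf <- stats::fft(c(w, rep(0, nfft - lw)))
    for (ch in seq_len(nch)) {
      xf <- stats::fft(c(x[ch, ], rep(0, nfft - n)))
      conv <- stats::fft(xf * wf, inverse = TRUE) / nfft
      # full convolution; the wavelet centre sits at lag `half`
      amp[ch, j, ] <- 2 * Mod(conv[half + seq_len(n)])
    }
    edge[j, c(seq_len(min(half, n)), seq.int(max(1L, n - half + 1L), n))] <- TRUE
  }
  structure(list(amplitude = amp, freq_hz = freqs_hz,
                 times_s = (seq_len(n) - 1L) / rate_hz, edge = edge),
            class = "tfr_map")
}

#' Action-offset-locked ERP
#'
#' Cuts epochs around per-trial action offsets and averages them. The
#' time-locking rule follows the control condition: solo trials lock to each
#' co-actor's own controller offset (pass that actor's offsets); joint
#' trials lock to the common joint-cursor offset, identical for both
#' co-actors.
#'
#' @param rec an `eeg_recording` (filtered).
#' @param offset_ms per-trial offset times, ms on the recording's time base
#'   (`NA` = trial excluded).
#' @param window_s epoch window around the offset (default -0.5 to +1 s).
#' @return An `erp` (channels x samples), with `n_trials` the number of
#'   trials with defined offsets that fit the recording.
#' @export
offset_locked_erp <- function(rec, offset_ms, window_s = c(-0.5, 1.0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$rate_hz
  i0 <- round(window_s[1] * fs); i1 <- round(window_s[2] * fs)
  centres <- round(offset_ms / 1000 * fs) + 1L
  centres <- centres[!is.na(centres)]
  centres <- centres[centres + i0 >= 1L & centres + i1 <= nrow(rec$data)]
  if (!length(centres)) stop("no trials with defined offsets in range")
  acc <- matrix(0, ncol(rec$data), i1 - i0 + 1L)
  for (cs in centres)
    acc <- acc + t(rec$data[cs + (i0:i1), , drop = FALSE])
  structure(list(data = acc / length(centres), times = (i0:i1) / fs,
                 rate_hz = fs, labels = rec$labels,
                 n_trials = length(centres)),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("ERP: %d channels x %d samples at %g Hz, mean of %d trials\n",
              nrow(x$data), ncol(x$data), x$rate_hz, x$n_trials))
  invisible(x)
}

#' @export
plot.erp <- function(x, channel = 1L, ...) {
  ch <- if (is.character(channel)) match(channel, x$labels) else channel
  graphics::plot(x$times, x$data[ch, ], type = "l",
                 xlab = "time (s)", ylab = "amplitude (uV)",
                 main = paste("ERP at", x$labels[ch]), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
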