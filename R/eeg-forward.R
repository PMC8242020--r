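# Linear EEG forward model for the dyad simulator.
#
# The synthetic EEG is a sum of independent components, each a source time
# course multiplied by a Gaussian electrode gain map:
#   * 1/f background noise (per-channel independent plus a component shared
#     across channels, mimicking volume conduction),
#   * the 7 Hz control-cue SSVEP (occipital, phase-locked to cue onset, with
#     a multiplicative joint-control modulation),
#   * 17/19 Hz target and distractor tags (occipital, phase-locked to the
#     spatial cue),
#   * small visual onset potentials to the fixation, control and spatial
#     cues (occipital),
#   * the delta-band action-offset potential (central, peaking near 200, 500
#     and 800 ms after action offset).
# Additivity is exact: components other than noise are deterministic given
# the markers, and the noise stream is seeded separately, so a synthesis
# restricted to one component reproduces that component of the full mix.

#' EEG forward model parameters
#'
#' @param rate_hz sampling rate of the synthetic recording (Hz). The
#'   acquisition-grade rate is 2000 Hz; lighter rates are routinely used for
#'   simulation studies since every component lives below 45 Hz.
#' @param noise_uv standard deviation of the 1/f background per channel (uV).
#' @param noise_exponent spectral exponent of the background (power ~ 1/f^a).
#' @param shared_noise_frac fraction of background variance shared across
#'   channels (volume conduction stand-in).
#' @param cue_ssvep list: `freq_hz`, `amp_uv`, `centre`, `sigma`,
#'   `joint_gain` (multiplicative amplitude modulation on joint trials).
#' @param tag_ssvep list: `target_uv`, `distractor_uv`, `centre`, `sigma`.
#'   Target and distractor placeholders flicker at 17/19 Hz (assignment per
#'   trial from the design), amplitudes reflecting attentional selection.
#' @param onset_erp list: `amp_uv`, `centre`, `sigma` for the visual onset
#'   potentials, or `NULL` to disable.
#' @param offset_erp list: `amp_uv`, `centre`, `sigma` for the action-offset
#'   potential, or `NULL` to disable.
#' @return An `eeg_forward_model` list.
#' @export
eeg_forward_model <- function(rate_hz = 500,
                              noise_uv = 10,
                              noise_exponent = 1,
                              shared_noise_frac = 0.3,
                              cue_ssvep = list(freq_hz = 7, amp_uv = 2,
                                               centre = "Oz", sigma = 0.35,
                                               joint_gain = 1.15),
                              tag_ssvep = list(target_uv = 0.75,
                                               distractor_uv = 0.10,
                                               centre = "Oz", sigma = 0.35),
                              onset_erp = list(amp_uv = 3, centre = "Oz",
                                               sigma = 0.35),
                              offset_erp = list(amp_uv = 6, centre = "Cz",
                                                sigma = 0.35)) {
  structure(list(rate_hz = rate_hz, noise_uv = noise_uv,
                 noise_exponent = noise_exponent,
                 shared_noise_frac = shared_noise_frac,
                 cue_ssvep = cue_ssvep, tag_ssvep = tag_ssvep,
                 onset_erp = onset_erp, offset_erp = offset_erp,
                 montage = standard_montage()),
            class = "eeg_forward_model")
}

#' 1/f ("pink") noise
#'
#' Spectrally shaped Gaussian noise: a white complex spectrum is scaled by
#' f^(-exponent/2) (power ~ 1/f^exponent) and inverse-transformed. Each
#' column is standardised to unit variance before scaling by `sd`.
#'
#' @param n samples; @param nchan channels; @param exponent spectral
#'   exponent; @param sd target standard deviation per channel.
#' @return n x nchan matrix. Consumes the current RNG stream.
#' @export
one_over_f_noise <- function(n, nchan = 1, exponent = 1, sd = 1) {
  nf <- stats::nextn(n)                  # composite FFT length, then truncate
  m <- matrix(stats::rnorm(nf * nchan), nf, nchan)
  f <- c(1, seq_len(nf - 1))                       # guard the DC bin
  f <- pmin(f, nf - f + 1)                         # mirrored frequency index
  scale <- f^(-exponent / 2)
  scale[1] <- 0                                    # zero-mean output
  sp <- stats::mvfft(m) * scale
  x <- Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n), , drop = FALSE] / nf
  x <- sweep(x, 2L, apply(x, 2L, stats::sd), `/`) * sd
  x
}

#' Action-offset potential template
#'
#' A slow central waveform spanning 0-1 s after action offset with peaks
#' near 200, 500 and 800 ms (alternating polarity), built from Gaussian
#' bumps and max-normalised to amplitude 1. Its spectral energy is
#' concentrated in the delta band (< 4 Hz).
#'
#' @param rate_hz sampling rate.
#' @return Numeric vector of length `rate_hz` (1 s), peak |amplitude| 1.
#' @export
offset_erp_template <- function(rate_hz) {
  t <- seq(0, 1, length.out = round(rate_hz) + 1)[-(round(rate_hz) + 1)]
  g <- function(mu, s) exp(-(t - mu)^2 / (2 * s^2))
  v <- -0.6 * g(0.2, 0.09) + 1.0 * g(0.5, 0.12) - 0.5 * g(0.8, 0.11)
  v / max(abs(v))
}

#' Visual onset potential template
#'
#' A brief biphasic deflection (P1/N1-like) spanning 0-0.4 s after stimulus
#' onset, max-normalised to amplitude 1.
#'
#' @param rate_hz sampling rate.
#' @return Numeric vector of length 0.4 * rate_hz.
#' @export
onset_erp_template <- function(rate_hz) {
  n <- round(0.4 * rate_hz)
  t <- seq(0, 0.4, length.out = n + 1)[-(n + 1)]
  g <- function(mu, s) exp(-(t - mu)^2 / (2 * s^2))
  v <- g(0.1, 0.025) - 0.7 * g(0.18, 0.04)
  v / max(abs(v))
}


#' Synthesize one participant's EEG recording
#'
#' Renders the forward model over a session's marker stream. SSVEP phases
#' are locked to their stimulus onsets (the control-cue tag to control-cue
#' onset, the 17/19 Hz tags to spatial-cue onset); the offset potential is
#' inserted at each trial's action-offset marker for this participant (the
#' participant's own controller offset on solo trials, the common
#' joint-cursor offset on joint trials -- the caller encodes this rule in
#' the `offset_ms` column it passes).
#'
#' @param trial_info data.frame with one row per trial: `trial`, `control`
#'   (`"solo"`/`"joint"`), `target_freq_hz`, `distractor_freq_hz`,
#'   `start_ms` (trial start in recording time), epoch onsets `precue_ms`,
#'   `cue_ms`, `spatial_ms` (recording time), `total_ms`, and `offset_ms`
#'   (action offset in recording time, `NA` when undefined).
#' @param forward forward model, see [eeg_forward_model()].
#' @param seed integer seed for the background-noise stream.
#' @param include character subset of
#'   `c("noise", "cue_ssvep", "tag_ssvep", "onset_erp", "offset_erp")`;
#'   components not listed are omitted (the model is additive, so partial
#'   syntheses sum exactly to the full one).
#' @param participant,pair identifiers stored on the recording.
#' @return An `eeg_recording`: list with `data` (samples x 61 channels, uV),
#'   `rate_hz`, `labels`, `markers` (data.frame `label`, `sample`, `trial`),
#'   `participant`, `pair`.
#' @export
synthesize_eeg <- function(trial_info, forward, seed,
                           include = c("noise", "cue_ssvep", "tag_ssvep",
                                       "onset_erp", "offset_erp"),
                           participant = 1L, pair = 1L) {
  fs <- forward$rate_hz
  mont <- forward$montage
  nchan <- nrow(mont)
  total_ms <- max(trial_info$start_ms + trial_info$total_ms)
  n <- ceiling(total_ms / 1000 * fs)
  if (any(trial_info$start_ms < 0) ||
      any(!is.na(trial_info$offset_ms) &
          trial_info$offset_ms / 1000 * fs > n))
    stop("markers fall outside the recording span")
  smp <- function(ms) round(ms / 1000 * fs) + 1L
  data <- matrix(0, n, nchan)

  if ("noise" %in% include && forward$noise_uv > 0) {
    set.seed(as.integer(seed))
    own <- one_over_f_noise(n, nchan, forward$noise_exponent,
                            sd = forward$noise_uv *
                              sqrt(1 - forward$shared_noise_frac))
    shared <- one_over_f_noise(n, 1, forward$noise_exponent,
                               sd = forward$noise_uv *
                                 sqrt(forward$shared_noise_frac))
    data <- data + own + shared %*% t(rep(1, nchan))
  }

  occ <- function(spec) gain_map(spec$centre, spec$sigma, mont)
  tvec <- (seq_len(n) - 1L) / fs                 # recording time, s

  for (i in seq_len(nrow(trial_info))) {
    tr <- trial_info[i, ]
    if ("cue_ssvep" %in% include && !is.null(forward$cue_ssvep) &&
        forward$cue_ssvep$amp_uv > 0) {
      cs <- forward$cue_ssvep
      i0 <- smp(tr$cue_ms); i1 <- smp(tr$spatial_ms) - 1L
      idx <- i0:min(i1, n)
      amp <- cs$amp_uv * if (tr$control == "joint") cs$joint_gain else 1
      src <- amp * sin(2 * pi * cs$freq_hz * (tvec[idx] - tvec[i0]))
      data[idx, ] <- data[idx, ] + outer(src, occ(cs))
    }
    if ("tag_ssvep" %in% include && !is.null(forward$tag_ssvep) &&
        (forward$tag_ssvep$target_uv > 0 || forward$tag_ssvep$distractor_uv > 0)) {
      ts <- forward$tag_ssvep
      i0 <- smp(tr$precue_ms)
      i1 <- min(smp(tr$spatial_ms + 2500) - 1L, n)
      idx <- i0:i1
      ph <- tvec[idx] - tvec[smp(tr$spatial_ms)]  # phase 0 at spatial cue
      src <- ts$target_uv * sin(2 * pi * tr$target_freq_hz * ph) +
             ts$distractor_uv * sin(2 * pi * tr$distractor_freq_hz * ph)
      data[idx, ] <- data[idx, ] + outer(src, occ(ts))
    }
    if ("onset_erp" %in% include && !is.null(forward$onset_erp) &&
        forward$onset_erp$amp_uv > 0) {
      oe <- forward$onset_erp
      tpl <- oe$amp_uv * onset_erp_template(fs)
      g_oe <- occ(oe)
      for (ms in c(tr$precue_ms, tr$cue_ms, tr$spatial_ms)) {
        idx <- smp(ms) + seq_along(tpl) - 1L
        ok <- idx >= 1L & idx <= n
        if (any(ok))
          data[idx[ok], ] <- data[idx[ok], ] + outer(tpl[ok], g_oe)
      }
    }
    if ("offset_erp" %in% include && !is.null(forward$offset_erp) &&
        forward$offset_erp$amp_uv > 0 && !is.na(tr$offset_ms)) {
      fe <- forward$offset_erp
      tpl <- fe$amp_uv * offset_erp_template(fs)
      idx <- smp(tr$offset_ms) + seq_along(tpl) - 1L
      ok <- idx >= 1L & idx <= n
      if (any(ok))
        data[idx[ok], ] <- data[idx[ok], ] + outer(tpl[ok], occ(fe))
    }
  }

  markers <- do.call(rbind, lapply(seq_len(nrow(trial_info)), function(i) {
    tr <- trial_info[i, ]
    data.frame(
      label = c("trial_start", "fixation_onset", "control_cue_onset",
                "spatial_cue_onset",
                if (!is.na(tr$offset_ms)) "action_offset"),
      sample = c(smp(tr$start_ms), smp(tr$precue_ms), smp(tr$cue_ms),
                 smp(tr$spatial_ms),
                 if (!is.na(tr$offset_ms)) smp(tr$offset_ms)),
      trial = tr$trial, stringsAsFactors = FALSE)
  }))
  structure(list(data = data, rate_hz = fs, labels = mont$label,
                 markers = markers, participant = participant, pair = pair),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording: %d channels x %d samples at %g Hz (%.1f s), %d markers\n",
    ncol(x$data), nrow(x$data), x$rate_hz, nrow(x$data) / x$rate_hz,
    nrow(x$markers)))
  invisible(x)
}
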