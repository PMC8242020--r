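# EEG conditioning: band limits, linearity, artefact flagging, resampling
# fidelity and marker remapping, gaze cleaning.

make_sine_rec <- function(freqs, fs, dur_s = 20, dc = 0) {
  tt <- (seq_len(dur_s * fs) - 1L) / fs
  data <- sapply(freqs, function(f) if (f == 0) rep(dc, length(tt))
                 else sin(2 * pi * f * tt))
  toy_recording(data, fs)
}

test_that("filtering hits the stated band limits at zero phase", {
  fs <- 256
  rec <- make_sine_rec(c(10, 50, 0), fs, dc = 1)
  out <- filter_eeg(rec)
  mid <- (5 * fs):(15 * fs)          # away from edges
  r10 <- stats::sd(out$data[mid, 1]) / stats::sd(rec$data[mid, 1])
  r50 <- stats::sd(out$data[mid, 2]) / stats::sd(rec$data[mid, 2])
  expect_gt(r10, 0.95)               # passband preserved within 5%
  expect_lt(r10, 1.05)
  expect_lt(r50, 0.1)                # >= 20 dB attenuation in the notch
  expect_lt(abs(mean(out$data[mid, 3])), 1e-3)   # DC removed
  # zero phase: a 10 Hz sinusoid keeps its phase (max lag correlation at 0)
  cc <- stats::ccf(out$data[mid, 1], rec$data[mid, 1], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # both methods agree in the passband
  out2 <- filter_eeg(rec, method = "filtfilt")
  expect_equal(stats::sd(out2$data[mid, 1]), stats::sd(out$data[mid, 1]),
               tolerance = 0.01)
  expect_error(filter_eeg(toy_recording(cbind(rnorm(100)), 64)), "twice")
})

test_that("filtering and resampling are linear; channels are preserved", {
  fs <- 256
  set.seed(3)
  a <- toy_recording(cbind(rnorm(fs * 4)), fs)
  b <- toy_recording(cbind(rnorm(fs * 4)), fs)
  ab <- a; ab$data <- a$data + b$data
  expect_equal(filter_eeg(ab)$data,
               filter_eeg(a)$data + filter_eeg(b)$data, tolerance = 1e-9)
  expect_equal(resample_eeg(ab, 64)$data,
               resample_eeg(a, 64)$data + resample_eeg(b, 64)$data,
               tolerance = 1e-9)
  rec <- make_sine_rec(c(7, 10), fs)
  expect_identical(filter_eeg(rec)$labels, rec$labels)
  expect_identical(resample_eeg(rec, 64)$labels, rec$labels)
})

test_that("artefact flagging follows the 100 uV rule and is monotone", {
  dat <- array(0, c(5, 3, 100))
  ep <- toy_epochs(dat, 64)
  expect_true(all(reject_artefact_trials(ep)$valid))      # all-zero: none
  dat[3, 2, 50] <- 150                                    # one 150 uV spike
  ep <- toy_epochs(dat, 64)
  expect_equal(which(!reject_artefact_trials(ep, 100)$valid), 3L)
  expect_true(all(reject_artefact_trials(ep, Inf)$valid)) # vacuous rule
  # monotone in threshold: raising it never flags more trials
  set.seed(4)
  dat <- array(rnorm(20 * 3 * 100, sd = 40), c(20, 3, 100))
  ep <- toy_epochs(dat, 64)
  flagged <- sapply(c(50, 100, 200, 400), function(th)
    sum(!reject_artefact_trials(ep, th)$valid))
  expect_true(all(diff(flagged) <= 0))
  # absolute-value alternative behind the switch
  dat0 <- array(60, c(2, 1, 10))                          # constant 60 uV
  ep0 <- toy_epochs(dat0, 64)
  expect_true(all(reject_artefact_trials(ep0, 100)$valid))
  expect_false(any(reject_artefact_trials(ep0, 50, mode = "absolute")$valid))
})

test_that("resampling preserves in-band amplitude and remaps markers", {
  fs <- 2000
  rec <- make_sine_rec(7, fs, dur_s = 10)
  rec$markers <- data.frame(label = "m", sample = c(2001L, 10001L), trial = 1:2)
  r256 <- resample_eeg(rec, 256)
  mid <- (2 * 256):(8 * 256)
  amp <- stats::sd(r256$data[mid, 1]) / stats::sd(rec$data[(2 * fs):(8 * fs), 1])
  expect_equal(amp, 1, tolerance = 0.02)
  # t = 1 s and t = 5 s markers land at the proportional samples
  expect_equal(r256$markers$sample, c(257L, 1281L), tolerance = 1)
  expect_equal(r256$rate_hz, 256)
  # 30 Hz survives resampling to 64 Hz (below the 32 Hz Nyquist)
  rec30 <- make_sine_rec(30, 2000, dur_s = 10)
  r64 <- resample_eeg(rec30, 64)
  amp30 <- stats::sd(r64$data[(2 * 64):(8 * 64), 1]) /
    stats::sd(rec30$data[(2 * fs):(8 * fs), 1])
  expect_equal(amp30, 1, tolerance = 0.05)
  expect_error(resample_eeg(rec30, 4000), "upsampling")
})

test_that("gaze cleaning masks around blinks and pupil transients", {
  fs <- 120
  n <- 3 * fs
  tr <- data.frame(t_ms = (seq_len(n) - 1L) / fs * 1000,
                   x = 0, y = 0, pupil = 1000, valid = TRUE)
  # smooth trace: untouched
  expect_identical(clean_gaze(tr)$valid, tr$valid)
  # 100 ms blink at t = 1 s: the masked interval covers [0.8, 1.3] s
  bl <- tr
  blink <- bl$t_ms >= 1000 & bl$t_ms <= 1100
  bl$pupil[blink] <- 0; bl$valid[blink] <- FALSE
  cl <- clean_gaze(bl)
  expect_true(all(!cl$valid[bl$t_ms >= 810 & bl$t_ms <= 1290]))
  expect_true(all(cl$valid[bl$t_ms < 790 | bl$t_ms > 1310]))
  # constant pupil: percentile rule masks nothing (ties, strict exceedance)
  expect_identical(clean_gaze(tr)$valid, rep(TRUE, n))
  # a single sharp pupil jump is masked
  pj <- tr; pj$pupil[200] <- 4000
  expect_false(all(clean_gaze(pj)$valid))
})
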