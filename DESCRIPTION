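Package: dyadEEG
Title: Dyadic EEG Hyperscanning Analysis for Joint Cursor-Control Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dyadic (two-person)
    visuomotor joint-action experiments with simultaneous EEG recording.
    Implements the redundant joint cursor-control task (solo and gated-mean
    joint control laws, counterbalanced session designs, game-logic trial
    scoring), a closed-loop dyad simulator with a linear EEG forward model
    (1/f background, occipital SSVEP frequency tags, a central delta-band
    action-offset potential) and gaze generator, EEG preprocessing
    (zero-phase band-limiting, artefact flagging, anti-aliased resampling,
    epoching), behavioural kinematics (controller displacement, onset and
    offset detection, Menger circle-fit curvature, endpoint displacement),
    interpersonal behavioural coupling measures, SSVEP and event-related
    potential analyses (FFT amplitude spectra, Morlet wavelet transforms,
    offset-locked averaging), sliding-window inter-brain Pearson
    correlation maps with label-shuffling permutation thresholds, and
    single-trial brain-behaviour statistics (repeated-measures ANOVA,
    per-pair correlation and multiple regression with Bonferroni control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
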