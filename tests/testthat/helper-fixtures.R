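# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

# small canned pair session + constructed trajectories (seed pinned)
fixtures <- function() {
  if (is.null(.fx$fixtures)) .fx$fixtures <- make_fixtures(seed = 42)
  .fx$fixtures
}

# minimal eeg_recording constructor for signal-level tests
toy_recording <- function(data, rate_hz, markers = NULL,
                          labels = paste0("ch", seq_len(ncol(data)))) {
  if (is.null(markers))
    markers <- data.frame(label = "spatial_cue_onset", sample = 1L,
                          trial = 1L, stringsAsFactors = FALSE)
  structure(list(data = data, rate_hz = rate_hz, labels = labels,
                 markers = markers, participant = 1L, pair = 1L),
            class = "eeg_recording")
}

# minimal epoch_set constructor (trials x channels x samples)
toy_epochs <- function(data, rate_hz, t0 = 0,
                       labels = paste0("ch", seq_len(dim(data)[2]))) {
  structure(list(data = data, times = t0 + (seq_len(dim(data)[3]) - 1L) / rate_hz,
                 rate_hz = rate_hz, labels = labels,
                 valid = rep(TRUE, dim(data)[1]),
                 trial = seq_len(dim(data)[1]), conditions = NULL,
                 reference = "spatial_cue_onset"),
            class = "epoch_set")
}

# the mechanism study: 20 simulated pairs carried through the full pipeline;
# shared by the acceptance tests (built on first use)
mechanism_run <- function() {
  if (is.null(.fx$mech)) {
    cfg <- pipeline_config(n_pairs = 20, blocks = 3, block_size = 16,
                           n_perm = 1000, seed = 2026)
    .fx$mech <- run_pipeline(cfg)
  }
  .fx$mech
}
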