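# Shared fixture builders. Everything is generated in code at test time.

# One simulated subject at the calibrated defaults.
sim_subject <- function(seed = 1L, n_trials = 400L,
                        params = observer_params(0.78, 0.14),
                        race = race_config()) {
  cfg <- task_config(n_trials = n_trials, seed = seed)
  simulate_responder(generate_sequence(cfg), race, params, cfg)
}

# A small, fast EEG -> TFR chain: few frequencies, low sampling rate.
small_tf_config <- function() {
  tf_config(freqs_hz = exp(seq(log(2), log(30), length.out = 15)))
}

small_eeg_chain <- function(trials, lock = "fixation", seed = 1L,
                            gain = 3, noise = 10, fs = 125,
                            time_step = 5L, window = c(0, 0.5),
                            baseline = TRUE) {
  b <- switch(lock,
              fixation = burst_spec(4, 0.10, 0.05, 8, gain),
              go = burst_spec(4, 0.45, 0.12, 8, -gain),
              stop = burst_spec(16, 0.35, 0.03, 8, gain))
  ec <- eeg_sim_config(fs_hz = fs, noise_scale_uv = noise, burst = b,
                       artifact_rate = 0, seed = seed)
  ep <- simulate_epochs(trials, ec, lock)
  tfc <- small_tf_config()
  tf <- morlet_transform(ep, tfc, time_step = time_step)
  if (baseline) tf <- baseline_correct(tf, tfc)
  crop_tfr(tf, time_range = window)
}

# Synthetic subject z-maps: pure N(0, 1) noise, the calibrated null of
# the within-subject standardization.
noise_zmaps <- function(n_subjects, nf, nt, seed) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i)
    structure(list(z = matrix(rnorm(nf * nt), nf, nt),
                   covariate_name = "none", lock = "fixation",
                   freqs_hz = seq_len(nf), times_s = seq_len(nt),
                   n_trials = NA_integer_),
              class = "zmap"))
}
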