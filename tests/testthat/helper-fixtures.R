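# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# clean paired record: constant HR, no noise of any kind -> exact labels
clean_sim <- function() fixture("clean_sim", function() {
  simulate_record(synth_config(
    duration_s = 30, hr_bpm = 70, hr_sd = 0, noise_sd = 0,
    coupling_eps_sd = 0, dbp_noise_sd = 0, bp_drift = 0, seed = 3))
})

# the standard QRS fixture: hr 60, 10 s, moderate broadband noise
qrs_fixture <- function(seed = 42) {
  sim <- simulate_ecg(synth_config(duration_s = 10, hr_bpm = 60, hr_sd = 0,
                                   noise_sd = 0.1, seed = seed))
  ecg <- remove_baseline_wavelet(
    lowpass_filter(sim$record$channels$ecg, 125), 125)
  list(ecg = ecg, truth_idx = round(sim$truth$beat_times_s * 125))
}

# score a detection against ground-truth indices at the given tolerance
qrs_score <- function(detected, truth_idx, tol_samples = 6L) {
  tp <- sum(vapply(detected, function(i) any(abs(truth_idx - i) <= tol_samples),
                   logical(1)))
  list(sensitivity = tp / length(truth_idx),
       ppv = if (length(detected)) tp / length(detected) else NA_real_)
}

# small real-architecture labeled frame set for model tests
small_labeled_frames <- function() fixture("small_frames", function() {
  sim <- simulate_record(synth_config(
    duration_s = 60, hr_bpm = 75, hr_sd = 2, noise_sd = 0.02, seed = 21))
  frames <- preprocess_record(sim$record)
  label_frames(frames)
})

# tiny network configuration: full layer structure, few filters, fast
tiny_model_config <- function() {
  model_config(frame_len = 128L, conv_filters = c(2L, 3L, 4L, 5L),
               kernel_size = 3L, feature_dim = 6L, fc_nodes = c(4L, 3L))
}
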