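test_that("beat placement is exact for a deterministic rhythm", {
  sim <- simulate_ecg(synth_config(duration_s = 10, hr_bpm = 60, hr_sd = 0,
                                   noise_sd = 0, seed = 1))
  bt <- sim$truth$beat_times_s
  expect_length(bt, 10L)
  expect_equal(diff(bt), rep(1.0, 9), tolerance = 1e-12)
})

test_that("the generator is bit-deterministic under a fixed seed", {
  cfg <- synth_config(duration_s = 15, noise_sd = 0.05, powerline_amp = 0.05,
                      wander_amp = 0.2, seed = 9)
  a <- simulate_record(cfg)
  b <- simulate_record(cfg)
  expect_identical(a$record$channels, b$record$channels)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_record(synth_config(duration_s = 15, noise_sd = 0.05,
                                     powerline_amp = 0.05, wander_amp = 0.2,
                                     seed = 10))
  expect_false(identical(a$record$channels$ecg, c2$record$channels$ecg))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_record(synth_config(duration_s = 5, seed = 77)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free ECG mean matches the integrated wave template", {
  # over a whole number of identical beats the mean equals the sum of the
  # Gaussian wave integrals divided by the cycle length
  sim <- simulate_ecg(synth_config(duration_s = 10, hr_bpm = 60, hr_sd = 0,
                                   noise_sd = 0, seed = 2))
  tpl <- ecg2bp:::pqrst_template()
  expected <- sum(tpl$amp * tpl$sigma * sqrt(2 * pi)) / 1.0  # RR = 1 s
  # restrict to an integer number of complete beats
  ecg <- sim$record$channels$ecg
  expect_equal(mean(ecg), expected, tolerance = 0.02)
})

test_that("rendered ABP extrema equal the stored per-beat pressures", {
  sim <- clean_sim()
  abp <- sim$record$channels$abp
  tr <- sim$truth
  ok <- tr$rendered
  # brute-force per-cycle scan between consecutive onsets
  for (i in which(ok)) {
    i0 <- tr$onset_idx[i] + 1L
    i1 <- if (i < length(tr$onset_idx)) tr$onset_idx[i + 1L] else length(abp)
    cyc <- abp[i0:i1]
    expect_equal(max(cyc), tr$per_beat_sbp[i], tolerance = 1e-12)
    expect_equal(min(cyc), tr$per_beat_dbp[i], tolerance = 1e-12)
  }
  # constant-HR noise-free config: every cycle hits the configured values
  expect_equal(unique(round(tr$per_beat_sbp, 9)), 120)
  expect_equal(unique(round(tr$per_beat_dbp, 9)), 80)
})

test_that("per-beat SBP always exceeds per-beat DBP", {
  for (seed in c(1, 7, 19)) {
    sim <- simulate_record(synth_config(duration_s = 20, hr_sd = 4,
                                        coupling_eps_sd = 4, dbp_noise_sd = 3,
                                        bp_drift = 8, seed = seed))
    expect_true(all(sim$truth$per_beat_sbp > sim$truth$per_beat_dbp))
  }
})

test_that("heart-rate ramp produces monotone SBP through the coupling", {
  cfg <- synth_config(duration_s = 60, hr_bpm = 60, hr_ramp_bpm = 30,
                      hr_sd = 0, coupling_eps_sd = 0, dbp_noise_sd = 0,
                      bp_drift = 0, noise_sd = 0, seed = 4)
  sim <- simulate_record(cfg)
  sbp <- sim$truth$per_beat_sbp
  third <- length(sbp) %/% 3
  expect_gt(mean(tail(sbp, third)), mean(head(sbp, third)))
})

test_that("power-line interference shows up as a spectral peak", {
  cfg <- synth_config(duration_s = 20, fs = 250, powerline_hz = 60,
                      powerline_amp = 0.2, noise_sd = 0, seed = 5)
  sim <- simulate_ecg(cfg)
  x <- sim$record$channels$ecg
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * 250 / n
  peak_f <- freqs[which.max(sp * (freqs > 45))]  # ignore cardiac band
  expect_lt(abs(peak_f - 60), 0.5)
})

test_that("fs below the power-line Nyquist rate warns about aliasing", {
  expect_warning(synth_config(fs = 100, powerline_hz = 60,
                              powerline_amp = 0.1), "alias")
})

test_that("simulate_dataset is reproducible and jitters record baselines", {
  cfg <- synth_config(duration_s = 10, seed = 31)
  ds1 <- simulate_dataset(cfg, 3)
  ds2 <- simulate_dataset(cfg, 3)
  for (i in 1:3) {
    expect_identical(ds1[[i]]$record$channels, ds2[[i]]$record$channels)
  }
  expect_false(identical(ds1[[1]]$record$channels$ecg,
                         ds1[[2]]$record$channels$ecg))
  # with jitter off, records differ only by their noise realization
  ds3 <- simulate_dataset(cfg, 2, hr_jitter_sd = 0, bp_jitter_sd = 0)
  expect_equal(ds3[[1]]$config$hr_bpm, ds3[[2]]$config$hr_bpm)
})

test_that("pooled per-beat SBP follows the configured coupling law", {
  # law of large numbers: mean SBP over many records ~ a + b * mean HR
  cfg <- synth_config(duration_s = 30, hr_bpm = 70, hr_sd = 2,
                      coupling_b = 0.5, coupling_eps_sd = 2, seed = 55)
  ds <- simulate_dataset(cfg, 50)
  sbp <- unlist(lapply(ds, function(d) d$truth$per_beat_sbp))
  hr <- unlist(lapply(ds, function(d) d$truth$hr_inst_bpm))
  a_bar <- mean(vapply(ds, function(d) d$config$coupling_a, numeric(1)))
  expect_equal(mean(sbp), a_bar + 0.5 * mean(hr), tolerance = 0.02)
  # and the slope is recoverable by regression across records
  fit <- stats::lm(sbp ~ hr)
  expect_equal(unname(stats::coef(fit)[2]), 0.5, tolerance = 0.15)
})

test_that("frame_truth agrees with stored per-beat values on clean data", {
  sim <- clean_sim()
  ft <- frame_truth(sim$record$channels$abp, 128)
  valid <- ft$valid
  expect_gt(sum(valid), 20)
  expect_true(all(abs(ft$sbp[valid] - 120) < 1e-9))
  expect_true(all(abs(ft$dbp[valid] - 80) < 1e-9))
})

test_that("degenerate configurations are rejected", {
  expect_error(synth_config(sbp_mmHg = 80, dbp_mmHg = 90), "exceed")
  expect_error(simulate_ecg(synth_config(duration_s = 0.2, seed = 1)),
               "too short")
})
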