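test_that("ABP extrema match the construction on clean beats", {
  sim <- simulate_record(synth_config(
    duration_s = 4, hr_bpm = 60, hr_sd = 0, noise_sd = 0,
    coupling_eps_sd = 0, dbp_noise_sd = 0, bp_drift = 0, seed = 6))
  abp <- sim$record$channels$abp
  ex <- find_abp_extrema(abp, 125)
  expect_false(ex$degenerate)
  expect_equal(abp[ex$peaks$indices + 1L], rep(120, length(ex$peaks$indices)),
               tolerance = 1e-9)
  expect_equal(abp[ex$troughs$indices + 1L],
               rep(80, length(ex$troughs$indices)), tolerance = 1e-9)
  # peaks and troughs strictly alternate
  merged <- sort(c(ex$peaks$indices, ex$troughs$indices))
  kinds <- ifelse(merged %in% ex$peaks$indices, "p", "t")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("flat and single-cycle signals are handled", {
  ex <- find_abp_extrema(rep(100, 500), 125)
  expect_true(ex$degenerate)
  expect_length(ex$peaks$indices, 0L)
  # one full cycle in a short frame
  sim <- clean_sim()
  tr <- sim$truth
  i0 <- tr$onset_idx[3] - 5L
  frame <- sim$record$channels$abp[(i0 + 1L):(i0 + 128L)]
  ex1 <- find_abp_extrema(frame, 125)
  expect_gte(length(ex1$peaks$indices), 1L)
  expect_gte(length(ex1$troughs$indices), 1L)
})

test_that("label_frame averages the extrema amplitudes in the frame", {
  # triangular two-beat frame with peaks {120, 122} and troughs {80, 78}
  seg <- function(from, to, n) seq(from, to, length.out = n + 1)[-(n + 1)]
  x <- c(seg(100, 120, 16), seg(120, 80, 32), seg(80, 122, 34),
         seg(122, 78, 36), seg(78, 90, 10))
  lab <- label_frame(x, fs = 125)
  expect_equal(lab$sbp, 121)
  expect_equal(lab$dbp, 79)
  expect_equal(lab$n_peaks, 2L)
  expect_equal(lab$n_troughs, 2L)
  expect_true(lab$valid)
  # frame with no complete cycle -> invalid
  ramp <- label_frame(seq(80, 120, length.out = 128), fs = 125)
  expect_false(ramp$valid)
  expect_equal(ramp$n_peaks, 0L)
  expect_error(label_frame(NULL, 125), "no ABP")
})

test_that("labels equal synthetic ground truth on noise-free records", {
  sim <- clean_sim()
  frames <- label_frames(preprocess_record(sim$record))
  ft <- frame_truth(sim$record$channels$abp, 128)
  both <- frames$labels$valid & ft$valid
  expect_gt(sum(both), 20)
  expect_lt(max(abs(frames$labels$sbp[both] - ft$sbp[both])), 1e-6)
  expect_lt(max(abs(frames$labels$dbp[both] - ft$dbp[both])), 1e-6)
  expect_true(all(frames$labels$sbp[both] > frames$labels$dbp[both]))
})

test_that("implausible pressures are flagged invalid", {
  sim <- clean_sim()
  fr <- preprocess_record(sim$record)
  hot <- fr$abp[1, ] + 200  # shift SBP beyond 250 mmHg
  expect_false(label_frame(hot, 125)$valid)
  cold <- fr$abp[1, ] - 70  # DBP below 20 mmHg
  expect_false(label_frame(cold, 125)$valid)
})

test_that("QRS detection recovers clean beats within one sample", {
  sim <- simulate_ecg(synth_config(duration_s = 10, hr_bpm = 60, hr_sd = 0,
                                   noise_sd = 0, seed = 5))
  ecg <- remove_baseline_wavelet(
    lowpass_filter(sim$record$channels$ecg, 125), 125)
  ann <- detect_qrs(ecg, 125)
  truth <- round(sim$truth$beat_times_s * 125)
  expect_length(ann$indices, 10L)
  expect_true(all(abs(ann$indices - truth) <= 1L))
})

test_that("QRS detection stays accurate under moderate noise", {
  fx <- qrs_fixture(seed = 42)
  ann <- detect_qrs(fx$ecg, 125)
  sc <- qrs_score(ann$indices, fx$truth_idx)
  expect_gte(sc$sensitivity, 0.95)
  expect_gte(sc$ppv, 0.95)
})

test_that("flat input yields an empty annotation with a warning", {
  expect_warning(ann <- detect_qrs(rep(0, 1250), 125), "no beats")
  expect_length(ann$indices, 0L)
})

test_that("rhythm_summary computes RR and HR by definition", {
  rs <- rhythm_summary(beat_annotation(c(0L, 125L, 250L), "r_peak"), 125)
  expect_equal(rs$rr_s, c(1, 1))
  expect_equal(rs$hr_bpm, c(60, 60))
  rs2 <- rhythm_summary(beat_annotation(c(0L, 100L), "r_peak"), 125)
  expect_equal(rs2$rr_s, 0.8)
  expect_equal(rs2$hr_bpm, 75)
  expect_error(rhythm_summary(beat_annotation(5L, "r_peak"), 125),
               "at least 2")
})

test_that("a ramped heart rate shows as a rising HR trace", {
  sim <- simulate_ecg(synth_config(duration_s = 60, hr_bpm = 60,
                                   hr_ramp_bpm = 30, hr_sd = 0,
                                   noise_sd = 0.05, seed = 7))
  ecg <- remove_baseline_wavelet(
    lowpass_filter(sim$record$channels$ecg, 125), 125)
  rs <- rhythm_summary(detect_qrs(ecg, 125), 125)
  # smoothed HR trace rises monotonically with beat index
  smooth <- stats::filter(rs$hr_bpm, rep(1 / 5, 5), sides = 2)
  smooth <- smooth[!is.na(smooth)]
  expect_gt(stats::cor(seq_along(smooth), as.numeric(smooth)), 0.95)
  expect_gt(tail(smooth, 1), head(smooth, 1) + 20)
})

test_that("beat annotations validate their indices", {
  expect_error(beat_annotation(c(5L, 5L), "r_peak"), "strictly increasing")
  expect_error(beat_annotation(c(10L, 3L), "r_peak"), "strictly increasing")
  expect_error(beat_annotation(c(-1L), "r_peak"), ">= 0")
  expect_error(beat_annotation(c(600L), "r_peak", n_total = 500L), "beyond")
})
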