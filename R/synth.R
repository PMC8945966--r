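#' Configuration for the coupled ECG/ABP simulator
#'
#' The simulator emulates the paired single-channel ECG and arterial
#' blood-pressure (ABP) waveforms the estimation pipeline is designed for:
#' beat-synchronous PQRST morphology on the ECG side, a per-cycle
#' systolic-upstroke/diastolic-decay pressure pulse on the ABP side, and a
#' known statistical coupling between heart rate and systolic pressure so
#' that blood pressure is recoverable from the ECG rhythm alone. Additive
#' broadband noise, power-line interference and low-frequency baseline
#' wander contaminate the ECG channel; the ABP channel is rendered clean so
#' its per-cycle extrema are exact ground truth.
#'
#' The coupling is `SBP_i = a + b * HR_i + eps_i` per beat, with `HR_i` the
#' instantaneous heart rate (60 / RR) and `eps_i ~ N(0, coupling_eps_sd)`.
#' Diastolic pressure follows as `DBP_i = SBP_i - pulse_pressure + eta_i`
#' with `eta_i ~ N(0, dbp_noise_sd)`. A slow sinusoidal drift of amplitude
#' `bp_drift` is added to both pressures.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz.
#' @param hr_bpm mean heart rate in beats per minute.
#' @param hr_sd beat-to-beat heart-rate standard deviation (bpm).
#' @param hr_ramp_bpm total linear heart-rate drift over the record (bpm);
#'   0 for a stationary rhythm.
#' @param sbp_mmHg,dbp_mmHg baseline systolic/diastolic pressure; `sbp_mmHg`
#'   sets the coupling intercept via `a = sbp_mmHg - b * hr_bpm` so the mean
#'   SBP at the mean heart rate equals `sbp_mmHg`; `dbp_mmHg` sets the pulse
#'   pressure `sbp_mmHg - dbp_mmHg`.
#' @param bp_drift amplitude of the slow within-record BP variation (mmHg).
#' @param coupling_a,coupling_b coefficients of the HR-to-SBP relation in
#'   mmHg and mmHg/bpm. If `coupling_a` is `NULL` (default) it is derived
#'   from `sbp_mmHg` as above.
#' @param coupling_eps_sd SD of the per-beat SBP noise `eps` (mmHg).
#' @param dbp_noise_sd SD of the independent per-beat DBP noise (mmHg).
#' @param noise_sd broadband ECG noise SD, in mV.
#' @param powerline_hz,powerline_amp power-line interference frequency (Hz)
#'   and amplitude (mV).
#' @param wander_hz,wander_amp baseline-wander frequency (Hz) and amplitude
#'   (mV).
#' @param r_amp_mv R-wave amplitude (mV).
#' @param seed RNG seed; identical seed and config give bit-identical output.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 60, fs = 125,
                         hr_bpm = 70, hr_sd = 2, hr_ramp_bpm = 0,
                         sbp_mmHg = 120, dbp_mmHg = 80, bp_drift = 0,
                         coupling_a = NULL, coupling_b = 0.5,
                         coupling_eps_sd = 2, dbp_noise_sd = 1,
                         noise_sd = 0.02, powerline_hz = 60,
                         powerline_amp = 0, wander_hz = 0.2,
                         wander_amp = 0, r_amp_mv = 1.0, seed = 1L) {
  if (sbp_mmHg <= dbp_mmHg) stop("sbp_mmHg must exceed dbp_mmHg", call. = FALSE)
  if (duration_s <= 0 || fs <= 0) stop("duration_s and fs must be positive",
                                       call. = FALSE)
  if (hr_bpm <= 0) stop("hr_bpm must be positive", call. = FALSE)
  if (powerline_amp > 0 && fs < 2 * powerline_hz) {
    warning("fs < 2 * powerline_hz: the interference tone will alias")
  }
  if (is.null(coupling_a)) coupling_a <- sbp_mmHg - coupling_b * hr_bpm
  structure(list(
    duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, hr_sd = hr_sd,
    hr_ramp_bpm = hr_ramp_bpm, sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
    bp_drift = bp_drift, coupling_a = coupling_a, coupling_b = coupling_b,
    coupling_eps_sd = coupling_eps_sd, dbp_noise_sd = dbp_noise_sd,
    noise_sd = noise_sd, powerline_hz = powerline_hz,
    powerline_amp = powerline_amp, wander_hz = wander_hz,
    wander_amp = wander_amp, r_amp_mv = r_amp_mv, seed = as.integer(seed)
  ), class = "synth_config")
}

# PQRST Gaussian-wave template: amplitude (relative to R), center offset from
# the R peak (s), and width (s) for each of the five waves.
pqrst_template <- function() {
  data.frame(
    wave  = c("P", "Q", "R", "S", "T"),
    amp   = c(0.15, -0.10, 1.00, -0.20, 0.30),
    mu    = c(-0.200, -0.040, 0.000, 0.040, 0.250),
    sigma = c(0.025, 0.010, 0.012, 0.010, 0.045)
  )
}

# restore the caller's RNG state on exit so simulation calls do not clobber it
local_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Simulate a single-channel ECG with known beat times
#'
#' Renders one Gaussian wave per PQRST deflection at beat times drawn from
#' the configured heart-rate process, then adds white noise, a power-line
#' sinusoid and a baseline-wander sinusoid. The returned ground truth
#' carries the exact R-peak times; [simulate_abp()] extends it with
#' per-beat pressures.
#'
#' @param config a [synth_config()].
#' @return list with elements `record` (a [waveform_record()] with an `ecg`
#'   channel) and `truth` (list with `beat_times_s`, `hr_inst_bpm`, `rr_s`).
#' @export
simulate_ecg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  restore <- local_seed(config$seed)
  on.exit(restore())
  n <- round(config$duration_s * config$fs)

  # beat placement: draw per-beat HR around the (possibly ramping) target
  beat_times <- numeric(0)
  t <- 0.4  # first R peak offset
  repeat {
    frac <- min(t / config$duration_s, 1)
    hr_target <- config$hr_bpm + config$hr_ramp_bpm * frac
    hr <- max(30, min(220, hr_target + stats::rnorm(1, 0, config$hr_sd)))
    if (t > config$duration_s - 0.1) break
    beat_times <- c(beat_times, t)
    t <- t + 60 / hr
  }
  if (length(beat_times) < 1L) {
    stop("duration too short to place a single beat", call. = FALSE)
  }

  tt <- (seq_len(n) - 1L) / config$fs
  ecg <- numeric(n)
  tpl <- pqrst_template()
  for (bt in beat_times) {
    for (w in seq_len(nrow(tpl))) {
      mu <- bt + tpl$mu[w]
      sig <- tpl$sigma[w]
      i0 <- max(1L, floor((mu - 5 * sig) * config$fs) + 1L)
      i1 <- min(n, ceiling((mu + 5 * sig) * config$fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      ecg[idx] <- ecg[idx] +
        config$r_amp_mv * tpl$amp[w] * exp(-((tt[idx] - mu)^2) / (2 * sig^2))
    }
  }
  if (config$noise_sd > 0) ecg <- ecg + stats::rnorm(n, 0, config$noise_sd)
  if (config$powerline_amp > 0) {
    ecg <- ecg + config$powerline_amp * sin(2 * pi * config$powerline_hz * tt)
  }
  if (config$wander_amp > 0) {
    ecg <- ecg + config$wander_amp * sin(2 * pi * config$wander_hz * tt)
  }

  rr <- diff(beat_times)
  rr_all <- if (length(rr)) c(rr, rr[length(rr)]) else 60 / config$hr_bpm
  truth <- list(beat_times_s = beat_times, rr_s = rr_all,
                hr_inst_bpm = 60 / rr_all)
  record <- waveform_record(list(ecg = ecg), fs = config$fs,
                            record_id = sprintf("synth-%d", config$seed),
                            units = c(ecg = "mV"))
  list(record = record, truth = truth)
}

#' Simulate the arterial pressure channel matching a set of beat times
#'
#' Each cardiac cycle is rendered as a raised-cosine systolic upstroke
#' followed by an exponential diastolic decay, then affinely rescaled so the
#' cycle's discrete maximum equals that beat's SBP and its minimum equals
#' the DBP exactly. Per-beat SBP follows the configured coupling with
#' instantaneous heart rate plus drift and noise; DBP is SBP minus the pulse
#' pressure plus independent noise. The pressure pulse is delayed 0.15 s
#' after the R peak (a fixed pulse-arrival offset).
#'
#' @param config a [synth_config()].
#' @param truth ground-truth list from [simulate_ecg()] (needs
#'   `beat_times_s`).
#' @return list with `record` (a [waveform_record()] with an `abp` channel)
#'   and `truth` extended with `per_beat_sbp`, `per_beat_dbp`,
#'   `onset_idx`, `peak_idx`, `trough_idx` (0-based sample indices).
#' @export
simulate_abp <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  restore <- local_seed(config$seed + 104729L)  # independent stream
  on.exit(restore())
  n <- round(config$duration_s * config$fs)
  bt <- truth$beat_times_s
  nb <- length(bt)
  hr <- truth$hr_inst_bpm

  drift <- if (config$bp_drift > 0) {
    config$bp_drift * sin(2 * pi * bt / max(60, config$duration_s))
  } else rep(0, nb)
  eps <- stats::rnorm(nb, 0, config$coupling_eps_sd)
  sbp <- config$coupling_a + config$coupling_b * hr + drift + eps
  pp <- config$sbp_mmHg - config$dbp_mmHg
  eta <- stats::rnorm(nb, 0, config$dbp_noise_sd)
  dbp <- sbp - pp + eta  # drift already enters through sbp
  dbp <- pmin(dbp, sbp - 10)  # enforce a physiological pulse pressure floor

  onset <- bt + 0.15
  onset_idx <- pmin(round(onset * config$fs), n - 1L)
  abp <- rep(dbp[1], n)
  peak_idx <- integer(nb)
  trough_idx <- integer(nb)
  for (i in seq_len(nb)) {
    i0 <- onset_idx[i] + 1L  # 1-based start
    i1 <- if (i < nb) onset_idx[i + 1L] else n
    if (i1 <= i0) { peak_idx[i] <- NA_integer_; trough_idx[i] <- NA_integer_; next }
    m <- i1 - i0 + 1L
    u <- (seq_len(m) - 1L) / config$fs
    cyc <- u[m] + 1 / config$fs
    ts <- 0.3 * cyc                       # systolic upstroke duration
    tau <- 0.25 * cyc                     # diastolic decay constant
    s <- ifelse(u < ts, 0.5 * (1 - cos(pi * u / ts)), exp(-(u - ts) / tau))
    rng <- range(s)
    y <- dbp[i] + (sbp[i] - dbp[i]) * (s - rng[1]) / (rng[2] - rng[1])
    abp[i0:i1] <- y
    peak_idx[i] <- i0 - 1L + which.max(y) - 1L   # 0-based
    trough_idx[i] <- i0 - 1L + which.min(y) - 1L
  }
  # lead-in before the first onset: hold the first diastolic value
  if (onset_idx[1] > 0) abp[seq_len(onset_idx[1])] <- dbp[1]

  keep <- !is.na(peak_idx)
  truth$per_beat_sbp <- sbp
  truth$per_beat_dbp <- dbp
  truth$onset_idx <- onset_idx
  truth$peak_idx <- peak_idx
  truth$trough_idx <- trough_idx
  truth$rendered <- keep
  record <- waveform_record(list(abp = abp), fs = config$fs,
                            record_id = sprintf("synth-%d", config$seed),
                            units = c(abp = "mmHg"))
  list(record = record, truth = truth)
}

#' Simulate one paired ECG + ABP record
#'
#' Convenience wrapper running [simulate_ecg()] then [simulate_abp()] and
#' merging the channels into a single two-channel record.
#'
#' @param config a [synth_config()].
#' @return list with `record` (channels `ecg`, `abp`) and the full `truth`.
#' @export
simulate_record <- function(config) {
  e <- simulate_ecg(config)
  a <- simulate_abp(config, e$truth)
  record <- waveform_record(
    list(ecg = e$record$channels$ecg, abp = a$record$channels$abp),
    fs = config$fs, record_id = e$record$record_id,
    units = c(ecg = "mV", abp = "mmHg")
  )
  list(record = record, truth = a$truth)
}

#' Simulate an independent multi-record dataset
#'
#' Each record gets its own seed derived deterministically from the master
#' seed, and its heart-rate and blood-pressure baselines are jittered
#' around the configured values (normal jitter, SDs `hr_jitter_sd` and
#' `bp_jitter_sd`) so records emulate distinct physiological states, the
#' way different subjects or sessions would.
#'
#' @param config a [synth_config()] giving the population-level baselines;
#'   `config$seed` is the master seed.
#' @param n_records number of records (>= 1).
#' @param hr_jitter_sd SD of the per-record heart-rate baseline jitter (bpm).
#' @param bp_jitter_sd SD of the per-record SBP baseline jitter (mmHg),
#'   applied through the coupling intercept.
#' @return list of `n_records` elements, each a `list(record, truth,
#'   config)`.
#' @export
simulate_dataset <- function(config, n_records, hr_jitter_sd = 10,
                             bp_jitter_sd = 5) {
  stopifnot(inherits(config, "synth_config"), n_records >= 1)
  restore <- local_seed(config$seed + 15485863L)
  on.exit(restore())
  hr_jit <- stats::rnorm(n_records, 0, hr_jitter_sd)
  bp_jit <- stats::rnorm(n_records, 0, bp_jitter_sd)
  sub_seeds <- (config$seed + 7919L * seq_len(n_records)) %% 2147483647L
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    cfg_r <- config
    cfg_r$hr_bpm <- max(35, config$hr_bpm + hr_jit[r])
    # keep the coupling law fixed across records: jitter enters as an
    # intercept shift, not a re-derivation from the jittered HR
    cfg_r$coupling_a <- config$coupling_a + bp_jit[r]
    cfg_r$seed <- as.integer(sub_seeds[r])
    sim <- simulate_record(cfg_r)
    sim$record$record_id <- sprintf("synth-%d-r%02d", config$seed, r)
    out[[r]] <- list(record = sim$record, truth = sim$truth, config = cfg_r)
  }
  out
}

#' Ground-truth per-frame labels by brute-force extrema scan
#'
#' Independent oracle for label extraction: scans each fixed-length frame of
#' the rendered ABP channel for strict local maxima/minima (simple
#' sign-change test, no prominence or refractory logic) and averages their
#' amplitudes. On noise-free synthetic ABP these equal the per-beat
#' SBP/DBP values stored in the ground truth.
#'
#' @param abp numeric ABP sample vector.
#' @param frame_len frame length in samples (default 128).
#' @return data frame with one row per complete frame: `frame_index`
#'   (0-based), `sbp`, `dbp`, `n_peaks`, `n_troughs`, `valid`.
#' @export
frame_truth <- function(abp, frame_len = 128L) {
  nf <- floor(length(abp) / frame_len)
  out <- data.frame(frame_index = seq_len(nf) - 1L, sbp = NA_real_,
                    dbp = NA_real_, n_peaks = 0L, n_troughs = 0L,
                    valid = FALSE)
  for (f in seq_len(nf)) {
    x <- abp[((f - 1L) * frame_len + 1L):(f * frame_len)]
    d <- diff(x)
    pk <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
    tr <- which(d[-length(d)] < 0 & d[-1] > 0) + 1L
    out$n_peaks[f] <- length(pk)
    out$n_troughs[f] <- length(tr)
    if (length(pk) && length(tr)) {
      out$sbp[f] <- mean(x[pk])
      out$dbp[f] <- mean(x[tr])
      out$valid[f] <- out$sbp[f] > out$dbp[f]
    }
  }
  out
}
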