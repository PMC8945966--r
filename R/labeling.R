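strict_local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  list(max = which(d[-(n - 1L)] > 0 & d[-1L] < 0) + 1L,
       min = which(d[-(n - 1L)] < 0 & d[-1L] > 0) + 1L)
}

# keep the most extreme candidate within each refractory window
enforce_refractory <- function(idx, values, min_dist, take_max) {
  if (length(idx) < 2L) return(idx)
  keep <- idx[1L]
  out <- integer(0)
  best <- values[1L]
  for (i in 2L:length(idx)) {
    if (idx[i] - keep < min_dist) {
      better <- if (take_max) values[i] > best else values[i] < best
      if (better) { keep <- idx[i]; best <- values[i] }
    } else {
      out <- c(out, keep)
      keep <- idx[i]
      best <- values[i]
    }
  }
  c(out, keep)
}

#' Locate systolic peaks and diastolic troughs in an ABP signal
#'
#' Strict local maxima/minima are screened by a prominence floor (a
#' fraction of the signal's dynamic range), a refractory distance between
#' same-kind extrema, and finally forced to alternate (between two
#' consecutive peaks only the deepest trough survives, and vice versa). A
#' flat signal has no dynamic range and returns the degenerate flag with
#' empty annotations.
#'
#' @param abp numeric ABP sample vector (typically one frame or record).
#' @param fs sampling rate in Hz.
#' @param refractory_s minimum separation of same-kind extrema in seconds
#'   (default 0.3, below any plausible cardiac cycle).
#' @param prominence_frac prominence floor as a fraction of the signal's
#'   dynamic range (default 0.1).
#' @return list with `peaks` and `troughs` ([beat_annotation()] objects,
#'   0-based indices) and `degenerate` flag.
#' @export
find_abp_extrema <- function(abp, fs, refractory_s = 0.3,
                             prominence_frac = 0.1) {
  rng <- diff(range(abp))
  empty <- list(peaks = beat_annotation(integer(0), "abp_peak"),
                troughs = beat_annotation(integer(0), "abp_trough"),
                degenerate = TRUE)
  if (!is.finite(rng) || rng <= 0) return(empty)
  ex <- strict_local_extrema(abp)
  pk <- ex$max; tr <- ex$min
  if (!length(pk) && !length(tr)) return(empty)
  floor_abs <- prominence_frac * rng

  # prominence of a peak: height above the higher of the two flanking
  # minima taken to the neighbouring peaks (signal ends count as flanks)
  prominence <- function(cand, others, sig, peak = TRUE) {
    s <- if (peak) sig else -sig
    vapply(seq_along(cand), function(i) {
      ci <- cand[i]
      left <- if (i > 1L) cand[i - 1L] else 1L
      right <- if (i < length(cand)) cand[i + 1L] else length(s)
      base <- max(min(s[left:ci]), min(s[ci:right]))
      s[ci] - base
    }, numeric(1))
  }
  if (length(pk)) pk <- pk[prominence(pk, NULL, abp, TRUE) >= floor_abs]
  if (length(tr)) tr <- tr[prominence(tr, NULL, abp, FALSE) >= floor_abs]
  min_dist <- round(refractory_s * fs)
  pk <- enforce_refractory(pk, abp[pk], min_dist, take_max = TRUE)
  tr <- enforce_refractory(tr, abp[tr], min_dist, take_max = FALSE)

  # alternation: among same-kind runs keep the single most extreme point
  if (length(pk) && length(tr)) {
    all_idx <- c(pk, tr)
    kind <- rep(c(1L, 2L), c(length(pk), length(tr)))
    o <- order(all_idx)
    all_idx <- all_idx[o]; kind <- kind[o]
    keep <- rep(TRUE, length(all_idx))
    i <- 1L
    while (i <= length(all_idx)) {
      j <- i
      while (j < length(all_idx) && kind[j + 1L] == kind[i]) j <- j + 1L
      if (j > i) {
        run <- i:j
        v <- abp[all_idx[run]]
        best <- if (kind[i] == 1L) run[which.max(v)] else run[which.min(v)]
        keep[setdiff(run, best)] <- FALSE
      }
      i <- j + 1L
    }
    pk <- all_idx[keep & kind == 1L]
    tr <- all_idx[keep & kind == 2L]
  }
  list(peaks = beat_annotation(pk - 1L, "abp_peak"),
       troughs = beat_annotation(tr - 1L, "abp_trough"),
       degenerate = length(pk) == 0L && length(tr) == 0L)
}

#' Label one frame with its mean systolic/diastolic pressure
#'
#' SBP is the mean amplitude of the systolic peaks found in the frame's ABP
#' samples, DBP the mean amplitude of the diastolic troughs. A frame is
#' valid only if it contains at least one peak and one trough, SBP exceeds
#' DBP, and both lie within the configured physiological bounds; invalid
#' frames are excluded from training.
#'
#' @param abp_frame numeric ABP samples of one frame.
#' @param fs sampling rate in Hz.
#' @param sbp_max,dbp_min plausibility bounds in mmHg (defaults 250 and 20).
#' @param ... passed to [find_abp_extrema()].
#' @return list of class `bp_label`: `sbp`, `dbp`, `n_peaks`, `n_troughs`,
#'   `valid`.
#' @export
label_frame <- function(abp_frame, fs, sbp_max = 250, dbp_min = 20, ...) {
  if (is.null(abp_frame)) stop("frame has no ABP samples to label",
                               call. = FALSE)
  ex <- find_abp_extrema(abp_frame, fs, ...)
  np <- length(ex$peaks$indices)
  nt <- length(ex$troughs$indices)
  sbp <- if (np) mean(abp_frame[ex$peaks$indices + 1L]) else NA_real_
  dbp <- if (nt) mean(abp_frame[ex$troughs$indices + 1L]) else NA_real_
  valid <- np >= 1L && nt >= 1L && is.finite(sbp) && is.finite(dbp) &&
    sbp > dbp && sbp <= sbp_max && dbp >= dbp_min
  structure(list(sbp = sbp, dbp = dbp, n_peaks = np, n_troughs = nt,
                 valid = valid), class = "bp_label")
}

#' Label every frame of a frame set
#'
#' Applies [label_frame()] to each ABP frame and attaches the result as the
#' `labels` data frame of the frame set (columns `sbp`, `dbp`, `n_peaks`,
#' `n_troughs`, `valid`).
#'
#' @param frames a `frame_set` with an ABP matrix.
#' @param ... passed to [label_frame()].
#' @return the frame set with `$labels` attached.
#' @export
label_frames <- function(frames, ...) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(frames$abp)) stop("frame set has no ABP channel to label",
                                call. = FALSE)
  n <- n_frames(frames)
  labs <- vector("list", n)
  for (i in seq_len(n)) {
    labs[[i]] <- label_frame(frames$abp[i, ], frames$fs, ...)
  }
  frames$labels <- data.frame(
    sbp = vapply(labs, `[[`, numeric(1), "sbp"),
    dbp = vapply(labs, `[[`, numeric(1), "dbp"),
    n_peaks = vapply(labs, `[[`, integer(1), "n_peaks"),
    n_troughs = vapply(labs, `[[`, integer(1), "n_troughs"),
    valid = vapply(labs, `[[`, logical(1), "valid")
  )
  frames
}

#' Detect QRS complexes (R peaks) in a conditioned ECG
#'
#' Classic energy-transform detector: differentiate, square, integrate over
#' a moving window, then pick integration-wave peaks with an adaptive
#' signal/noise threshold and a refractory period. Each detection is
#' refined to the local ECG maximum in a short window around it, so
#' reported indices land on R peaks.
#'
#' @param ecg numeric conditioned ECG vector (after [preprocess_record()]'s
#'   filter chain, or any reasonably clean ECG).
#' @param fs sampling rate in Hz.
#' @param refractory_s minimum RR interval honoured by the detector
#'   (default 0.25 s).
#' @param mwi_s moving-window-integration width in seconds (default 0.15).
#' @return a [beat_annotation()] of kind `r_peak` (0-based indices); empty,
#'   with a warning, if no beats are found.
#' @export
detect_qrs <- function(ecg, fs, refractory_s = 0.25, mwi_s = 0.15) {
  n <- length(ecg)
  if (n < fs) {
    warning("signal shorter than one second; no beats detected")
    return(beat_annotation(integer(0), "r_peak"))
  }
  # QRS-band bandpass concentrates energy where the QRS lives and rejects
  # broadband noise, P/T waves and residual drift before the energy
  # transform
  bp <- signal::butter(3, pmin(c(5, 15) / (fs / 2), 0.95), type = "pass")
  xb <- filtfilt_padded(bp, ecg)
  d <- c(0, diff(xb))
  sq <- d^2
  w <- max(1L, round(mwi_s * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  ex <- strict_local_extrema(mwi)
  cand <- ex$max
  if (!length(cand)) {
    warning("no beats found")
    return(beat_annotation(integer(0), "r_peak"))
  }
  min_dist <- round(refractory_s * fs)
  cand <- enforce_refractory(cand, mwi[cand], min_dist, take_max = TRUE)

  # adaptive signal/noise threshold, seeded from the first two seconds
  init <- mwi[seq_len(min(n, 2L * round(fs)))]
  spki <- max(init)
  npki <- mean(init)
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  for (ci in cand) {
    p <- mwi[ci]
    if (p >= thr) {
      peaks <- c(peaks, ci)
      spki <- 0.125 * p + 0.875 * spki
    } else {
      npki <- 0.125 * p + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (!length(peaks)) {
    warning("no beats found")
    return(beat_annotation(integer(0), "r_peak"))
  }
  # energy post-filter: QRS integration peaks cluster far above noise and
  # T-wave bumps that slip past the running threshold
  if (length(peaks) >= 3L) {
    peaks <- peaks[mwi[peaks] >= 0.15 * stats::median(mwi[peaks])]
  }
  # refine to the ECG maximum near each integration peak (the MWI peak lags
  # the R wave by roughly half the window)
  half <- as.integer(round(0.10 * fs)) + w %/% 2L
  r <- vapply(peaks, function(ci) {
    lo <- max(1L, ci - half)
    hi <- min(n, ci + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  r <- sort(unique(r))
  r <- enforce_refractory(r, ecg[r], min_dist, take_max = TRUE)
  # amplitude post-filter: T waves and noise bumps that slip past the
  # energy threshold sit well below the R-wave amplitude of the record
  if (length(r) >= 3L) {
    amp <- ecg[r] - stats::median(ecg)
    r <- r[amp >= 0.4 * stats::median(amp)]
  }
  beat_annotation(r - 1L, "r_peak", n_total = n)
}

#' RR intervals and heart rate from a beat annotation
#'
#' @param annotation a [beat_annotation()] with at least two R peaks.
#' @param fs sampling rate in Hz.
#' @return list of class `rhythm_summary`: `r_peaks` (the annotation),
#'   `rr_s` (successive R-R intervals, seconds), `hr_bpm` (instantaneous
#'   heart rate, `60 / rr_s`), `mean_hr_bpm`.
#' @export
rhythm_summary <- function(annotation, fs) {
  stopifnot(inherits(annotation, "beat_annotation"))
  if (length(annotation$indices) < 2L) {
    stop("need at least 2 R peaks for RR intervals", call. = FALSE)
  }
  rr <- diff(annotation$indices) / fs
  hr <- 60 / rr
  structure(list(r_peaks = annotation, rr_s = rr, hr_bpm = hr,
                 mean_hr_bpm = mean(hr)), class = "rhythm_summary")
}

#' @export
print.rhythm_summary <- function(x, ...) {
  cat(sprintf("<rhythm_summary> %d beats, mean HR %.1f bpm, RR %.3f +- %.3f s\n",
              length(x$r_peaks$indices), x$mean_hr_bpm, mean(x$rr_s),
              stats::sd(x$rr_s)))
  invisible(x)
}
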