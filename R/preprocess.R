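#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), so the effective magnitude response is the squared
#' design response and the phase response is zero — R-peak timing is not
#' shifted. The default 50 Hz cut-off removes power-line and other
#' high-frequency interference from ECG sampled at 125 Hz.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz; must exceed `2 * cutoff`.
#' @param cutoff cut-off frequency in Hz (default 50).
#' @param order Butterworth design order (default 4).
#' @return filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 50, order = 4) {
  if (fs <= 2 * cutoff) {
    stop("fs must exceed 2 * cutoff (got fs = ", fs, ", cutoff = ", cutoff,
         ")", call. = FALSE)
  }
  minlen <- 3L * (2L * order + 1L)
  if (length(x) < minlen) {
    stop("signal too short to filter (need >= ", minlen, " samples)",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_padded(bf, x)
}

# forward-backward filtering with odd-symmetric reflection padding at both
# ends, so edge transients stay outside the returned samples
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  # generous pad: IIR edge transients decay below double precision well
  # within 150 samples for the filter orders used here
  pl <- min(n - 1L, 150L)
  head_pad <- 2 * x[1] - x[(pl + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pl)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(pl + 1L):(pl + n)])
}

#' Remove baseline wander by wavelet decomposition
#'
#' Performs a multilevel Daubechies-4 decomposition deep enough that the
#' approximation band lies below `max_drift_hz` (approximation band edge is
#' `fs / 2^(levels + 1)`), zeroes the approximation coefficients, and
#' reconstructs. Sub-`max_drift_hz` drift — respiration and electrode
#' motion — is suppressed while the QRS band passes essentially unchanged;
#' a constant offset is removed entirely. The signal is symmetrically
#' padded to a multiple of `2^levels` before the periodised transform and
#' cropped after reconstruction.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param max_drift_hz upper edge of the drift band to remove (default
#'   0.5 Hz; at 125 Hz this selects 7 decomposition levels, band edge
#'   0.49 Hz).
#' @return baseline-corrected vector, same length as `x`.
#' @export
remove_baseline_wavelet <- function(x, fs, max_drift_hz = 0.5) {
  levels <- ceiling(log2(fs / max_drift_hz)) - 1L
  levels <- max(levels, 1L)
  block <- 2L^levels
  if (length(x) < block) {
    stop("signal too short for ", levels, "-level decomposition (need >= ",
         block, " samples)", call. = FALSE)
  }
  n <- length(x)
  m <- as.integer(ceiling(n / block) * block)
  pad <- m - n
  # symmetric (reflect) padding split across both ends softens edge effects
  pl <- pad %/% 2L
  pr <- pad - pl
  xe <- c(if (pl > 0) x[pl:1] else numeric(0), x,
          if (pr > 0) x[n:(n - pr + 1L)] else numeric(0))
  dec <- dwt_multilevel(xe, levels)
  dec$a[] <- 0
  ye <- idwt_multilevel(dec)
  ye[(pl + 1L):(pl + n)]
}

#' Segment aligned ECG/ABP signals into fixed-length frames
#'
#' Non-overlapping tiling: frame `i` (0-based) covers samples
#' `[i * frame_len, (i + 1) * frame_len)`. A trailing remainder shorter
#' than `frame_len` is discarded. ECG and ABP frames share start samples.
#'
#' @param ecg numeric ECG sample vector.
#' @param abp optional ABP vector of identical length, or `NULL` at
#'   inference time.
#' @param frame_len frame length in samples (default 128).
#' @param record_id label carried into the frame set.
#' @param fs sampling rate carried into the frame set.
#' @return an object of class `frame_set`: list with `ecg` (matrix, one row
#'   per frame), `abp` (matrix or `NULL`), `frame_index` (0-based),
#'   `start_sample` (0-based), `frame_len`, `fs`, `record_id` (one per
#'   frame). Zero frames yields matrices with zero rows (with a warning).
#' @export
segment_pair <- function(ecg, abp = NULL, frame_len = 128L,
                         record_id = "record", fs = NA_real_) {
  frame_len <- as.integer(frame_len)
  if (!is.null(abp) && length(abp) != length(ecg)) {
    stop("ecg and abp must have equal length (", length(ecg), " vs ",
         length(abp), ")", call. = FALSE)
  }
  nf <- floor(length(ecg) / frame_len)
  if (nf == 0L) warning("signal shorter than one frame; returning 0 frames")
  used <- nf * frame_len
  ecg_m <- if (nf > 0L) {
    matrix(ecg[seq_len(used)], nrow = nf, ncol = frame_len, byrow = TRUE)
  } else matrix(numeric(0), nrow = 0L, ncol = frame_len)
  abp_m <- if (!is.null(abp)) {
    if (nf > 0L) matrix(abp[seq_len(used)], nrow = nf, ncol = frame_len,
                        byrow = TRUE)
    else matrix(numeric(0), nrow = 0L, ncol = frame_len)
  } else NULL
  structure(list(
    ecg = ecg_m, abp = abp_m,
    frame_index = seq_len(nf) - 1L,
    start_sample = (seq_len(nf) - 1L) * frame_len,
    frame_len = frame_len, fs = fs,
    record_id = rep(record_id, nf)
  ), class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames x %d samples (%s ABP, %s labels)\n",
              nrow(x$ecg), x$frame_len,
              if (is.null(x$abp)) "no" else "with",
              if (is.null(x$labels)) "no" else "with"))
  invisible(x)
}

#' Number of frames in a frame set
#' @param frames a `frame_set`.
#' @return frame count.
#' @export
n_frames <- function(frames) nrow(frames$ecg)

#' Subset a frame set by row
#' @param frames a `frame_set`.
#' @param idx integer row indices (1-based).
#' @return the subsetted `frame_set` (labels subsetted too, if present).
#' @export
subset_frames <- function(frames, idx) {
  stopifnot(inherits(frames, "frame_set"))
  out <- frames
  out$ecg <- frames$ecg[idx, , drop = FALSE]
  if (!is.null(frames$abp)) out$abp <- frames$abp[idx, , drop = FALSE]
  out$frame_index <- frames$frame_index[idx]
  out$start_sample <- frames$start_sample[idx]
  out$record_id <- frames$record_id[idx]
  if (!is.null(frames$labels)) out$labels <- frames$labels[idx, , drop = FALSE]
  out
}

#' Concatenate frame sets from multiple records
#' @param ... `frame_set` objects with identical `frame_len` and `fs`.
#' @return a single `frame_set`.
#' @export
bind_frames <- function(...) {
  fs_list <- list(...)
  if (length(fs_list) == 1L && !inherits(fs_list[[1]], "frame_set")) {
    fs_list <- fs_list[[1]]
  }
  stopifnot(all(vapply(fs_list, inherits, logical(1), "frame_set")))
  fl <- unique(vapply(fs_list, function(f) f$frame_len, integer(1)))
  stopifnot(length(fl) == 1L)
  out <- fs_list[[1]]
  out$ecg <- do.call(rbind, lapply(fs_list, `[[`, "ecg"))
  abps <- lapply(fs_list, `[[`, "abp")
  out$abp <- if (any(vapply(abps, is.null, logical(1)))) NULL
             else do.call(rbind, abps)
  out$frame_index <- unlist(lapply(fs_list, `[[`, "frame_index"))
  out$start_sample <- unlist(lapply(fs_list, `[[`, "start_sample"))
  out$record_id <- unlist(lapply(fs_list, `[[`, "record_id"))
  labs <- lapply(fs_list, `[[`, "labels")
  if (all(!vapply(labs, is.null, logical(1)))) {
    out$labels <- do.call(rbind, labs)
  } else out$labels <- NULL
  out
}

#' Condition and segment a paired record
#'
#' The full preprocessing chain: the ECG channel is low-pass filtered
#' ([lowpass_filter()]) and baseline-corrected
#' ([remove_baseline_wavelet()]); the ABP channel, when present, passes
#' through unfiltered by default so that its extrema — the label source —
#' are not attenuated. Both channels are then segmented into aligned
#' non-overlapping frames.
#'
#' @param record a [waveform_record()] with an `ecg` channel and optionally
#'   an `abp` channel.
#' @param cutoff low-pass cut-off in Hz.
#' @param baseline logical: apply wavelet baseline removal to the ECG.
#' @param filter_abp logical: also low-pass filter the ABP channel
#'   (default `FALSE`).
#' @param frame_len frame length in samples.
#' @return a `frame_set`; `abp` is `NULL` when the record has no ABP
#'   channel (inference-time use).
#' @export
preprocess_record <- function(record, cutoff = 50, baseline = TRUE,
                              filter_abp = FALSE, frame_len = 128L) {
  stopifnot(inherits(record, "waveform_record"))
  if (!("ecg" %in% names(record$channels))) {
    stop("record has no 'ecg' channel (channels: ",
         paste(names(record$channels), collapse = ", "), ")", call. = FALSE)
  }
  ecg <- lowpass_filter(record$channels$ecg, record$fs, cutoff = cutoff)
  if (baseline) ecg <- remove_baseline_wavelet(ecg, record$fs)
  abp <- record$channels$abp
  if (!is.null(abp) && filter_abp) {
    abp <- lowpass_filter(abp, record$fs, cutoff = cutoff)
  }
  segment_pair(ecg, abp, frame_len = frame_len,
               record_id = record$record_id, fs = record$fs)
}
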