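#' Construct a sampled multichannel waveform record
#'
#' A `waveform_record` is the basic container the whole package operates on:
#' one or more named, uniformly sampled channels sharing a sampling rate.
#' Typical use holds an ECG channel (mV) and a simultaneous arterial
#' blood-pressure channel (mmHg) acquired at the same rate.
#'
#' Sample indexing is 0-based throughout the package and time intervals are
#' half-open `[start, end)`, so a record of `n` samples at rate `fs` spans
#' `[t0, t0 + n/fs)` seconds.
#'
#' @param channels named list of equal-length finite numeric vectors, e.g.
#'   `list(ecg = ..., abp = ...)`.
#' @param fs sampling rate in Hz (> 0).
#' @param record_id character label for the record.
#' @param units named character vector mapping channel names to unit strings
#'   (e.g. `c(ecg = "mV", abp = "mmHg")`). Missing channels default to `""`.
#' @param t0 start offset of the first sample, in seconds.
#'
#' @return an object of class `waveform_record` with fields `record_id`,
#'   `fs`, `channels`, `units`, `t0`.
#' @export
waveform_record <- function(channels, fs, record_id = "record",
                            units = NULL, t0 = 0) {
  if (!is.list(channels) || length(channels) < 1L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of numeric vectors",
         call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (any(lens == 0L)) stop("channels must be non-empty", call. = FALSE)
  if (length(unique(lens)) != 1L) {
    stop("all channels must have identical length (got ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch)) stop("channel '", nm, "' is not numeric", call. = FALSE)
    if (any(!is.finite(ch))) {
      stop("channel '", nm, "' contains non-finite samples", call. = FALSE)
    }
    channels[[nm]] <- as.double(ch)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  u <- setNames(rep("", length(channels)), names(channels))
  if (!is.null(units)) {
    known <- intersect(names(units), names(channels))
    u[known] <- unname(units[known])
  }
  structure(
    list(record_id = as.character(record_id), fs = as.double(fs),
         channels = channels, units = u, t0 = as.double(t0)),
    class = "waveform_record"
  )
}

#' Number of samples per channel of a record
#' @param record a `waveform_record`.
#' @return integer sample count.
#' @export
n_samples <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  length(record$channels[[1L]])
}

#' Record duration in seconds
#' @param record a `waveform_record`.
#' @return duration `n_samples / fs` in seconds.
#' @export
record_duration <- function(record) n_samples(record) / record$fs

#' @export
print.waveform_record <- function(x, ...) {
  cat("<waveform_record> ", x$record_id, "\n", sep = "")
  cat(sprintf("  fs: %g Hz, %d samples, %.3f s (t0 = %g s)\n",
              x$fs, n_samples(x), record_duration(x), x$t0))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %s [%s]: range %.4g .. %.4g\n", nm, x$units[[nm]],
                min(ch), max(ch)))
  }
  invisible(x)
}

#' Extract a time slice of a record
#'
#' Returns the samples falling in the half-open interval
#' `[start_s, end_s)` measured from the start of the record (not from
#' `t0`). All channels are sliced identically and `t0` is advanced so the
#' absolute time of each remaining sample is unchanged.
#'
#' @param record a `waveform_record`.
#' @param start_s,end_s slice bounds in seconds; `0 <= start_s < end_s <=
#'   duration`.
#' @return a `waveform_record` covering the requested interval.
#' @export
slice_record <- function(record, start_s, end_s) {
  stopifnot(inherits(record, "waveform_record"))
  dur <- record_duration(record)
  if (!is.finite(start_s) || !is.finite(end_s) ||
      start_s < 0 || end_s > dur + 1e-9 || start_s >= end_s) {
    stop(sprintf("invalid slice [%g, %g) for record of duration %g s",
                 start_s, end_s, dur), call. = FALSE)
  }
  # half-open: first sample at index ceil(start_s*fs), last before end_s*fs
  i0 <- as.integer(ceiling(start_s * record$fs - 1e-9))
  i1 <- as.integer(ceiling(end_s * record$fs - 1e-9)) - 1L
  idx <- seq.int(i0 + 1L, i1 + 1L)
  waveform_record(
    channels = lapply(record$channels, function(ch) ch[idx]),
    fs = record$fs, record_id = record$record_id, units = record$units,
    t0 = record$t0 + i0 / record$fs
  )
}

#' Beat annotation: fiducial sample indices
#'
#' Holds sorted 0-based sample indices of detected fiducial points:
#' ECG R-peaks, ABP systolic peaks, or ABP diastolic troughs.
#'
#' @param indices integer vector of 0-based sample indices, strictly
#'   increasing.
#' @param kind one of `"r_peak"`, `"abp_peak"`, `"abp_trough"`.
#' @param n_total total number of samples in the annotated signal (used to
#'   bound-check indices); optional.
#' @return an object of class `beat_annotation`.
#' @export
beat_annotation <- function(indices, kind = c("r_peak", "abp_peak", "abp_trough"),
                            n_total = NULL) {
  kind <- match.arg(kind)
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    stop("annotation indices must be strictly increasing", call. = FALSE)
  }
  if (any(indices < 0L)) stop("annotation indices must be >= 0", call. = FALSE)
  if (!is.null(n_total) && length(indices) && max(indices) >= n_total) {
    stop("annotation index beyond end of signal", call. = FALSE)
  }
  structure(list(indices = indices, kind = kind), class = "beat_annotation")
}

#' @export
print.beat_annotation <- function(x, ...) {
  cat(sprintf("<beat_annotation> %s: %d points\n", x$kind, length(x$indices)))
  invisible(x)
}
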