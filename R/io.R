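#' Read a waveform record from disk
#'
#' Two on-disk formats are supported:
#'
#' * `"csv"`: comma-separated samples, one column per channel with a header
#'   row of channel names, preceded by commented metadata lines
#'   (`# key: value`) carrying `record_id`, `fs`, `t0` and per-channel
#'   units. This is the package's native, diff-friendly text format,
#'   written by [write_record()].
#' * `"wfdb"`: a minimal subset of the WFDB format used by MIMIC-style
#'   records — a text header `<record>.hea` plus a 16-bit little-endian
#'   interleaved signal file `<record>.dat` (format 16 only). `path` is the
#'   header file or the record name without extension.
#'
#' @param path path to the record file (`.csv`, or `.hea`/record name for
#'   WFDB).
#' @param format `"csv"` or `"wfdb"`; default guesses from the extension.
#' @return a [waveform_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format, csv = read_record_csv(path), wfdb = read_record_wfdb(path))
}

#' Write a waveform record to disk
#'
#' The CSV writer stores full double precision (15 significant digits), so
#' a read/write round trip is lossless for practical purposes. The WFDB
#' writer quantizes each channel to 16-bit integers with an automatically
#' chosen per-channel gain; the quantization step (1/gain) bounds the
#' round-trip error and is recorded in the header.
#'
#' @param record a [waveform_record()].
#' @param path output path: a `.csv` file, or the `.hea` path / record name
#'   for WFDB.
#' @param format `"csv"` or `"wfdb"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "wfdb")) {
  stopifnot(inherits(record, "waveform_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format,
         csv = write_record_csv(record, path),
         wfdb = write_record_wfdb(record, path))
  invisible(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(record_id = sub("\\.csv$", "", basename(path)),
               fs = NA_real_, t0 = 0, units = character())
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-zA-Z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) next
    key <- m[2]; val <- trimws(m[3])
    if (key == "fs") meta$fs <- as.numeric(val)
    else if (key == "t0") meta$t0 <- as.numeric(val)
    else if (key == "record_id") meta$record_id <- val
    else if (key == "units") {
      pairs <- strsplit(strsplit(val, ",")[[1]], "=")
      u <- vapply(pairs, function(p) trimws(p[2]), character(1))
      names(u) <- vapply(pairs, function(p) trimws(p[1]), character(1))
      meta$units <- u
    }
  }
  if (!is.finite(meta$fs)) {
    stop("CSV record is missing a '# fs: <Hz>' metadata line: ", path,
         call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("CSV record has no samples: ", path, call. = FALSE)
  header <- strsplit(body[1], ",")[[1]]
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  ncell <- lengths(cells)
  if (any(ncell != length(header))) {
    stop("ragged CSV: rows with ", paste(unique(ncell[ncell != length(header)]),
         collapse = "/"), " fields but ", length(header),
         " channels declared", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (any(is.na(vals))) stop("non-numeric sample values in ", path, call. = FALSE)
  mat <- matrix(vals, ncol = length(header), byrow = TRUE)
  channels <- setNames(lapply(seq_along(header), function(j) mat[, j]),
                       trimws(header))
  waveform_record(channels, fs = meta$fs, record_id = meta$record_id,
                  units = meta$units, t0 = meta$t0)
}

write_record_csv <- function(record, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write ", path, call. = FALSE)
  on.exit(close(con))
  units_str <- paste(sprintf("%s=%s", names(record$units), record$units),
                     collapse = ", ")
  writeLines(c(
    "# ecg2bp waveform record v1",
    paste0("# record_id: ", record$record_id),
    paste0("# fs: ", format(record$fs, digits = 15)),
    paste0("# t0: ", format(record$t0, digits = 15)),
    paste0("# units: ", units_str),
    paste(names(record$channels), collapse = ",")
  ), con)
  mat <- vapply(record$channels, format, digits = 15, trim = TRUE,
                FUN.VALUE = character(n_samples(record)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  writeLines(apply(mat, 1L, paste, collapse = ","), con)
}

# Minimal WFDB subset: header line "name nsig fs nsamp"; one signal line per
# channel "file 16 gain(baseline)/units adcres adczero initval cksum bsize desc".
read_record_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("malformed WFDB header: ", hea, call. = FALSE)
  rec_name <- top[1]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (length(lines) < 1L + nsig) {
    stop("WFDB header declares ", nsig, " signals but has ",
         length(lines) - 1L, " signal lines", call. = FALSE)
  }
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (as.integer(sub("[^0-9].*$", "", f[2])) != 16L) {
      stop("only WFDB format 16 is supported", call. = FALSE)
    }
    spec <- f[3]  # gain(baseline)/units
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", spec))
    baseline <- if (grepl("\\(", spec)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", spec))
    } else 0
    units <- if (grepl("/", spec)) sub("^.*/", "", spec) else ""
    name <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = "_") else f[1]
    list(file = f[1], gain = gain, baseline = baseline, units = units,
         name = name)
  })
  dat <- file.path(dirname(hea), sig[[1]]$file)
  if (!file.exists(dat)) stop("file not found: ", dat, call. = FALSE)
  raw <- readBin(dat, integer(), n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp) {
    stop("WFDB signal file shorter than header declares", call. = FALSE)
  }
  mat <- matrix(as.double(raw), nrow = nsig)
  channels <- list(); units <- character()
  for (i in seq_len(nsig)) {
    s <- sig[[i]]
    channels[[s$name]] <- (mat[i, ] - s$baseline) / s$gain
    units[s$name] <- s$units
  }
  waveform_record(channels, fs = fs, record_id = rec_name, units = units)
}

write_record_wfdb <- function(record, path) {
  base <- sub("\\.hea$", "", path)
  rec_name <- basename(base)
  hea <- paste0(base, ".hea")
  dat_name <- paste0(rec_name, ".dat")
  n <- n_samples(record)
  nsig <- length(record$channels)
  # per-channel gain: map the channel's absolute range into +-30000 counts
  digital <- matrix(0L, nrow = nsig, ncol = n)
  sig_lines <- character(nsig)
  for (i in seq_len(nsig)) {
    nm <- names(record$channels)[i]
    ch <- record$channels[[i]]
    span <- max(abs(ch), 1e-12)
    gain <- 30000 / span
    gain <- signif(gain, 6)
    digital[i, ] <- as.integer(round(ch * gain))
    sig_lines[i] <- sprintf("%s 16 %g(0)/%s 16 0 %d 0 0 %s",
                            dat_name, gain, record$units[[nm]],
                            digital[i, 1], nm)
  }
  con <- try(file(hea, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write ", hea, call. = FALSE)
  writeLines(c(sprintf("%s %d %s %d", rec_name, nsig,
                       format(record$fs, digits = 15), n), sig_lines), con)
  close(con)
  writeBin(as.integer(digital), file.path(dirname(hea), dat_name),
           size = 2L, endian = "little")
}
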