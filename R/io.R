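# Plain-text multichannel EEG records and the 35 Hz preprocessing chain.
#
# File dialect: line 1 is "# fs=<Hz> channels=<n>", the body is a numeric
# matrix with samples as rows and channels as columns, whitespace- or
# comma-delimited.

#' Construct an EEG record
#'
#' An `eeg_record` holds a channels-by-samples voltage matrix (microvolts)
#' together with its sampling rate. Total duration is `T = samples / fs`.
#'
#' @param data Numeric matrix, channels x samples, all values finite.
#' @param fs Sampling rate in Hz, positive.
#' @param subject_id,trial_id Optional labels carried through the pipeline.
#' @return An object of class `eeg_record` with elements `data`, `fs`,
#'   `subject_id`, `trial_id` and duration `T` (seconds).
#' @examples
#' rec <- eeg_record(matrix(rnorm(512), nrow = 2), fs = 256)
#' rec$T
#' @export
eeg_record <- function(data, fs, subject_id = NA_character_,
                       trial_id = NA_character_) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix (channels x samples)", call. = FALSE)
  if (ncol(data) < 2L)
    stop("an EEG record needs at least 2 samples per channel", call. = FALSE)
  if (!all(is.finite(data)))
    stop("EEG voltages must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0)
    stop("'fs' must be a single positive sampling rate in Hz", call. = FALSE)
  structure(
    list(data = data, fs = as.numeric(fs), subject_id = subject_id,
         trial_id = trial_id, T = ncol(data) / fs),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s) x %d samples @ %g Hz (%.4g s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$T))
  invisible(x)
}

is_eeg_record <- function(x) inherits(x, "eeg_record")

assert_record <- function(record) {
  if (!is_eeg_record(record))
    stop("expected an 'eeg_record' object", call. = FALSE)
  invisible(record)
}

#' Read a plain-text EEG record
#'
#' Parses the package's text dialect: a header line `# fs=<Hz> channels=<n>`
#' followed by a numeric body with one row per sample and one column per
#' channel (whitespace- or comma-delimited).
#'
#' @param path Path to an existing text file.
#' @return An [eeg_record()].
#' @seealso [write_eeg_text()] for the inverse.
#' @export
read_eeg_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("format error in ", path, ": need a header line and at least one row",
         call. = FALSE)
  hdr <- lines[[1L]]
  m <- regmatches(hdr, regexec("^#\\s*fs=([0-9.eE+-]+)\\s+channels=([0-9]+)", hdr))[[1L]]
  if (length(m) != 3L)
    stop("format error in ", path,
         " at line 1: expected header '# fs=<Hz> channels=<n>'", call. = FALSE)
  fs <- as.numeric(m[[2L]])
  n_ch <- as.integer(m[[3L]])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  widths <- lengths(fields)
  if (any(widths != n_ch)) {
    bad <- which(widths != n_ch)[[1L]]
    stop(sprintf("format error in %s at line %d: expected %d values, found %d",
                 path, bad + 1L, n_ch, widths[[bad]]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- which(vapply(fields, function(f)
      anyNA(suppressWarnings(as.numeric(f))), logical(1L)))[[1L]]
    stop(sprintf("format error in %s at line %d: non-numeric value",
                 path, bad_row + 1L), call. = FALSE)
  }
  # each text row is one sample across channels; column-major fill by sample
  # yields the channels x samples orientation directly
  eeg_record(matrix(vals, nrow = n_ch), fs = fs)
}

#' Write a plain-text EEG record
#'
#' Emits the dialect [read_eeg_text()] accepts; values are written with 12
#' significant digits so a read/write round trip is an identity within text
#' rounding.
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_text <- function(record, path) {
  assert_record(record)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(sprintf("# fs=%.12g channels=%d", record$fs, nrow(record$data)), con)
  body <- apply(t(record$data), 1L, function(row)
    paste(formatC(row, digits = 12, format = "g"), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

# forward-backward IIR filtering with odd-reflection edge padding, so DC is
# passed exactly and edge transients do not leak into the record
filt_zerophase <- function(bf, x) {
  n <- length(x)
  # pad long enough for the slowest filter pole to ring down below 1e-10
  pad <- min(n - 1L, 12L * (2L * (length(bf$b) - 1L) + 1L))
  xe <- c(2 * x[[1L]] - x[(pad + 1L):2], x,
          2 * x[[n]] - x[(n - 1L):(n - pad)])
  y <- rev(as.numeric(signal::filter(bf, xe)))
  y <- rev(as.numeric(signal::filter(bf, y)))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter and decimate an EEG record
#'
#' Reproduces the study preprocessing: a zero-phase Butterworth low-pass at
#' `cutoff` (forward-backward filtering, so detection timestamps are not
#' biased by filter delay) followed by uniform resampling to `target_fs`.
#' A 180 s record at 256 Hz becomes exactly 6300 samples at 35 Hz.
#'
#' @param record An [eeg_record()] with `fs >= 2 * cutoff`.
#' @param cutoff Low-pass corner frequency in Hz.
#' @param target_fs Output sampling rate in Hz, `<= record$fs`.
#' @param order Butterworth order (applied twice by the zero-phase filter).
#' @return A new [eeg_record()] at `target_fs` with
#'   `round(record$T * target_fs)` samples and unit DC gain.
#' @export
lowpass_decimate <- function(record, cutoff = 35, target_fs = 35, order = 4) {
  assert_record(record)
  if (target_fs > record$fs)
    stop("'target_fs' (", target_fs, ") exceeds the record sampling rate (",
         record$fs, ")", call. = FALSE)
  if (record$fs < 2 * cutoff)
    stop("record sampling rate must be at least twice the cutoff", call. = FALSE)
  filtered <- if (cutoff < record$fs / 2) {
    bf <- signal::butter(order, cutoff / (record$fs / 2), type = "low")
    t(apply(record$data, 1L, function(x) filt_zerophase(bf, x)))
  } else {
    record$data
  }
  if (target_fs == record$fs) {
    out <- filtered
  } else {
    n_out <- round(record$T * target_fs)
    t_in <- (seq_len(ncol(filtered)) - 1L) / record$fs
    t_out <- (seq_len(n_out) - 1L) / target_fs
    out <- t(apply(filtered, 1L, function(x)
      stats::approx(t_in, x, xout = t_out, rule = 2)$y))
  }
  eeg_record(out, fs = target_fs, subject_id = record$subject_id,
             trial_id = record$trial_id)
}

#' Select the dominant channel of a record
#'
#' The analysis channel is the electrode with the biggest fluctuations.
#' By default this is operationalised as the largest peak-to-peak amplitude;
#' `method = "var"` uses variance instead. Ties go to the lowest index.
#'
#' @param record An [eeg_record()].
#' @param method `"p2p"` (peak-to-peak, default) or `"var"`.
#' @return Integer channel index (1-based).
#' @export
select_dominant_channel <- function(record, method = c("p2p", "var")) {
  assert_record(record)
  method <- match.arg(method)
  score <- switch(method,
    p2p = apply(record$data, 1L, function(x) diff(range(x))),
    var = apply(record$data, 1L, stats::var))
  which.max(score) # which.max already breaks ties by lowest index
}

#' Average EEG records across trials
#'
#' Element-wise arithmetic mean of identically shaped records (the grand
#' average across a subject's artifact-free trials).
#'
#' @param records List of [eeg_record()] objects with equal `fs`, channel
#'   count and sample count.
#' @return The mean [eeg_record()].
#' @export
average_trials <- function(records) {
  if (!is.list(records) || length(records) < 1L)
    stop("'records' must be a non-empty list of eeg_record objects", call. = FALSE)
  lapply(records, assert_record)
  ref <- records[[1L]]
  for (r in records[-1L]) {
    if (!identical(dim(r$data), dim(ref$data)) || r$fs != ref$fs)
      stop("alignment error: records differ in shape or sampling rate",
           call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(records, `[[`, "data")) / length(records)
  eeg_record(acc, fs = ref$fs, subject_id = ref$subject_id)
}
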