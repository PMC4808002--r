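# Synthetic seizure records and cohorts.
#
# The generator emulates the study design: 3-minute, 24-channel records at
# 256 Hz with a pre-seizure segment of strongly persistent activity, an
# internal-stimulus precursor that drops the Hurst exponent 19-35 s before
# onset, an ictal amplitude burst on one dominant electrode, and recovery
# after the seizure ends. Every record carries full ground truth, so the
# downstream estimators and detectors are testable without clinical data.

#' Specification of a synthetic seizure record
#'
#' Defaults encode the reference scenario: 180 s at 256 Hz, 24 channels,
#' baseline Hurst 0.9 dropping to 0.3 at the precursor (t = 50 s), seizure
#' onset at t = 80 s and end at t = 160 s, a 50 uV baseline peak scale and an
#' ictal burst sized so the dominant-channel voltage spans roughly -769 to
#' +1230 uV (a 1000 uV peak scale plus a +230 uV ictal offset).
#'
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of channels.
#' @param h_baseline,h_precursor Hurst targets in (0, 1) for the baseline and
#'   the precursor-to-seizure-end regime.
#' @param t_precursor,t_onset,t_end Event times in seconds,
#'   `0 < t_precursor < t_onset < t_end <= duration_s`.
#' @param baseline_amp,ictal_amp Peak voltage scales in microvolts
#'   (`ictal_amp > baseline_amp > 0`); the generating fGn has unit variance
#'   and is multiplied by `amp / 4` (a 4-sigma peak convention).
#' @param ictal_offset Positive DC offset in microvolts added during the
#'   ictal window only, making the ictal range asymmetric.
#' @param dominant_channel Index of the channel that receives the full ictal
#'   amplitude; the others get it attenuated by 0.3.
#' @param seed Integer seed; identical specs give bitwise-identical records.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 180, fs = 256, n_channels = 24,
                           h_baseline = 0.9, h_precursor = 0.3,
                           t_precursor = 50, t_onset = 80, t_end = 160,
                           baseline_amp = 50, ictal_amp = 1000,
                           ictal_offset = 230, dominant_channel = 1,
                           seed = 1) {
  n_channels <- as.integer(n_channels)
  dominant_channel <- as.integer(dominant_channel)
  spec <- list(duration_s = duration_s, fs = fs, n_channels = n_channels,
               h_baseline = h_baseline, h_precursor = h_precursor,
               t_precursor = t_precursor, t_onset = t_onset, t_end = t_end,
               baseline_amp = baseline_amp, ictal_amp = ictal_amp,
               ictal_offset = ictal_offset,
               dominant_channel = dominant_channel, seed = seed)
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(spec) {
  with(spec, {
    if (!(0 < t_precursor && t_precursor < t_onset && t_onset < t_end &&
          t_end <= duration_s))
      stop("need 0 < t_precursor < t_onset < t_end <= duration_s", call. = FALSE)
    check_hurst_param(h_baseline)
    check_hurst_param(h_precursor)
    if (!(ictal_amp > baseline_amp && baseline_amp > 0))
      stop("need ictal_amp > baseline_amp > 0", call. = FALSE)
    if (fs <= 0 || n_channels < 1)
      stop("'fs' must be positive and 'n_channels' >= 1", call. = FALSE)
    if (dominant_channel < 1 || dominant_channel > n_channels)
      stop("'dominant_channel' out of range", call. = FALSE)
  })
  invisible(spec)
}

#' Event annotation of a record
#'
#' Ground-truth precursor, seizure-onset and seizure-end times in seconds.
#'
#' @param t_precursor,t_onset,t_end Times in seconds with
#'   `0 <= t_precursor < t_onset < t_end`.
#' @return An object of class `event_annotation`.
#' @export
event_annotation <- function(t_precursor, t_onset, t_end) {
  if (!(t_precursor >= 0 && t_precursor < t_onset && t_onset < t_end))
    stop("need 0 <= t_precursor < t_onset < t_end", call. = FALSE)
  structure(list(t_precursor = t_precursor, t_onset = t_onset, t_end = t_end),
            class = "event_annotation")
}

#' Generate a synthetic seizure record
#'
#' Builds each channel from stitched fGn segments: baseline Hurst up to the
#' precursor, precursor Hurst from there to the seizure end (one continuous
#' fGn segment, so the only change at onset is amplitude), an ictal
#' multiplicative amplitude burst plus positive offset on `[t_onset, t_end)`,
#' and a return to the baseline regime afterwards. Segments are zero-mean, so
#' joints carry no DC step. Non-dominant channels receive the ictal amplitude
#' and offset attenuated by 0.3.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `record` (an [eeg_record()]) and
#'   `annotation` (an [event_annotation()]). The record carries the
#'   generating segment boundaries (in samples) as attribute `"segments"`.
#' @export
gen_seizure_record <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  validate_spec(spec)
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  i_p <- round(spec$t_precursor * spec$fs)
  i_o <- round(spec$t_onset * spec$fs)
  i_e <- round(spec$t_end * spec$fs)
  b_scale <- spec$baseline_amp / 4
  data <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (ch in seq_len(spec$n_channels)) {
    att <- if (ch == spec$dominant_channel) 1 else 0.3
    i_scale <- spec$ictal_amp / 4 * att
    i_off <- spec$ictal_offset * att
    x <- numeric(n)
    x[seq_len(i_p)] <- gen_fgn(i_p, spec$h_baseline) * b_scale
    seg <- gen_fgn(i_e - i_p, spec$h_precursor)
    x[(i_p + 1L):i_o] <- seg[seq_len(i_o - i_p)] * b_scale
    x[(i_o + 1L):i_e] <- seg[(i_o - i_p + 1L):(i_e - i_p)] * i_scale + i_off
    if (i_e < n)
      x[(i_e + 1L):n] <- gen_fgn(n - i_e, spec$h_baseline) * b_scale
    data[ch, ] <- x
  }
  record <- eeg_record(data, fs = spec$fs)
  attr(record, "segments") <- c(precursor = i_p, onset = i_o, end = i_e)
  attr(record, "dominant_channel") <- spec$dominant_channel
  list(record = record,
       annotation = event_annotation(spec$t_precursor, spec$t_onset, spec$t_end))
}

#' Generate a precursor-free baseline record
#'
#' Stationary fGn on every channel at the baseline Hurst and amplitude, with
#' no precursor and no seizure: the null condition for false-alarm
#' calibration of the detectors.
#'
#' @param duration_s,fs,n_channels,h_baseline,baseline_amp,seed As in
#'   [synthetic_spec()].
#' @return An [eeg_record()].
#' @export
gen_baseline_record <- function(duration_s = 180, fs = 256, n_channels = 1,
                                h_baseline = 0.9, baseline_amp = 50,
                                seed = 1) {
  check_hurst_param(h_baseline)
  set.seed(seed)
  n <- round(duration_s * fs)
  data <- t(vapply(seq_len(n_channels),
                   function(ch) gen_fgn(n, h_baseline) * baseline_amp / 4,
                   numeric(n)))
  eeg_record(data, fs = fs)
}

#' Generate a synthetic cohort
#'
#' Subject `i` receives `trials_per_subject` seizure records whose true lead
#' time (onset minus precursor) is `lead_values[i]` plus an independent
#' uniform jitter of +/- 1 s per trial, mirroring a design in which each
#' printed subject value is an average over repeated trials.
#'
#' @param n_subjects Number of subjects; must equal `length(lead_values)`.
#' @param trials_per_subject Trials per subject (0 gives an empty cohort).
#' @param lead_values True subject-level lead times in seconds, each in
#'   `(0, t_onset)` of `spec_template`.
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @param spec_template A [synthetic_spec()] providing every field except
#'   `t_precursor` and `seed`.
#' @param jitter_s Half-width of the per-trial uniform jitter in seconds.
#' @return A list with one element per subject, each a list of
#'   `list(record, annotation)` trials (as from [gen_seizure_record()]).
#' @export
gen_cohort <- function(n_subjects, trials_per_subject, lead_values, seed = 1,
                       spec_template = synthetic_spec(), jitter_s = 1) {
  if (length(lead_values) == 0L)
    stop("'lead_values' must be non-empty", call. = FALSE)
  if (n_subjects != length(lead_values))
    stop("'n_subjects' must equal length(lead_values)", call. = FALSE)
  if (any(lead_values <= 0 | lead_values >= spec_template$t_onset))
    stop("lead values must lie in (0, t_onset)", call. = FALSE)
  if (trials_per_subject == 0L) return(list())
  lapply(seq_len(n_subjects), function(i) {
    lapply(seq_len(trials_per_subject), function(j) {
      trial_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      set.seed(trial_seed)
      jit <- stats::runif(1L, -jitter_s, jitter_s)
      sp <- unclass(spec_template)
      sp$t_precursor <- spec_template$t_onset - (lead_values[[i]] + jit)
      sp$seed <- trial_seed + 1L
      out <- gen_seizure_record(do.call(synthetic_spec, sp))
      out$record$subject_id <- as.character(i)
      out$record$trial_id <- as.character(j)
      out
    })
  })
}

#' Deterministic sample of a binomial multiplicative cascade
#'
#' Returns `n` values in (0, 1) whose empirical distribution follows the
#' binomial (p, 1-p) multiplicative cascade at dyadic depth `depth`: the
#' inverse cascade CDF evaluated on an equispaced grid of probabilities.
#' The cascade is the standard multifractal benchmark; its generalized
#' dimensions have the closed form
#' \eqn{D_q = \log_2(p^q + (1-p)^q) / (1 - q)} (Shannon limit at q = 1).
#'
#' @param n Number of values.
#' @param p Left-branch weight in (0, 1), `p != 0.5` for a non-trivial
#'   spectrum.
#' @param depth Dyadic recursion depth.
#' @param shuffle_seed Optional seed to randomly permute the values (binning
#'   ignores order, so this is cosmetic).
#' @return Numeric vector of `n` values in (0, 1).
#' @export
gen_cascade_series <- function(n = 2^14, p = 0.7, depth = 10,
                               shuffle_seed = NULL) {
  if (p <= 0 || p >= 1) stop("'p' must be in (0, 1)", call. = FALSE)
  w <- 1
  for (l in seq_len(depth)) w <- as.vector(rbind(w * p, w * (1 - p)))
  cw <- cumsum(w)
  u <- (seq_len(n) - 0.5) / n
  idx <- findInterval(u, cw) + 1L
  idx[idx > length(w)] <- length(w)
  vals <- (idx - 0.5) / length(w)
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    vals <- sample(vals)
  }
  vals
}

#' Closed-form cascade dimensions
#'
#' Generalized dimensions of the binomial multiplicative cascade, used as an
#' independent oracle for the estimated fractal spectrum.
#'
#' @param q Vector of moment orders.
#' @param p Left-branch weight in (0, 1).
#' @return Numeric vector `D_q`.
#' @export
cascade_dimension <- function(q, p = 0.7) {
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-12) -(p * log2(p) + (1 - p) * log2(1 - p))
    else log2(p^qi + (1 - p)^qi) / (1 - qi)
  }, numeric(1L))
}

#' Read and write annotation files
#'
#' Annotations travel as a one-row CSV with columns
#' `t_precursor,t_onset,t_end` (seconds).
#'
#' @param annotation An [event_annotation()].
#' @param path File path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns an [event_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  if (!inherits(annotation, "event_annotation"))
    stop("expected an 'event_annotation'", call. = FALSE)
  utils::write.csv(as.data.frame(unclass(annotation)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path)
  event_annotation(df$t_precursor[[1L]], df$t_onset[[1L]], df$t_end[[1L]])
}
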