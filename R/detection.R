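# Precursor-deflection detection, onset location, lead times.
#
# The deflection detector formalises what the study reads off the plots: a
# sudden, sustained departure of the trajectory from its own baseline. The
# baseline level is the median of the early trajectory, the scale is its
# MAD, and a deflection is declared when the value stays k scales beyond
# the baseline for m consecutive points.

#' Detect a sustained deflection in a trajectory
#'
#' Baseline level and scale are the median and MAD of the trajectory values
#' inside the first `baseline_s` seconds. The deflection time is the first
#' point where the value crosses `k * scale` below (direction `"down"`) or
#' above (`"up"`) the baseline and stays crossed for `m` consecutive points.
#' For window-derived trajectories the reported time is the *start* of the
#' first crossing window (`centre - window_s / 2`): the change must begin at
#' or after that instant, and the crossing itself lags the changepoint by the
#' fraction of the window the new regime needs to pull the estimate across
#' the threshold.
#'
#' `scale_floor` / `scale_cap` optionally bound the MAD; with a short
#' baseline of strongly overlapping windows the MAD underestimates the slow
#' wander of long-range-dependent trajectories, so [analyze_record()] bounds
#' it by the estimator's Monte-Carlo sampling deviation.
#'
#' @param traj A [trajectory()] spanning at least `baseline_s + m * step_s`.
#' @param direction `"down"` or `"up"`.
#' @param baseline_s Baseline span in seconds.
#' @param k Threshold multiplier.
#' @param m Persistence (consecutive points beyond threshold).
#' @param scale_floor,scale_cap Bounds applied to the MAD scale.
#' @return Deflection time in seconds, or `NA` if none; attribute
#'   `"baseline"` carries the baseline level and scale used.
#' @examples
#' tr <- trajectory(1:100, c(rep(0.9, 50), rep(0.3, 50)))
#' detect_deflection(tr, "down", baseline_s = 20)
#' @export
detect_deflection <- function(traj, direction = c("down", "up"),
                              baseline_s = 20, k = 4, m = 3,
                              scale_floor = 0, scale_cap = Inf) {
  if (!inherits(traj, "trajectory"))
    stop("expected a 'trajectory' object", call. = FALSE)
  direction <- match.arg(direction)
  t <- traj$times
  v <- traj$values
  step <- if (is.finite(traj$step_s)) traj$step_s else
    if (length(t) > 1L) t[[2L]] - t[[1L]] else 1
  if (max(t) - min(t) < baseline_s + m * step)
    stop("trajectory shorter than baseline_s + m steps", call. = FALSE)
  base_idx <- t < t[[1L]] + baseline_s
  bv <- v[base_idx & is.finite(v)]
  if (length(bv) < 3L)
    stop("not enough finite baseline points", call. = FALSE)
  level <- stats::median(bv)
  scale <- min(max(stats::mad(bv), scale_floor), scale_cap)
  dev <- if (direction == "down") level - v else v - level
  crossed <- !is.na(dev) & dev > k * scale
  run <- 0L
  t_sign <- NA_real_
  for (i in seq_along(crossed)) {
    run <- if (crossed[[i]]) run + 1L else 0L
    if (run >= m) {
      t_sign <- t[[i - m + 1L]] - traj$window_s / 2
      break
    }
  }
  structure(t_sign, baseline = c(level = level, scale = scale))
}

#' Detect seizure onset from the amplitude burst
#'
#' Onset is the first time the sliding 1-second peak-to-peak amplitude
#' exceeds `k` times the peak-to-peak amplitude of the first `baseline_s`
#' seconds, sustained for at least `sustain_s` seconds. Intended for
#' synthetic or benchmark data when the annotation is withheld; an annotated
#' onset always takes precedence in [analyze_record()].
#'
#' @param record An [eeg_record()] longer than `baseline_s`.
#' @param channel Channel index (default: dominant channel).
#' @param baseline_s Baseline span in seconds.
#' @param k Amplitude-ratio threshold.
#' @param sustain_s Minimum duration the burst must persist.
#' @return Onset time in seconds, or `NA` if no burst is found.
#' @export
detect_onset <- function(record, channel = select_dominant_channel(record),
                         baseline_s = 20, k = 5, sustain_s = 2) {
  assert_record(record)
  if (record$T <= baseline_s)
    stop("record must be longer than 'baseline_s'", call. = FALSE)
  x <- record$data[channel, ]
  fs <- record$fs
  win <- max(2L, round(fs))          # 1-second windows
  step <- max(1L, round(fs / 2))     # half-second hop
  starts <- seq(1L, length(x) - win + 1L, by = step)
  p2p <- vapply(starts, function(i) diff(range(x[i:(i + win - 1L)])),
                numeric(1L))
  times <- (starts - 1L) / fs
  base_p2p <- diff(range(x[seq_len(round(baseline_s * fs))]))
  if (base_p2p == 0) base_p2p <- .Machine$double.eps
  hot <- p2p > k * base_p2p
  need <- max(1L, ceiling(sustain_s / (step / fs)))
  run <- 0L
  for (i in seq_along(hot)) {
    run <- if (hot[[i]]) run + 1L else 0L
    if (run >= need) return(times[[i - need + 1L]])
  }
  NA_real_
}

#' Lead time between precursor sign and onset
#'
#' `t_onset - t_sign` in seconds. A negative value (sign found after onset)
#' is returned flagged rather than raised, so cohort summaries can count
#' detection failures.
#'
#' @param t_sign,t_onset Times in seconds.
#' @return Numeric lead time with logical attribute `"flagged"` (`TRUE` when
#'   negative).
#' @examples
#' lead_time(50, 80) # 30 s
#' @export
lead_time <- function(t_sign, t_onset) {
  lead <- t_onset - t_sign
  structure(lead, flagged = isTRUE(lead < 0))
}

default_detection_config <- function() {
  list(window_s = 10, step_s = 1, method = "rs", q = 1,
       fd_measure = "graph", baseline_s = 30, k = 4, m = 3,
       preprocess = TRUE, cutoff_hz = 35, target_fs = 35,
       h_scale_band = c(0.05, 0.08), fd_scale_band = c(0.04, 0.06),
       concordance_tol_s = NULL)
}

#' Full precursor analysis of one record
#'
#' Runs the study pipeline on a record: select the dominant channel,
#' low-pass/decimate it, compute sliding Hurst and fractal-dimension
#' trajectories, detect the downward Hurst deflection and the upward FD
#' deflection, check their concordance, locate seizure onset (annotated
#' onset takes precedence, otherwise the amplitude detector), find the
#' post-onset recovery deflection, and compute the lead time. The
#' Hurst-based deflection time is authoritative; the FD channel serves as
#' confirmation.
#'
#' @param record An [eeg_record()].
#' @param annotation Optional [event_annotation()]; when given, its
#'   `t_onset` is used for the lead time.
#' @param config Named list overriding the defaults: `window_s` (10 s),
#'   `step_s` (1 s), `method` ("rs"), `q` (1), `fd_measure` ("graph"),
#'   `baseline_s` (30 s), `k` (4), `m` (3), `preprocess` (TRUE: low-pass at
#'   `cutoff_hz` = 35 and resample to `target_fs` = 35), `h_scale_band` and
#'   `fd_scale_band` (MAD bounds, see [detect_deflection()]),
#'   `concordance_tol_s` (default `2 * window_s`).
#' @return Object of class `detection_result` with fields `t_sign`,
#'   `t_sign_fd`, `t_onset_detected`, `t_recovery`, `lead_time`,
#'   `lead_flagged`, `concordant`, `channel`, `diagnostics`, and the two
#'   trajectories.
#' @export
analyze_record <- function(record, annotation = NULL, config = list()) {
  assert_record(record)
  cfg <- utils::modifyList(default_detection_config(), config)
  if (is.null(cfg$concordance_tol_s)) cfg$concordance_tol_s <- 2 * cfg$window_s

  channel <- select_dominant_channel(record)
  work <- eeg_record(record$data[channel, , drop = FALSE], fs = record$fs)
  if (isTRUE(cfg$preprocess) && record$fs > cfg$target_fs &&
      record$fs >= 2 * cfg$cutoff_hz)
    work <- lowpass_decimate(work, cutoff = cfg$cutoff_hz,
                             target_fs = cfg$target_fs)

  traj_h <- sliding_hurst(work, channel = 1L, window_s = cfg$window_s,
                          step_s = cfg$step_s, method = cfg$method)
  traj_fd <- sliding_fd(work, channel = 1L, window_s = cfg$window_s,
                        step_s = cfg$step_s, q = cfg$q,
                        fd_measure = cfg$fd_measure)

  t_sign_h <- detect_deflection(traj_h, "down", baseline_s = cfg$baseline_s,
                                k = cfg$k, m = cfg$m,
                                scale_floor = cfg$h_scale_band[[1L]],
                                scale_cap = cfg$h_scale_band[[2L]])
  t_sign_fd <- detect_deflection(traj_fd, "up", baseline_s = cfg$baseline_s,
                                 k = cfg$k, m = cfg$m,
                                 scale_floor = cfg$fd_scale_band[[1L]],
                                 scale_cap = cfg$fd_scale_band[[2L]])
  concordant <- !is.na(t_sign_h) && !is.na(t_sign_fd) &&
    abs(as.numeric(t_sign_h) - as.numeric(t_sign_fd)) <= cfg$concordance_tol_s

  t_onset <- if (!is.null(annotation)) annotation$t_onset
             else detect_onset(record, channel = channel)

  lead <- NA_real_
  lead_flagged <- FALSE
  if (!is.na(t_sign_h) && !is.na(t_onset)) {
    lt <- lead_time(as.numeric(t_sign_h), t_onset)
    lead <- as.numeric(lt)
    lead_flagged <- attr(lt, "flagged")
  }

  # recovery: first upward Hurst deflection after onset, judged against the
  # early post-onset (ictal) level.
  t_recovery <- NA_real_
  if (!is.na(t_onset)) {
    # start one window past onset so windows straddling the ictal amplitude
    # jump cannot masquerade as recovery
    post <- traj_h$times >= t_onset + cfg$window_s
    if (sum(post) > cfg$m + 3L) {
      post_traj <- trajectory(traj_h$times[post], traj_h$values[post],
                              window_s = traj_h$window_s,
                              step_s = traj_h$step_s,
                              measure_name = traj_h$measure_name)
      span <- max(post_traj$times) - min(post_traj$times)
      bs <- min(cfg$baseline_s, max(span - (cfg$m + 1) * cfg$step_s, cfg$step_s))
      t_recovery <- tryCatch(
        as.numeric(detect_deflection(post_traj, "up", baseline_s = bs,
                                     k = cfg$k, m = cfg$m,
                                     scale_floor = cfg$h_scale_band[[1L]],
                                     scale_cap = cfg$h_scale_band[[2L]])),
        error = function(e) NA_real_)
    }
  }

  structure(list(
    t_sign = as.numeric(t_sign_h),
    t_sign_fd = as.numeric(t_sign_fd),
    t_onset_detected = as.numeric(t_onset),
    t_recovery = t_recovery,
    lead_time = lead,
    lead_flagged = lead_flagged,
    concordant = concordant,
    channel = channel,
    diagnostics = list(h_baseline = attr(t_sign_h, "baseline"),
                       fd_baseline = attr(t_sign_fd, "baseline")),
    traj_hurst = traj_h,
    traj_fd = traj_fd,
    config = cfg), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f s", v)
  cat("<detection_result>\n")
  cat("  precursor sign (Hurst):", fmt(x$t_sign), "\n")
  cat("  precursor sign (FD):   ", fmt(x$t_sign_fd),
      if (isTRUE(x$concordant)) "(concordant)" else "", "\n")
  cat("  onset:                 ", fmt(x$t_onset_detected), "\n")
  cat("  lead time:             ", fmt(x$lead_time),
      if (isTRUE(x$lead_flagged)) "(flagged: sign after onset)" else "", "\n")
  cat("  recovery:              ", fmt(x$t_recovery), "\n")
  invisible(x)
}
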