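# Subject- and cohort-level aggregation of precursor lead times, plus the
# packaged printed lead-time table of the 120-subject study.

#' Subject-level lead time from trial leads
#'
#' Arithmetic mean of the valid (non-flagged, non-missing) trial leads of
#' one subject. Flagged trials (negative leads, i.e. sign found after
#' onset) are excluded and counted.
#'
#' @param trial_leads Numeric vector of per-trial lead times in seconds;
#'   `NA` or negative entries count as invalid.
#' @return Mean lead in seconds with attribute `"n_excluded"`; `NA` with
#'   attribute `"reason"` when no trial is valid.
#' @examples
#' subject_leads(c(28, 32))
#' @export
subject_leads <- function(trial_leads) {
  if (length(trial_leads) < 1L)
    stop("'trial_leads' must be non-empty", call. = FALSE)
  valid <- !is.na(trial_leads) & trial_leads >= 0
  if (!any(valid))
    return(structure(NA_real_, n_excluded = sum(!valid),
                     reason = "no valid (non-flagged) trial leads"))
  structure(mean(trial_leads[valid]), n_excluded = sum(!valid))
}

#' Cohort summary of lead times
#'
#' Mean, sample standard deviation (divisor n-1), a confidence interval for
#' the mean, and the range. The default interval is the normal
#' approximation `mean +/- z * sd / sqrt(n)`; `method = "t"` uses the
#' Student-t quantile instead.
#'
#' @param leads Numeric vector of subject-level leads in seconds, `n >= 2`.
#' @param confidence Confidence level (default 0.95).
#' @param method `"normal"` (default) or `"t"`.
#' @return Object of class `cohort_summary` with fields `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `minimum`, `maximum`, `confidence`, `method`.
#' @examples
#' summarize_leads(load_table1()$lead_s)
#' @export
summarize_leads <- function(leads, confidence = 0.95,
                            method = c("normal", "t")) {
  method <- match.arg(method)
  leads <- as.numeric(leads)
  if (length(leads) < 2L || anyNA(leads))
    stop("need at least 2 non-missing lead values", call. = FALSE)
  n <- length(leads)
  m <- mean(leads)
  s <- stats::sd(leads)
  crit <- switch(method,
    normal = stats::qnorm(1 - (1 - confidence) / 2),
    t = stats::qt(1 - (1 - confidence) / 2, df = n - 1L))
  half <- crit * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s, ci_low = m - half,
                 ci_high = m + half, minimum = min(leads),
                 maximum = max(leads), confidence = confidence,
                 method = method),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> n = %d: mean %.2f s, sd %.2f s, %g%% CI [%.2f, %.2f], range [%g, %g]\n",
    x$n, x$mean, x$sd, 100 * x$confidence, x$ci_low, x$ci_high,
    x$minimum, x$maximum))
  invisible(x)
}

#' Packaged 120-subject lead-time table
#'
#' The printed per-subject lead times (seconds between the precursor sign
#' and seizure onset, each the average of eight trials) for the 120-subject
#' cohort, shipped as a plain CSV fixture.
#'
#' @return Data frame with columns `subject` (1..120) and `lead_s`
#'   (integers in 19..35).
#' @examples
#' tab <- load_table1()
#' tab$lead_s[tab$subject == 1]
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_leads.csv", package = "preictal")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged lead-time table not found", call. = FALSE)
  df <- utils::read.csv(path)
  if (!identical(names(df), c("subject", "lead_s")) || nrow(df) != 120L ||
      !identical(df$subject, 1:120) || anyNA(df$lead_s))
    stop("packaged lead-time table is corrupt", call. = FALSE)
  df
}
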