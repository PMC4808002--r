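# lag-1 autocorrelation for a process with known zero mean and unit variance;
# the mean-subtracting sample ACF is badly biased under long-range dependence
lag1 <- function(x) mean(x[-1] * x[-length(x)])

test_that("fGn generator matches the closed-form autocovariance", {
  # H = 0.5 is uncorrelated noise
  x <- gen_fgn(4096, 0.5, seed = 1)
  expect_lt(abs(lag1(x)), 0.05)
  # anti-persistent: negative lag-1 correlation, fast convergence
  z <- gen_fgn(8192, 0.3, seed = 1)
  expect_lt(abs(lag1(z) - (2^(2 * 0.3 - 1) - 1)), 0.05)
  # persistent fGn: rho(1) = 2^(2H-1) - 1; single realisations of H = 0.9
  # noise have per-seed sd about 0.15 in this statistic, so average seeds
  r <- vapply(1:60, function(s) lag1(gen_fgn(8192, 0.9, seed = s)),
              numeric(1))
  expect_lt(abs(mean(r) - (2^(2 * 0.9 - 1) - 1)), 0.06)
})

test_that("fGn marginal is standard normal to sampling accuracy", {
  for (h in c(0.3, 0.7)) {
    n <- 8192
    x <- gen_fgn(n, h, seed = 11)
    # sd of the sample mean of fGn scales as n^(H-1), not n^(-1/2)
    expect_lt(abs(mean(x)), 3 * n^(h - 1))
    expect_lt(abs(mean(x^2) - 1), 0.1)
  }
  # strongly persistent noise: second moment converges slowly, average seeds
  m2 <- vapply(1:40, function(s) mean(gen_fgn(8192, 0.9, seed = 100 + s)^2),
               numeric(1))
  expect_lt(abs(mean(m2) - 1), 0.1)
})

test_that("fGn generation is reproducible and validates parameters", {
  expect_identical(gen_fgn(4096, 0.7, seed = 1), gen_fgn(4096, 0.7, seed = 1))
  expect_error(gen_fgn(128, 1.2), "Hurst")
  expect_error(gen_fgn(128, 0), "Hurst")
  expect_error(gen_fgn(1, 0.5), ">= 2")
})

test_that("sequential-conditional fallback reproduces the fGn correlations", {
  set.seed(42)
  r1 <- replicate(40, lag1(preictal:::fgn_hosking(256, 0.8)))
  expect_lt(abs(mean(r1) - (2^(2 * 0.8 - 1) - 1)), 0.06)
})

test_that("seizure record has the designed ictal amplitude burst", {
  out <- make_seizure(seed = 4)
  rec <- out$record
  ann <- out$annotation
  expect_s3_class(rec, "eeg_record")
  expect_equal(ann$t_precursor, 50)
  expect_equal(ann$t_onset, 80)
  dom <- attr(rec, "dominant_channel")
  x <- rec$data[dom, ]
  idx_ict <- seq(round(80 * rec$fs) + 1, round(160 * rec$fs))
  idx_pre <- seq_len(round(80 * rec$fs))
  p2p_ict <- diff(range(x[idx_ict]))
  p2p_pre <- diff(range(x[idx_pre]))
  expect_gte(p2p_ict / p2p_pre, 5)
  # non-dominant channels carry the attenuated burst
  other <- setdiff(seq_len(nrow(rec$data)), dom)[1]
  expect_lt(diff(range(rec$data[other, idx_ict])), p2p_ict)
})

test_that("degenerate spec with no Hurst change is stationary across the boundary", {
  out <- gen_seizure_record(synthetic_spec(
    n_channels = 1, t_precursor = 79.9, h_precursor = 0.9, seed = 5))
  x <- out$record$data[1, ]
  fs <- out$record$fs
  a <- x[seq_len(round(50 * fs))]
  b <- x[seq(round(50 * fs) + 1, round(79 * fs))]
  expect_gt(var(a) / var(b), 0.8)
  expect_lt(var(a) / var(b), 1.25)
})

test_that("record generation is deterministic in the generator seed", {
  o1 <- make_seizure(seed = 9, n_channels = 2)
  o2 <- make_seizure(seed = 9, n_channels = 2)
  expect_identical(o1$record$data, o2$record$data)
  expect_identical(unclass(o1$annotation), unclass(o2$annotation))
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(t_precursor = 90), "t_precursor")
  expect_error(synthetic_spec(h_precursor = 1.5), "Hurst")
  expect_error(synthetic_spec(ictal_amp = 10), "ictal_amp")
})

test_that("cohort leads follow the requested per-subject values with jitter", {
  tmpl <- synthetic_spec(n_channels = 2)
  cohort <- gen_cohort(3, 2, c(30, 20, 26), seed = 7, spec_template = tmpl)
  expect_length(cohort, 3)
  expect_length(unlist(cohort, recursive = FALSE), 6)
  for (i in 1:3) {
    for (trial in cohort[[i]]) {
      lead <- trial$annotation$t_onset - trial$annotation$t_precursor
      expect_lt(abs(lead - c(30, 20, 26)[i]), 1 + 1e-9)
    }
  }
  one <- gen_cohort(1, 1, 19, seed = 1, spec_template = tmpl)
  lead <- one[[1]][[1]]$annotation$t_onset - one[[1]][[1]]$annotation$t_precursor
  expect_lt(abs(lead - 19), 1 + 1e-9)
  expect_identical(gen_cohort(1, 0, 25, spec_template = tmpl), list())
  expect_error(gen_cohort(0, 1, numeric(0)), "non-empty")
})

test_that("cascade sampler matches its target measure at coarse scales", {
  x <- gen_cascade_series(2^14, p = 0.7, depth = 10)
  # mass of the left half must be ~p
  expect_lt(abs(mean(x < 0.5) - 0.7), 0.01)
  expect_true(all(x > 0 & x < 1))
})
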