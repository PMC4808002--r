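test_that("bin probabilities implement the bin-count definition", {
  d <- bin_probabilities(rep(2.5, 100), delta_v = 0.1)
  expect_identical(d$n_bins, 1L)
  expect_equal(d$weights, 1)

  d2 <- bin_probabilities(c(0, 1, 0, 1), delta_v = 0.5)
  expect_identical(d2$n_bins, 2L)
  expect_equal(d2$weights, c(0.5, 0.5))

  set.seed(1)
  d3 <- bin_probabilities(runif(1000, 0, 10), delta_v = 1)
  expect_identical(d3$n_bins, 10L)
  expect_equal(sum(d3$weights), 1, tolerance = 1e-12)
  expect_identical(sum(d3$counts), 1000L)
  expect_error(bin_probabilities(1:10, delta_v = 0), "positive")
})

test_that("weights are normalised and affine-covariant", {
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(500)
    dv <- runif(1, 0.05, 0.5)
    d <- bin_probabilities(x, dv)
    expect_equal(sum(d$weights), 1, tolerance = 1e-12)
    a <- runif(1, 0.5, 3)
    b <- rnorm(1)
    expect_equal(bin_probabilities(a * x + b, a * dv)$weights, d$weights)
  }
})

test_that("Renyi entropy matches hand-computed values", {
  expect_equal(renyi_entropy(rep(1 / 8, 8), q = 2), 3)
  expect_equal(renyi_entropy(rep(1 / 8, 8), q = 0), 3)
  expect_equal(renyi_entropy(c(0.5, 0.25, 0.25), q = 2), -log2(0.375))
  expect_equal(renyi_entropy(c(0.5, 0.5), q = 1), 1)
  # Shannon limit is continuous at q = 1
  w <- c(0.6, 0.3, 0.1)
  e1 <- renyi_entropy(w, 1)
  expect_lt(abs(renyi_entropy(w, 1 + 1e-6) - e1), 1e-4)
  expect_lt(abs(renyi_entropy(w, 1 - 1e-6) - e1), 1e-4)
})

test_that("Renyi entropy is non-increasing in q for arbitrary distributions", {
  set.seed(11)
  qs <- seq(-10, 10, by = 0.5)
  for (rep in 1:10) {
    w <- rgamma(sample(2:20, 1), 1)
    w <- w / sum(w)
    e <- vapply(qs, function(q) renyi_entropy(w, q), numeric(1))
    expect_true(all(diff(e) <= 1e-9))
  }
})

test_that("generalized dimension recovers known distributions", {
  # constant series: one occupied bin at every scale
  const <- generalized_dimension(rep(1, 256), q = 2)
  expect_identical(const$dimension, 0)
  expect_true(is.na(const$r2))
  # space-filling uniform marginal has dimension 1
  set.seed(5)
  x <- runif(65536)
  for (q in c(0, 1, 2)) {
    est <- generalized_dimension(x, q)$dimension
    expect_lt(abs(est - 1), 0.1)
  }
})

test_that("self-similar equal-probability distributions are flat in q", {
  # dyadic uniform support: every occupied bin equally probable at dyadic scales
  x <- rep((0:255 + 0.5) / 256, each = 16)
  grid <- 1 / 2^(1:6)
  dims <- vapply(c(-2, 0, 1, 2, 5),
                 function(q) generalized_dimension(x, q, grid)$dimension,
                 numeric(1))
  expect_lt(max(dims) - min(dims), 0.02)
})

test_that("binomial cascade dimensions match the closed form", {
  x <- gen_cascade_series(2^14, p = 0.7, depth = 10)
  grid <- diff(range(x)) / 2^(1:6)
  for (q in c(-5, -2, 0, 1, 2, 5)) {
    est <- generalized_dimension(x, q, grid)$dimension
    expect_lt(abs(est - cascade_dimension(q, 0.7)), 0.05)
  }
})

test_that("fractal spectrum separates monofractal from multifractal series", {
  set.seed(9)
  u <- runif(4096)
  flat <- fractal_spectrum(u)
  expect_lte(flat$spectrum_range, 0.15)
  expect_true(all(diff(flat$dimensions) <= 0.02))
  casc <- fractal_spectrum(gen_cascade_series(2^14),
                           delta_v_grid = 1 / 2^(1:6))
  expect_gte(casc$spectrum_range, 0.3)
  expect_true(all(diff(casc$dimensions) <= 0.02))
  # q = 0 entropy at the finest scale counts occupied bins
  d <- bin_probabilities(u, min(flat$delta_v_grid))
  expect_equal(flat$entropies[flat$q_grid == 0], log2(sum(d$counts > 0)),
               tolerance = 1e-9)
})

test_that("constant series has an all-zero spectrum", {
  sp <- fractal_spectrum(rep(4, 256), delta_v_grid = 1 / 2^(1:6))
  expect_true(all(sp$dimensions == 0))
  expect_identical(sp$spectrum_range, 0)
})

test_that("graph dimension separates smooth from rough profiles", {
  expect_identical(graph_dimension(rep(1, 350)), 0)
  set.seed(3)
  smooth_d <- mean(replicate(10, graph_dimension(gen_fgn(350, 0.9))))
  rough_d <- mean(replicate(10, graph_dimension(gen_fgn(350, 0.3))))
  expect_gt(rough_d - smooth_d, 0.2)
  expect_gt(smooth_d, 1)
  expect_lt(rough_d, 2)
})

test_that("sliding FD trajectory has the contracted length and rises after the precursor", {
  out <- make_seizure(seed = 10, n_channels = 1)
  dec <- lowpass_decimate(out$record)
  tr <- sliding_fd(dec, channel = 1)
  expect_length(tr$values, 171)
  expect_true(all(tr$values[!tr$flags] >= 0))
  before <- mean(tr$values[tr$times < 45], na.rm = TRUE)
  after <- mean(tr$values[tr$times > 55 & tr$times < 75], na.rm = TRUE)
  expect_gt(after, before)
})

test_that("sliding FD of a constant record is zero everywhere", {
  rec <- eeg_record(matrix(5, nrow = 1, ncol = 35 * 30), fs = 35)
  tr <- sliding_fd(rec, channel = 1)
  expect_true(all(tr$values == 0))
})
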