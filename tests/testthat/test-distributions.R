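test_that("sampled histograms conserve counts and are seed-reproducible", {
  x <- sin(seq(0, 200, by = 0.01))
  edges <- stg_bin_edges("share", 101, c(-1, 1))
  h1 <- sample_histogram(x, edges, n_samples = 1e5, seed = 4)
  h2 <- sample_histogram(x, edges, n_samples = 1e5, seed = 4)
  h3 <- sample_histogram(x, edges, n_samples = 1e5, seed = 5)
  expect_equal(sum(h1), 1e5)
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
  expect_equal(attr(h1, "clipped"), 0)
  # exhaustive sampling uses every sample once
  h4 <- sample_histogram(x, edges, n_samples = NULL)
  expect_equal(sum(h4), length(x))
})

test_that("out-of-range samples are clipped into edge bins with a warning", {
  edges <- seq(0, 1, by = 0.1)
  expect_warning(h <- sample_histogram(c(-5, 0.5, 7), edges,
                                       n_samples = NULL),
                 "clipped")
  expect_equal(sum(h), 3)
  expect_equal(h[1], 1L)
  expect_equal(h[10], 1L)
})

test_that("a linear ramp yields a uniform histogram", {
  x <- seq(-70, 35, length.out = 2e5 + 1)
  edges <- stg_bin_edges("V", 101)
  h <- sample_histogram(x, edges, n_samples = 5e5, seed = 1)
  expect_lt(max(abs(h - mean(h))) / mean(h), 0.05)
})

test_that("a sinusoid reproduces the arcsine distribution", {
  A <- 40
  x <- A * sin(seq(0, 2000 * pi, length.out = 4e6))
  edges <- seq(-A, A, length.out = 402)
  h <- sample_histogram(x, edges, n_samples = 2e6, seed = 2)
  emp_cdf <- cumsum(h) / sum(h)
  th_cdf <- 0.5 + asin(pmin(pmax(edges[-1] / A, -1), 1)) / pi
  expect_lt(max(abs(emp_cdf - th_cdf)), 0.01)
  # density peaks at the extremes
  expect_gt(h[1], 5 * h[200])
})

test_that("a sawtooth reproduces the uniform distribution", {
  x <- rep(seq(0, 1, length.out = 1001), 200)
  edges <- seq(0, 1.0000001, length.out = 101)
  h <- sample_histogram(x, edges, n_samples = 2e6, seed = 3)
  emp_cdf <- cumsum(h) / sum(h)
  expect_lt(max(abs(emp_cdf - edges[-1])), 0.01)
})

test_that("ridge enhancement differentiates log10(p + 1) along bins", {
  expect_equal(ridge_map(rep(5, 50)), matrix(0, 1, 50))

  # single-peak row: exactly one +/- sign change at the peak
  peak <- dnorm(seq(-4, 4, length.out = 201)) * 1e4
  r <- ridge_map(peak)
  sign_changes <- sum(diff(sign(r[1, abs(r[1, ]) > 1e-9])) < 0)
  expect_equal(sign_changes, 1)

  # two-Gaussian mixture: two ridges
  v <- seq(-8, 8, length.out = 401)
  mix <- (dnorm(v, -3) + dnorm(v, 3)) * 1e4
  r2 <- ridge_map(mix)
  expect_equal(sum(diff(sign(r2[1, abs(r2[1, ]) > 1e-9])) < 0), 2)

  # interior uses central differences of the display transform
  row <- c(0, 10, 100, 10, 0)
  lp <- log10(row + 1)
  expect_equal(ridge_map(row)[1, 3], (lp[4] - lp[2]) / 2)
  expect_error(ridge_map(c(-1, 2, 3)), "non-negative")
})

test_that("conductance-sweep histograms anchor to the control run", {
  m <- stg_models("a")
  sw <- sweep_distribution(m, "Na", "V", levels = c(1, 0.5),
                          duration = 4000, transient = 2000, dt = 0.1,
                          n_bins = 201, n_samples = 1e5, seed = 8)
  expect_equal(dim(sw$counts), c(2, 201))
  expect_equal(rowSums(sw$counts), c(1e5, 1e5))
  expect_false(any(sw$failed))

  # the level-1 row equals a control histogram computed directly
  tr <- stg_simulate(m, 4000, 0.1, 2000, record_currents = FALSE)
  h <- suppressWarnings(sample_histogram(tr$V, sw$edges, 1e5, seed = 8))
  expect_equal(sw$counts[1, ], as.integer(h))

  # reproducibility from the seed
  sw2 <- sweep_distribution(m, "Na", "V", levels = c(1, 0.5),
                           duration = 4000, transient = 2000, dt = 0.1,
                           n_bins = 201, n_samples = 1e5, seed = 8)
  expect_identical(sw$counts, sw2$counts)
})

test_that("share sweeps live on [0,1] and vanish with their conductance", {
  m <- stg_models("a")
  sw <- sweep_distribution(m, "CaT", "share", levels = c(1, 0),
                          duration = 3000, transient = 1500, dt = 0.1,
                          share_sign = "in", n_bins = 101,
                          n_samples = 1e4, seed = 1)
  expect_equal(rowSums(sw$counts), c(1e4, 1e4))
  # at level 0 the CaT share is identically zero: all mass in the first bin
  expect_equal(sw$counts[2, 1], 1e4)
  expect_equal(sum(sw$counts[2, -1]), 0)
})
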