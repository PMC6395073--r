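test_that("threshold crossings follow the upward/downward definitions", {
  expect_equal(detect_crossings(c(-30, -10), -20, "up"), 1L)
  expect_equal(detect_crossings(c(-10, -30), -20, "down"), 1L)
  expect_length(detect_crossings(rep(-40, 100), -20, "up"), 0)
  # a value landing exactly on the threshold counts for the next crossing
  expect_equal(detect_crossings(c(-20, -10), -20, "up"), 1L)
  expect_error(detect_crossings(-1, 0), "at least 2")

  # one full sine period crossing zero: exactly one of each
  x <- sin(2 * pi * seq(0, 1, length.out = 1000))
  expect_length(detect_crossings(x, 0, "up"), 1)
  expect_length(detect_crossings(x, 0, "down"), 1)
})

test_that("crossing counts survive resampling of a band-limited signal", {
  f <- function(t) sin(2 * pi * t / 100)
  coarse <- f(seq(0, 1000, by = 1))
  fine <- f(seq(0, 1000, by = 0.1))
  for (thr in c(-0.5, 0, 0.5)) {
    expect_equal(length(detect_crossings(coarse, thr, "up")),
                 length(detect_crossings(fine, thr, "up")))
  }
})

test_that("up and down crossing counts differ by at most one", {
  set.seed(7)
  for (i in 1:20) {
    x <- cumsum(rnorm(500))
    thr <- stats::quantile(x, runif(1, 0.1, 0.9))
    d <- abs(length(detect_crossings(x, thr, "up")) -
               length(detect_crossings(x, thr, "down")))
    expect_lte(d, 1)
  }
})

test_that("burst segmentation reproduces hand-computed statistics", {
  # three 3-spike bursts 1 s apart, then one more spike to close the last
  S <- c(1000, 1010, 1020, 2000, 2010, 2020, 3000, 3010, 3020, 4000)
  st <- burst_statistics(S)
  expect_equal(st$n_bursts, 4)
  expect_equal(length(st$fb_samples), 3)
  expect_equal(st$fb_samples, rep(1, 3))          # tau_b = 20 + 980 = 1000 ms
  expect_equal(st$dc_samples, rep(0.02, 3))       # delta_b / tau_b
  expect_equal(st$mean_fb, 1)
  expect_equal(st$mean_dc, 0.02)
  expect_equal(st$std_fb, 0)
  expect_true(st$stable)
  # burst start/end indices pair one-to-one
  expect_equal(st$bs, c(1L, 4L, 7L, 10L))
  expect_equal(st$be, c(3L, 6L, 9L, 10L))
})

test_that("an isolated spike is a burst of duration zero", {
  S <- c(1000, 2000, 3000)
  st <- burst_statistics(S)
  expect_equal(st$n_bursts, 3)
  expect_equal(st$dc_samples, c(0, 0))
  expect_equal(st$fb_samples, c(1, 1)) # tau_b = 0 + 1000 ms
})

test_that("trains with fewer than 3 spikes are flagged unstable", {
  st <- burst_statistics(c(100, 1150))
  expect_false(st$stable)
  expect_equal(length(st$fb_samples), 1)
  st0 <- burst_statistics(numeric(0))
  expect_equal(st0$n_bursts, 0)
  expect_false(st0$stable)
})

test_that("burst grouping matches a brute-force pairwise grouper", {
  for (seed in 1:12) {
    S <- random_spike_train(n_bursts = 8, seed = seed)
    st <- burst_statistics(S)
    ref <- brute_force_groups(S, 100)
    grp <- rep(seq_along(st$bs), st$be - st$bs + 1)
    expect_equal(grp, ref, label = paste("seed", seed))
  }
})

test_that("duty cycles stay in [0,1] and frequencies positive", {
  for (seed in 13:24) {
    st <- burst_statistics(random_spike_train(6, seed))
    expect_true(all(st$dc_samples >= 0 & st$dc_samples <= 1))
    expect_true(all(st$fb_samples > 0))
  }
})

test_that("slow-wave and mid crossings are counted from the voltage trace", {
  t <- seq(0, 9999, by = 1)
  V <- -45 + 15 * sin(2 * pi * t / 1000) # 10 cycles, range [-60, -30]
  S <- c(100, 1100, 2100) # irrelevant spikes
  st <- burst_statistics(S, V, stg_thresholds(mid = c(-35, -40)))
  expect_equal(st$n_sw, 20L) # 10 downward crossings at each of -49, -51
  expect_equal(st$n_mid, c(10L, 10L))
})

test_that("inter-spike intervals are first differences", {
  expect_equal(isi_values(c(0, 10, 20)), c(10, 10))
  expect_length(isi_values(5), 0)
  expect_length(isi_values(numeric(0)), 0)
})

test_that("distinct ISI counting clusters values by relative tolerance", {
  expect_equal(distinct_isi_count(c(10, 10.05, 500)), 2)
  expect_equal(distinct_isi_count(rep(7.3, 50)), 1)
  expect_equal(distinct_isi_count(c(10, 20, 40, 80)), 4)
  # order must not matter
  expect_equal(distinct_isi_count(c(500, 10.05, 10)), 2)
  expect_error(distinct_isi_count(numeric(0)), "empty")
})
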