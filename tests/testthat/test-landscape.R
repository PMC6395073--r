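test_that("burster penalty terms match their definitions", {
  st <- mock_stats(mean_fb = 1, mean_dc = 0.2, n_sw = 20, n_bursts = 10)
  expect_equal(unname(burster_penalties(st)), c(0, 0, 0))

  st2 <- mock_stats(mean_fb = 1.1, mean_dc = 0.25, n_sw = 20, n_bursts = 10)
  terms <- burster_penalties(st2)
  expect_equal(unname(terms),
               c((1 - 1.1)^2, (0.2 - 0.25)^2, 0))
  # weighted total with (alpha, beta, gamma) = (1, 100, 1)
  tg <- burster_target()
  expect_equal(sum(tg$weights * terms), 0.01 + 100 * 0.0025,
               tolerance = 1e-12)
})

test_that("unstable statistics are refused by the burster penalties", {
  st <- mock_stats(1, 0.2, 20, 10, stable = FALSE)
  expect_error(burster_penalties(st), "discard")
})

test_that("the total error is monotone in the frequency mismatch", {
  tg <- burster_target()
  E <- sapply(seq(1, 2, by = 0.1), function(fb) {
    st <- mock_stats(fb, 0.2, 20, 10)
    sum(tg$weights * burster_penalties(st, tg))
  })
  expect_true(all(diff(E) > 0))
})

test_that("tonic penalties reward clean repolarization", {
  tg <- tonic_target(f_tg = 10)
  # ideal tonic spiker: every mid threshold crossed once per spike, no
  # slow-wave crossings, all duty cycles zero
  st <- mock_stats(10, 0, n_sw = 0, n_bursts = 100, n_spikes = 100,
                   n_mid = c(100L, 100L, 100L), dc_samples = rep(0, 99))
  terms <- tonic_penalties(st, lag = 0, tg)
  expect_equal(unname(terms), c(0, 0, 0, 0, 0))

  # hyperpolarizing below -51 once per period over 10 s at 10 Hz:
  # 100 periods x 2 slow-wave thresholds -> E_sw = 200^2
  st2 <- mock_stats(10, 0, n_sw = 200, n_bursts = 100, n_spikes = 100,
                    n_mid = c(100L, 100L, 100L))
  expect_equal(tonic_penalties(st2, 0, tg)[["E_sw"]], 200^2)

  # mid-threshold mismatch accumulates squared deviations per threshold
  st3 <- mock_stats(10, 0, n_sw = 0, n_bursts = 100, n_spikes = 100,
                    n_mid = c(90L, 110L, 100L))
  expect_equal(tonic_penalties(st3, 0, tg)[["E_mid"]], 100 + 100)
  expect_error(tonic_penalties(mock_stats(10, 0, 0, 1, n_mid = c(1L)), 0, tg),
               "mid thresholds")
})

test_that("spike-to-repolarization lag is measured between crossings", {
  # sawtooth-like spikes: rise through -20 at t = k*100, fall through -35
  # 12 ms later
  dt <- 1
  V <- rep(-60, 1000)
  for (k in seq(50, 950, by = 100)) {
    V[k + 0:3] <- c(-25, 10, -10, -30) # up-crossing of -20 at k-1..k
    V[k + 4:14] <- seq(-30, -50, length.out = 11) # down-crossing of -35
  }
  tr <- structure(list(t0 = 0, dt = dt, V = V), class = "stg_trace")
  lag <- crossing_lag(tr, -20, -35)
  expect_gt(lag, 3)
  expect_lt(lag, 9)
})

test_that("candidate scoring is deterministic and penalizes silence", {
  obj <- landscape_objective()
  x0 <- rep(0, 9) # all-zero conductances: silent cell, invalid tau_ca
  expect_equal(obj(x0), stg_penalty_score())
  silent <- c(rep(0, 8), 100)
  expect_equal(obj(silent), stg_penalty_score())

  m <- stg_models("a")
  x <- c(unname(m$g), m$tau_ca)
  s1 <- obj(x)
  s2 <- obj(x)
  expect_identical(s1, s2)
  expect_true(is.finite(s1))
})

test_that("the tonic target scores a bursting cell end to end", {
  # a burster violates the tonic slow-wave and mid-threshold requirements,
  # so every structural term must engage with a positive penalty
  sc <- score_parameters(stg_models("a"), tonic_target(f_tg = 3))
  expect_false(sc$discarded)
  expect_named(sc$terms, c("E_f", "E_dc", "E_mid", "E_sw", "E_lag"))
  expect_gt(sc$terms[["E_sw"]], 0)   # bursts cross -50 +/- 1 mV
  expect_gt(sc$terms[["E_mid"]], 0)  # mid thresholds not crossed per spike
  expect_true(is.finite(sc$score) && sc$score > 0)
})

test_that("scoring a published burster returns stats and terms", {
  sc <- score_parameters(stg_models("a"))
  expect_false(sc$discarded)
  expect_named(sc$terms, c("E_f", "E_dc", "E_sw"))
  expect_true(all(sc$terms >= 0))
  expect_equal(sc$score, sum(burster_target()$weights * sc$terms))
  expect_gte(sc$score, 0)
})
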