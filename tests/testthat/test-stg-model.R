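kin <- stg_kinetics()

test_that("gating steady states behave at their anchors", {
  # sigmoid midpoint: half-activation voltage gives m_inf = 1/2
  g <- gate_steady_state(kin, "Na", V = -25.5)
  expect_equal(g$m_inf, 0.5, tolerance = 1e-12)
  g <- gate_steady_state(kin, "Kd", V = -12.3)
  expect_equal(g$m_inf, 0.5, tolerance = 1e-12)
  expect_true(is.na(gate_steady_state(kin, "Kd", V = 0)$h_inf))

  # KCa: calcium saturation factor
  expect_lt(gate_steady_state(kin, "KCa", V = 0, Ca = 1e-9)$m_inf, 1e-8)
  # at Ca = K_half the factor is exactly 1/2 of the voltage sigmoid
  vs <- 1 / (1 + exp((-10 + 28.3) / -12.6))
  expect_equal(gate_steady_state(kin, "KCa", V = -10, Ca = 3)$m_inf,
               0.5 * vs, tolerance = 1e-12)
  expect_error(gate_steady_state(kin, "KCa", V = 0, Ca = 0), "calcium")
  expect_error(gate_steady_state(kin, "nonsense", V = 0), "unknown channel")

  # time constants positive over the physiological range
  for (v in seq(-100, 60, by = 5)) {
    r <- gate_steady_state(kin, "CaS", v)
    expect_gt(r$tau_m, 0)
    expect_gt(r$tau_h, 0)
    expect_true(r$m_inf >= 0 && r$m_inf <= 1)
    expect_true(r$h_inf >= 0 && r$h_inf <= 1)
  }
})

test_that("calcium Nernst potential follows its closed form", {
  expect_equal(nernst_calcium(3000, 3000), 0)
  expect_equal(nernst_calcium(0.05, 3000, 12.2), 12.2 * log(60000))
  expect_equal(nernst_calcium(3000 * exp(1), 3000, 12.2), -12.2)
  # monotonically decreasing in intracellular calcium
  ca <- c(0.05, 0.5, 5, 50)
  expect_true(all(diff(nernst_calcium(ca)) < 0))
  expect_error(nernst_calcium(0), "positive")
})

test_that("membrane currents follow I = g m^p h^q (V - E)", {
  s <- stg_init_state(V = -40, gates = 0.5, Ca = 5)
  p0 <- stg_parameters(rep(0, 8), tau_ca = 100)
  expect_equal(unname(membrane_currents(s, p0)), rep(0, 8))

  # leak has no gates: g = 0.1 uS, V = -40, E_leak = -50 -> 1 nA
  pl <- stg_parameters(c(leak = 0.1, Na = 0, CaT = 0, CaS = 0, A = 0,
                         KCa = 0, Kd = 0, H = 0), tau_ca = 100)
  expect_equal(membrane_currents(s, pl)[["leak"]], 1)

  # Kd at the potassium reversal carries no current
  pk <- stg_parameters(c(Kd = 100, Na = 0, CaT = 0, CaS = 0, A = 0,
                         KCa = 0, H = 0, leak = 0), tau_ca = 100)
  sk <- stg_init_state(V = -80, gates = 0.5, Ca = 5)
  expect_equal(membrane_currents(sk, pk)[["Kd"]], 0)
  # and away from it, the m^4 gating is applied
  sk2 <- stg_init_state(V = -79, gates = 0.5, Ca = 5)
  expect_equal(membrane_currents(sk2, pk)[["Kd"]], 100 * 0.5^4 * 1)
})

test_that("state derivatives implement the membrane and calcium equations", {
  p0 <- stg_parameters(rep(0, 8), tau_ca = 100)
  s <- stg_init_state()
  ds <- stg_derivatives(s, p0, Ie = 10)
  expect_equal(ds[["V"]], 1) # Ie/C = 10 nA / 10 nF

  # calcium fixed point with no calcium current
  s2 <- stg_init_state(Ca = 0.05)
  expect_equal(stg_derivatives(s2, p0)[["Ca"]], 0)

  # with a constant total calcium current of -1 nA the fixed point is
  # Ca = Ca0 + CaF = 0.99 uM; engineer the current via g_CaT at m = h = 1
  s3 <- stg_init_state(V = -51, gates = 1, Ca = 0.99)
  eca <- nernst_calcium(0.99)
  gct <- 1 / (eca - (-51))
  p3 <- stg_parameters(c(Na = 0, CaT = gct, CaS = 0, A = 0, KCa = 0,
                         Kd = 0, H = 0, leak = 0), tau_ca = 100)
  expect_equal(membrane_currents(s3, p3)[["CaT"]], -1, tolerance = 1e-12)
  expect_equal(stg_derivatives(s3, p3)[["Ca"]], 0, tolerance = 1e-12)
})

test_that("the integrated system has exactly 13 state variables", {
  expect_length(stg_init_state(), 13)
  tr <- stg_simulate(stg_parameters(rep(0, 8), tau_ca = 100), 10, 0.1)
  expect_length(tr$final_state, 13)
})

test_that("RK4 reproduces a linear ODE to its order of accuracy", {
  # leak-only cell with E_leak = 0, g/C = 1: dV/dt = -V
  p <- stg_parameters(c(Na = 0, CaT = 0, CaS = 0, A = 0, KCa = 0, Kd = 0,
                        H = 0, leak = 10), tau_ca = 100, E_leak = 0)
  init <- stg_init_state(V = 1)
  tr <- stg_simulate(p, duration = 0.1, dt = 0.1, init = init,
                     record_currents = FALSE, method = "exact")
  # one-step local truncation of RK4 at dt = 0.1 is dt^5/5! ~ 8.3e-8
  expect_equal(tr$V[1], exp(-0.1), tolerance = 1e-7)

  # halving dt reduces the global error at t = 1 by ~16x (order 4)
  err <- sapply(c(0.1, 0.05), function(dt) {
    tr <- stg_simulate(p, duration = 1, dt = dt, init = init,
                       record_currents = FALSE, method = "exact")
    abs(tr$V[length(tr$V)] - exp(-1))
  })
  expect_gt(err[1] / err[2], 12)
  expect_lt(err[1] / err[2], 20)
})

test_that("a leak-only cell converges to the leak reversal", {
  p <- stg_parameters(c(Na = 0, CaT = 0, CaS = 0, A = 0, KCa = 0, Kd = 0,
                        H = 0, leak = 0.5), tau_ca = 100)
  tr <- stg_simulate(p, duration = 500, dt = 0.1,
                     init = stg_init_state(V = 10), record_currents = FALSE)
  expect_equal(tr$V[length(tr$V)], -50, tolerance = 1e-6)
})

test_that("integration is deterministic and respects state invariants", {
  m <- stg_models("b")
  tr1 <- stg_simulate(m, 2000, 0.1, 0, record_currents = FALSE)
  tr2 <- stg_simulate(m, 2000, 0.1, 0, record_currents = FALSE)
  expect_identical(tr1$V, tr2$V)
  expect_identical(tr1$Ca, tr2$Ca)

  # calcium stays positive and gates stay boxed for the published models
  for (lab in names(stg_models())) {
    tr <- stg_simulate(stg_models(lab), 3000, 0.1, 0,
                       record_currents = FALSE)
    expect_true(all(tr$Ca > 0), label = paste("Ca > 0 for", lab))
    gates <- tr$final_state[2:12]
    expect_true(all(gates >= 0 & gates <= 1),
                label = paste("gates boxed for", lab))
  }
})

test_that("current bookkeeping closes: C dV/dt + sum(I) - Ie -> 0 with dt", {
  # a smooth subthreshold configuration so the finite-difference residual is
  # governed by its O(dt^2) truncation rather than spike curvature
  m <- stg_parameters(c(Na = 0, CaT = 0.1, CaS = 0.2, A = 0.1, KCa = 0.1,
                        Kd = 0.5, H = 0.05, leak = 0.05), tau_ca = 100)
  resid <- sapply(c(0.2, 0.1, 0.05), function(dt) {
    tr <- stg_simulate(m, 400, dt, 0, Ie = 0.2, record_currents = TRUE)
    n <- length(tr$V)
    dvdt <- (tr$V[3:n] - tr$V[1:(n - 2)]) / (2 * dt) # central difference
    r <- m$C * dvdt + rowSums(tr$I)[2:(n - 1)] - 0.2
    max(abs(r))
  })
  # the central-difference residual is O(dt^2)
  expect_gt(resid[1] / resid[2], 3)
  expect_gt(resid[2] / resid[3], 3)
})

test_that("table-interpolated and exact gating evaluations agree", {
  m <- stg_models("c")
  tr_t <- stg_simulate(m, 500, 0.1, 0, record_currents = FALSE,
                       method = "table")
  tr_e <- stg_simulate(m, 500, 0.1, 0, record_currents = FALSE,
                       method = "exact")
  expect_lt(max(abs(tr_t$V - tr_e$V)), 1e-3)
})

test_that("a diverging simulation raises an integration-failure error", {
  # too-small capacitance makes the fixed-step scheme unstable
  m <- stg_models("a")
  m$C <- 1
  expect_error(stg_simulate(m, 2000, 0.1, 0),
               class = "burstscape_integration_failure")
})

test_that("an injected-current schedule matches its scalar equivalent", {
  m <- stg_models("a")
  n <- 2000 / 0.1
  tr1 <- stg_simulate(m, 2000, 0.1, 0, Ie = 0.5, record_currents = FALSE)
  tr2 <- stg_simulate(m, 2000, 0.1, 0, Ie = rep(0.5, n),
                      record_currents = FALSE)
  expect_identical(tr1$V, tr2$V)
})

test_that("kinetics validation rejects malformed configurations", {
  bad <- tempfile(fileext = ".yaml")
  y <- yaml::read_yaml(system.file("extdata", "kinetics_liu1998.yaml",
                                   package = "burstscape"))
  y$channels <- y$channels[c(2, 1, 3:7)] # wrong order
  yaml::write_yaml(y, bad)
  expect_error(stg_kinetics(bad), "in that order")
})
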