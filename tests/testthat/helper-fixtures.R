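# shared fixtures, lazily simulated once per test run
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# model (a) under the scoring protocol (20 s, first 10 s dropped)
trace_a <- function() cached("trace_a", {
  stg_simulate(stg_models("a"), duration = 20000, dt = 0.1,
               transient = 10000, record_currents = FALSE)
})

# short fig2 trace with currents recorded, for currentscape fixtures
trace_fig2_currents <- function() cached("trace_fig2_currents", {
  stg_simulate(stg_models("fig2"), duration = 13000, dt = 0.1,
               transient = 11000, record_currents = TRUE)
})

# brute-force O(n^2) burst grouper: merge spikes pairwise closer than gap
brute_force_groups <- function(S, gap) {
  n <- length(S)
  if (n == 0) return(integer(0))
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(S[i] - S[j]) < gap && grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# random spike train with bursty structure
random_spike_train <- function(n_bursts, seed) {
  set.seed(seed)
  starts <- cumsum(stats::runif(n_bursts, 150, 2000))
  sort(unlist(lapply(starts, function(s) {
    k <- sample(1:6, 1)
    s + cumsum(c(0, stats::runif(k - 1, 5, 95)))
  })))
}

# hand-built burst_statistics-like object for penalty-term tests
mock_stats <- function(mean_fb, mean_dc, n_sw, n_bursts, n_spikes = 30,
                       n_mid = integer(0), stable = TRUE,
                       dc_samples = numeric(0)) {
  structure(list(S = numeric(0), bs = integer(0), be = integer(0),
                 fb_samples = numeric(0), dc_samples = dc_samples,
                 mean_fb = mean_fb, std_fb = 0, mean_dc = mean_dc,
                 std_dc = 0, n_bursts = n_bursts, n_sw = n_sw,
                 n_spikes = n_spikes, n_mid = n_mid, stable = stable),
            class = "burst_statistics")
}
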