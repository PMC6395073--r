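.pkg_env <- new.env(parent = emptyenv())

.default_kinetics <- function() {
  if (is.null(.pkg_env$kinetics)) .pkg_env$kinetics <- stg_kinetics()
  .pkg_env$kinetics
}

# lazily built, cached voltage lookup table (0.01 mV grid over [-150, 100])
.kinetics_table <- function(kinetics) {
  if (is.null(kinetics$cache$table)) {
    kinetics$cache$table <- .stg_build_tables_cpp(kinetics$matrix,
                                                  -150, 100, 0.01)
  }
  kinetics$cache$table
}

.state_names <- c("V", "m_Na", "h_Na", "m_CaT", "h_CaT", "m_CaS", "h_CaS",
                  "m_A", "h_A", "m_KCa", "m_Kd", "m_H", "Ca")

#' Initial state of the model
#'
#' The 13-dimensional state vector (membrane potential, 11 gating variables,
#' intracellular calcium). The default is the fixed initial condition used
#' for every simulation in the study: V = -51 mV, all gates 0 (inactivation
#' gates start fully inactivated), Ca = 5 uM.
#'
#' @param V Membrane potential (mV).
#' @param gates Either a single value for all 11 gates or a named vector.
#' @param Ca Intracellular calcium (uM), must be positive.
#' @return Named numeric vector of length 13.
#' @export
stg_init_state <- function(V = -51, gates = 0, Ca = 5) {
  if (!(Ca > 0)) stop("initial calcium must be positive")
  s <- numeric(13)
  names(s) <- .state_names
  s["V"] <- V
  g <- rep_len(gates, 11)
  if (any(g < 0 | g > 1)) stop("gates must lie in [0, 1]")
  s[2:12] <- g
  s["Ca"] <- Ca
  s
}

#' Instantaneous membrane currents
#'
#' Per-channel currents I_i = g_i m^p h^q (V - E_i) in nA (outward
#' positive), with the calcium reversal computed from the state's calcium
#' concentration via the Nernst equation.
#'
#' @param state State vector as from [stg_init_state()].
#' @param params An [stg_parameters()] object.
#' @param kinetics Gating kinetics; default the packaged set.
#' @return Named numeric vector of 8 currents (nA).
#' @export
membrane_currents <- function(state, params, kinetics = NULL) {
  if (is.null(kinetics)) kinetics <- .default_kinetics()
  I <- .stg_currents_cpp(kinetics$matrix, unname(state), unname(params$g),
                         params$Ca_out, params$nernst_prefactor,
                         unname(.reversals(params)))
  names(I) <- STG_CHANNELS
  I
}

#' Time derivatives of the model state
#'
#' Right-hand side of the model equations: dV/dt = (Ie - sum(I_i))/C, gating
#' variables relax to their voltage-(and calcium-)dependent steady states,
#' and calcium integrates the calcium currents with buffering time constant
#' tau_Ca.
#'
#' @inheritParams membrane_currents
#' @param Ie Injected current (nA).
#' @return Named numeric vector of 13 derivatives (per ms).
#' @export
stg_derivatives <- function(state, params, Ie = 0, kinetics = NULL) {
  if (is.null(kinetics)) kinetics <- .default_kinetics()
  I <- membrane_currents(state, params, kinetics)
  r <- .stg_rates_cpp(kinetics$matrix, state[["V"]], state[["Ca"]])
  ds <- numeric(13)
  names(ds) <- .state_names
  ds["V"] <- (Ie - sum(I)) / params$C
  m_idx <- c(2L, 4L, 6L, 8L, 10L, 11L, 12L)
  h_idx <- c(3L, 5L, 7L, 9L, NA, NA, NA)
  for (i in 1:7) {
    ds[m_idx[i]] <- (r[i, 1] - state[[m_idx[i]]]) / r[i, 2]
    if (!is.na(h_idx[i]))
      ds[h_idx[i]] <- (r[i, 3] - state[[h_idx[i]]]) / r[i, 4]
  }
  ds["Ca"] <- (-params$CaF * (I[["CaT"]] + I[["CaS"]]) - state[["Ca"]] +
                 params$Ca0) / params$tau_ca
  ds
}

#' Simulate the model
#'
#' Integrates the model with a fixed-step 4th-order Runge-Kutta scheme and
#' records the membrane potential, intracellular calcium and (optionally)
#' every ionic current at each retained step. Samples earlier than
#' `transient` are discarded.
#'
#' @param params An [stg_parameters()] object.
#' @param duration Total simulated time (ms), including the transient.
#' @param dt Integration step (ms); the study protocol uses 0.1 ms.
#' @param transient Initial stretch (ms) dropped from the returned record.
#' @param Ie Injected current (nA): a scalar or a step-constant schedule with
#'   one value per integration step.
#' @param init Initial state; default [stg_init_state()].
#' @param kinetics Gating kinetics; default the packaged set.
#' @param record_currents If `FALSE`, only V and Ca are recorded (saves
#'   memory on long runs).
#' @param method `"table"` (default) evaluates the voltage-dependent gating
#'   functions through a precomputed 0.01 mV lookup table with linear
#'   interpolation; `"exact"` evaluates them directly.
#' @return An object of class `stg_trace` with fields `t0`, `dt`, `V`, `I`
#'   (N x 8 matrix, channel order `stg_channels()`), `Ca`, `Ie`, `params`,
#'   `final_state`.
#' @export
stg_simulate <- function(params, duration, dt = 0.1, transient = 0, Ie = 0,
                         init = stg_init_state(), kinetics = NULL,
                         record_currents = TRUE,
                         method = c("table", "exact")) {
  method <- match.arg(method)
  if (is.null(kinetics)) kinetics <- .default_kinetics()
  stopifnot(duration > transient, transient >= 0, dt > 0)
  tab <- if (method == "table") .kinetics_table(kinetics) else NULL
  res <- .stg_integrate_cpp(kinetics$matrix, unname(params$g), params$tau_ca,
                            params$C, params$Ca0, params$CaF, params$Ca_out,
                            params$nernst_prefactor,
                            unname(.reversals(params)), as.numeric(Ie), dt,
                            duration, transient, unname(init),
                            record_currents, tab)
  if (isTRUE(res$failed)) {
    stop(structure(class = c("burstscape_integration_failure", "error",
                             "condition"),
                   list(message = sprintf(
                     "integration failed (non-finite state) at step %d (t = %.3f ms)",
                     as.integer(res$step), res$time_ms),
                     call = sys.call(-1))))
  }
  I <- if (record_currents) {
    colnames(res$I) <- STG_CHANNELS
    res$I
  } else NULL
  fs <- res$final_state
  names(fs) <- .state_names
  structure(list(t0 = res$t0, dt = dt, V = res$V, I = I, Ca = res$Ca,
                 Ie = Ie, params = params, final_state = fs,
                 method = method),
            class = "stg_trace")
}

#' @export
print.stg_trace <- function(x, ...) {
  n <- length(x$V)
  cat(sprintf("STG trace: %d samples, dt = %g ms, window [%g, %g] ms\n",
              n, x$dt, x$t0, x$t0 + n * x$dt))
  cat(sprintf("  V range [%.2f, %.2f] mV; currents %srecorded\n",
              min(x$V), max(x$V), if (is.null(x$I)) "not " else ""))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace An `stg_trace`.
#' @return Numeric vector of sample times (ms).
#' @export
trace_times <- function(trace) trace$t0 + trace$dt * seq_along(trace$V)
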