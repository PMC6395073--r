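#' Bursting-activity optimization target
#'
#' Defines the landscape function for bursters: squared mismatches of the
#' mean burst frequency and duty cycle to their targets, plus a term asking
#' that the slow wave crosses its thresholds exactly once per burst,
#' E(g) = alpha*Ef + beta*Edc + gamma*Esw with
#' Ef = (f_tg - <fb>)^2, Edc = (dc_tg - <dc>)^2, Esw = (#sw/2 - #b)^2
#' (the factor 1/2 accounts for counting crossings at both slow-wave
#' thresholds).
#'
#' @param f_tg Target burst frequency (Hz), default 1.
#' @param dc_tg Target duty cycle, default 0.2.
#' @param weights Weights (alpha, beta, gamma), default c(1, 100, 1).
#' @param duration,transient,dt Simulation protocol (ms): 20 s total, first
#'   10 s dropped, dt = 0.1 ms.
#' @param thresholds An [stg_thresholds()] object.
#' @return An object of class `burster_target`.
#' @export
burster_target <- function(f_tg = 1, dc_tg = 0.2, weights = c(1, 100, 1),
                           duration = 20000, transient = 10000, dt = 0.1,
                           thresholds = stg_thresholds()) {
  structure(list(f_tg = f_tg, dc_tg = dc_tg, weights = weights,
                 duration = duration, transient = transient, dt = dt,
                 thresholds = thresholds),
            class = c("burster_target", "stg_target"))
}

#' Tonic-spiking optimization target
#'
#' Landscape function for tonic spikers: the duty-cycle target is zero, mid
#' thresholds between the spike and slow-wave thresholds must each be
#' crossed downward exactly once per spike, the membrane must never cross
#' the slow-wave thresholds, and a lag term separates tonic spikers from
#' single-spike bursters:
#' E(g) = alpha*Ef + beta*Edc + gamma*Emid + delta*Esw + eta*Elag with
#' Emid = sum_i (#mid_i - #s)^2 and Esw = (#sw)^2.
#'
#' @param f_tg Target spike frequency (Hz).
#' @param weights Weights (alpha, beta, gamma, delta, eta), default
#'   c(1000, 1000, 100, 100, 1).
#' @param mid Mid thresholds (mV).
#' @param duration,transient,dt Simulation protocol (ms).
#' @param thresholds An [stg_thresholds()] object (mid thresholds are set
#'   from `mid`).
#' @return An object of class `tonic_target`.
#' @export
tonic_target <- function(f_tg = 5, weights = c(1000, 1000, 100, 100, 1),
                         mid = c(-35, -40, -45), duration = 20000,
                         transient = 10000, dt = 0.1,
                         thresholds = stg_thresholds(mid = mid)) {
  thresholds$mid <- mid
  structure(list(f_tg = f_tg, dc_tg = 0, weights = weights, mid = mid,
                 duration = duration, transient = transient, dt = dt,
                 thresholds = thresholds),
            class = c("tonic_target", "stg_target"))
}

#' Burster penalty terms
#'
#' @param stats A stable [burst_statistics()] object.
#' @param target A [burster_target()].
#' @return Named vector (E_f, E_dc, E_sw).
#' @export
burster_penalties <- function(stats, target = burster_target()) {
  if (!isTRUE(stats$stable)) {
    stop("burster penalties are only defined for stable statistics; ",
         "unstable solutions are discarded")
  }
  c(E_f = (target$f_tg - stats$mean_fb)^2,
    E_dc = (target$dc_tg - stats$mean_dc)^2,
    E_sw = (stats$n_sw / 2 - stats$n_bursts)^2)
}

#' Spike-to-repolarization lag
#'
#' Mean lag (ms) between each upward crossing of the spike threshold and the
#' first subsequent downward crossing of the reference mid threshold.
#' Upward crossings with no subsequent mid crossing contribute the mean ISI
#' as a cap.
#'
#' @param trace An `stg_trace`.
#' @param t_spk Spike threshold (mV), upward.
#' @param t_mid Mid threshold (mV), downward.
#' @return Mean lag in ms (0 when there are no spikes).
#' @export
crossing_lag <- function(trace, t_spk = -20, t_mid = -35) {
  up <- detect_crossings(trace$V, t_spk, "up")
  down <- detect_crossings(trace$V, t_mid, "down")
  if (length(up) == 0) return(0)
  isi_cap <- if (length(up) >= 2) mean(diff(up)) * trace$dt else
    length(trace$V) * trace$dt
  lags <- vapply(up, function(u) {
    d <- down[down > u]
    if (length(d) == 0) isi_cap else (d[1] - u) * trace$dt
  }, numeric(1))
  mean(lags)
}

#' Tonic-spiker penalty terms
#'
#' @param stats A [burst_statistics()] object computed with the target's mid
#'   thresholds.
#' @param lag Lag value from [crossing_lag()].
#' @param target A [tonic_target()].
#' @return Named vector (E_f, E_dc, E_mid, E_sw, E_lag).
#' @export
tonic_penalties <- function(stats, lag, target = tonic_target()) {
  if (length(stats$n_mid) != length(target$mid)) {
    stop("statistics were not computed with the target's mid thresholds")
  }
  c(E_f = (target$f_tg - stats$mean_fb)^2,
    E_dc = (target$dc_tg - stats$mean_dc)^2,
    E_mid = sum((stats$n_mid - stats$n_spikes)^2),
    E_sw = stats$n_sw^2,
    E_lag = lag)
}

#' Score a parameter set against a target
#'
#' Simulates the model under the target's protocol, measures the trace and
#' combines the penalty terms with the target's weights. Solutions that fail
#' to integrate, produce fewer than 3 spikes, or are flagged unstable
#' (non-stationary burst frequency or duty cycle) are discarded and receive
#' a fixed penalty score of 1e6.
#'
#' @param params An [stg_parameters()] object.
#' @param target A [burster_target()] or [tonic_target()].
#' @param kinetics Gating kinetics; default the packaged set.
#' @param method Integrator evaluation mode, see [stg_simulate()].
#' @return A list with `score`, `terms` (the raw penalty terms), `stats`,
#'   and `discarded`.
#' @export
score_parameters <- function(params, target = burster_target(),
                             kinetics = NULL, method = "table") {
  tr <- tryCatch(
    stg_simulate(params, duration = target$duration, dt = target$dt,
                 transient = target$transient, kinetics = kinetics,
                 record_currents = FALSE, method = method),
    burstscape_integration_failure = function(e) NULL)
  if (is.null(tr)) {
    return(list(score = stg_penalty_score(), terms = NULL, stats = NULL,
                discarded = TRUE, reason = "integration failure"))
  }
  stats <- trace_statistics(tr, target$thresholds)
  tonic <- inherits(target, "tonic_target")
  if (!tonic && !isTRUE(stats$stable)) {
    return(list(score = stg_penalty_score(), terms = NULL, stats = stats,
                discarded = TRUE, reason = "unstable or too few spikes"))
  }
  if (tonic) {
    if (stats$n_spikes < 3 || length(stats$fb_samples) < 2) {
      return(list(score = stg_penalty_score(), terms = NULL, stats = stats,
                  discarded = TRUE, reason = "too few spikes"))
    }
    lag <- crossing_lag(tr, target$thresholds$spike, -35)
    terms <- tonic_penalties(stats, lag, target)
  } else {
    terms <- burster_penalties(stats, target)
  }
  list(score = sum(target$weights * terms), terms = terms, stats = stats,
       discarded = FALSE)
}

#' Penalty score assigned to discarded candidates
#'
#' Finite (1e6) so an optimizer can still rank failures below any behaving
#' solution.
#'
#' @return The penalty score.
#' @export
stg_penalty_score <- function() 1e6

#' Objective function over the 9-dimensional search space
#'
#' Returns a function mapping a candidate vector (8 maximal conductances in
#' channel order followed by tau_Ca) to its landscape score, suitable for
#' [ga_minimize()].
#'
#' @param target A [burster_target()] or [tonic_target()].
#' @param kinetics Gating kinetics; default the packaged set.
#' @param method Integrator evaluation mode.
#' @return A function `f(x)` returning a finite scalar score.
#' @export
landscape_objective <- function(target = burster_target(), kinetics = NULL,
                                method = "table") {
  if (is.null(kinetics)) kinetics <- .default_kinetics()
  function(x) {
    stopifnot(length(x) == 9)
    p <- tryCatch(stg_parameters(x[1:8], tau_ca = x[9]),
                  error = function(e) NULL)
    if (is.null(p)) return(stg_penalty_score())
    score_parameters(p, target, kinetics = kinetics, method = method)$score
  }
}
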