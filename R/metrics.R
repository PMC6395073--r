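#' Threshold set for trace characterization
#'
#' Thresholds used to characterize a voltage trace: the spike-detection
#' threshold (upward crossings), a pair of slow-wave thresholds (downward
#' crossings, used to verify that spiking is well separated from the slow
#' wave), optional mid thresholds for tonic-spiking targets, and the
#' inter-spike gap below which two spikes belong to the same burst.
#'
#' @param spike Spike detection threshold (mV), upward crossings.
#' @param slow_wave Two slow-wave thresholds (mV), downward crossings.
#' @param mid Mid thresholds (mV), downward crossings (tonic targets).
#' @param burst_gap Maximum intra-burst inter-spike interval (ms).
#' @return An object of class `stg_thresholds`.
#' @export
stg_thresholds <- function(spike = -20, slow_wave = c(-49, -51),
                           mid = numeric(0), burst_gap = 100) {
  if (length(slow_wave) != 2) stop("exactly two slow-wave thresholds required")
  if (!(burst_gap > 0)) stop("burst_gap must be positive")
  structure(list(spike = spike, slow_wave = slow_wave, mid = mid,
                 burst_gap = burst_gap),
            class = "stg_thresholds")
}

#' Threshold crossings of a sequence
#'
#' Indices at which a sequence crosses a threshold. An upward crossing at
#' index n means `x[n] <= threshold` and `x[n+1] > threshold`; a downward
#' crossing means `x[n] >= threshold` and `x[n+1] < threshold`.
#'
#' @param x Numeric sequence (length >= 2).
#' @param threshold Threshold value.
#' @param direction `"up"` or `"down"`.
#' @return Integer vector of crossing indices n (1-based, possibly empty).
#' @export
detect_crossings <- function(x, threshold, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(x) < 2) stop("sequence must have at least 2 samples")
  a <- x[-length(x)]
  b <- x[-1]
  .crossings(a, b, threshold, direction)
}

# crossing indices from pre-shifted copies (shared across thresholds)
.crossings <- function(a, b, threshold, direction) {
  if (direction == "up") which(a <= threshold & b > threshold)
  else which(a >= threshold & b < threshold)
}

#' Spike times of a voltage trace
#'
#' Upward crossings of the spike threshold, in ms.
#'
#' @param trace An `stg_trace`.
#' @param threshold Spike threshold (mV).
#' @return Numeric vector of spike times (ms).
#' @export
spike_times <- function(trace, threshold = -20) {
  idx <- detect_crossings(trace$V, threshold, "up")
  trace$t0 + trace$dt * idx
}

# group sorted spike times into bursts: spikes closer than `gap` share a burst
.burst_groups <- function(S, gap) {
  if (length(S) == 0) return(integer(0))
  c(0L, cumsum(diff(S) >= gap)) + 1L
}

#' Burst statistics of a spike train
#'
#' Segments a spike-time sequence into bursts (two spikes closer than
#' `burst_gap` belong to the same burst), and for every burst followed by
#' another spike derives one sample of the burst frequency f_b = 1/tau_b and
#' the duty cycle d_c = delta_b/tau_b, where delta_b is the burst duration
#' and tau_b the burst period (duration plus the gap to the next burst's
#' first spike). A lone spike is a burst of duration zero. Also counts
#' downward crossings at the two slow-wave thresholds (summed) and at any
#' mid thresholds, and flags the train unstable when the per-burst frequency
#' (duty cycle) spreads beyond 10% (20%) of its mean.
#'
#' @param S Sorted spike times (ms).
#' @param V Voltage sequence the spikes came from (for threshold-crossing
#'   counts); may be `NULL`, in which case crossing counts are `NA`.
#' @param thresholds An [stg_thresholds()] object.
#' @return An object of class `burst_statistics`: list with `S`, `bs`, `be`
#'   (burst start/end indices into `S`), `fb_samples` (Hz), `dc_samples`,
#'   `mean_fb`, `std_fb`, `mean_dc`, `std_dc`, `n_bursts`, `n_sw`,
#'   `n_spikes`, `n_mid`, `stable`.
#' @export
burst_statistics <- function(S, V = NULL, thresholds = stg_thresholds()) {
  if (is.unsorted(S)) stop("spike times must be sorted ascending")
  n_sw <- n_mid <- NA_integer_
  if (!is.null(V)) {
    a <- V[-length(V)]
    b <- V[-1]
    n_sw <- sum(vapply(thresholds$slow_wave, function(tt)
      length(.crossings(a, b, tt, "down")), integer(1)))
    n_mid <- vapply(thresholds$mid, function(tt)
      length(.crossings(a, b, tt, "down")), integer(1))
  }
  grp <- .burst_groups(S, thresholds$burst_gap)
  n_grp <- if (length(grp)) max(grp) else 0L
  bs <- which(c(TRUE, diff(grp) > 0))
  be <- c(bs[-1] - 1L, length(S))[seq_len(length(bs))]
  fb <- dc <- numeric(0)
  if (n_grp >= 2) {
    for (j in seq_len(n_grp - 1L)) {
      i0 <- bs[j]; i1 <- be[j]
      delta_b <- S[i1] - S[i0]
      tau_b <- delta_b + (S[i1 + 1L] - S[i1])
      fb <- c(fb, 1000 / tau_b)
      dc <- c(dc, delta_b / tau_b)
    }
  }
  mean_fb <- if (length(fb)) mean(fb) else NA_real_
  mean_dc <- if (length(dc)) mean(dc) else NA_real_
  std_fb <- if (length(fb) >= 2) stats::sd(fb) else NA_real_
  std_dc <- if (length(dc) >= 2) stats::sd(dc) else NA_real_
  stable <- length(S) >= 3 && length(fb) >= 2 &&
    std_fb < mean_fb * 0.1 && std_dc < mean_dc * 0.2
  structure(list(S = S, bs = bs, be = be, fb_samples = fb, dc_samples = dc,
                 mean_fb = mean_fb, std_fb = std_fb, mean_dc = mean_dc,
                 std_dc = std_dc, n_bursts = n_grp, n_sw = n_sw,
                 n_spikes = length(S), n_mid = n_mid, stable = stable,
                 thresholds = thresholds),
            class = "burst_statistics")
}

#' @export
print.burst_statistics <- function(x, ...) {
  cat(sprintf("burst statistics: %d spikes, %d bursts (%d periods)\n",
              x$n_spikes, x$n_bursts, length(x$fb_samples)))
  if (length(x$fb_samples)) {
    cat(sprintf("  <fb> = %.4f Hz (sd %.4g), <dc> = %.4f (sd %.4g)\n",
                x$mean_fb, x$std_fb, x$mean_dc, x$std_dc))
  }
  cat(sprintf("  slow-wave crossings = %s, stable = %s\n",
              format(x$n_sw), x$stable))
  invisible(x)
}

#' Burst statistics of a simulated trace
#'
#' Detects spikes on the trace and computes [burst_statistics()].
#'
#' @param trace An `stg_trace`.
#' @param thresholds An [stg_thresholds()] object.
#' @return A `burst_statistics` object.
#' @export
trace_statistics <- function(trace, thresholds = stg_thresholds()) {
  S <- spike_times(trace, thresholds$spike)
  burst_statistics(S, trace$V, thresholds)
}

#' Inter-spike intervals
#'
#' @param S Sorted spike times (ms).
#' @return First differences of `S` (ms); empty for fewer than 2 spikes.
#' @export
isi_values <- function(S) {
  if (length(S) < 2) return(numeric(0))
  diff(S)
}

#' Count distinct inter-spike-interval values
#'
#' Clusters ISI values by single linkage with a relative tolerance: two
#' values join the same cluster when they differ by less than `rel_tol`
#' times the smaller value. Used to classify periodic regimes (one value =
#' tonic spiking, small sets = periodic bursting, dense bands = aperiodic).
#'
#' @param isis Non-empty numeric vector of ISIs (ms).
#' @param rel_tol Relative tolerance (default 2%).
#' @return Integer number of clusters.
#' @export
distinct_isi_count <- function(isis, rel_tol = 0.02) {
  if (length(isis) == 0) stop("empty ISI sequence")
  x <- sort(isis)
  sum(c(TRUE, diff(x) > rel_tol * x[-length(x)]))
}
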