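#' Simulation protocol profiles
#'
#' Two named protocol profiles for the perturbation drivers. `"desk"` is the
#' scaled-down default used throughout the package and its tests; `"published"`
#' reproduces the published protocol sizes (long transients, fine grids,
#' high-resolution time step) and is correspondingly slow.
#'
#' @param profile `"desk"` or `"published"`.
#' @return A list of protocol settings (ms and counts) for the distribution
#'   sweeps (`dist_*`), the injected-current scans (`scan_*`), and the
#'   number of sweep/scan levels.
#' @export
stg_profile <- function(profile = c("desk", "published")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    list(name = "desk",
         dist_dt = 0.01, dist_transient = 30000, dist_duration = 60000,
         scan_dt = 0.1, scan_transient = 10000, scan_duration = 20000,
         n_levels = 101)
  } else {
    list(name = "published",
         dist_dt = 0.001, dist_transient = 120000, dist_duration = 150000,
         scan_dt = 0.1, scan_transient = 240000, scan_duration = 580000,
         n_levels = 1001)
  }
}

#' Traces under graded conductance decrements
#'
#' Simulates the model with one maximal conductance scaled to each level in
#' `levels` (always restarting from the same fixed initial condition) and
#' characterizes each trace.
#'
#' @param params An [stg_parameters()] object.
#' @param channel Channel to scale (see [stg_channels()]).
#' @param levels Scale factors in [0, 1], default 11 values 1 -> 0.
#' @param duration,transient,dt Simulation protocol (ms).
#' @param thresholds Thresholds for the burst statistics.
#' @param keep_traces If `FALSE`, traces are dropped after measuring
#'   (memory-friendly for fine level grids).
#' @param record_currents Record per-channel currents in kept traces.
#' @param kinetics,method Passed to [stg_simulate()].
#' @return A list of class `decrement_sweep`: per level a list with
#'   `level`, `failed`, `trace` (or `NULL`), and `stats`.
#' @export
decrement_traces <- function(params, channel,
                             levels = seq(1, 0, length.out = 11),
                             duration = 20000, transient = 10000, dt = 0.1,
                             thresholds = stg_thresholds(),
                             keep_traces = TRUE, record_currents = FALSE,
                             kinetics = NULL, method = "table") {
  ci <- match(channel, STG_CHANNELS)
  if (is.na(ci)) stop("unknown channel: ", channel)
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  out <- lapply(levels, function(lev) {
    p <- params
    p$g[ci] <- p$g[ci] * lev
    tr <- tryCatch(
      stg_simulate(p, duration = duration, dt = dt, transient = transient,
                   kinetics = kinetics, record_currents = record_currents,
                   method = method),
      burstscape_integration_failure = function(e) NULL)
    if (is.null(tr)) {
      return(list(level = lev, failed = TRUE, trace = NULL, stats = NULL))
    }
    st <- trace_statistics(tr, thresholds)
    list(level = lev, failed = FALSE,
         trace = if (keep_traces) tr, stats = st)
  })
  structure(out, class = "decrement_sweep", channel = channel)
}

#' Complete removal of one current
#'
#' Equivalent to [decrement_traces()] at a single level of 0.
#'
#' @inheritParams decrement_traces
#' @param ... Passed to [decrement_traces()].
#' @return A list with `trace` and `stats` (and `failed`).
#' @export
delete_channel <- function(params, channel, ...) {
  decrement_traces(params, channel, levels = 0, ...)[[1]]
}

#' Inter-spike-interval scan over injected current
#'
#' Simulates the model at each injected-current value (each level restarted
#' from the same fixed initial condition), collects the full multiset of
#' inter-spike intervals from the retained window, and summarizes each
#' level by its distinct-ISI count (2% single-linkage clusters), maximum
#' ISI, and mean firing rate. Levels with fewer than 2 spikes yield an
#' empty ISI set and are flagged silent.
#'
#' @param params An [stg_parameters()] object.
#' @param I_range Injected-current range (nA), default -1..5.
#' @param n_levels Number of equally spaced current values (>= 2). The
#'   published scans use 1001 levels over 240 s windows; the default desk
#'   protocol is far coarser.
#' @param duration,transient,dt Simulation protocol (ms).
#' @param spike_threshold Spike detection threshold (mV).
#' @param rel_tol Relative tolerance for the distinct-ISI clustering.
#' @param kinetics,method Passed to [stg_simulate()].
#' @return An object of class `isi_scan`: list with `Ie` (nA), `isis`
#'   (list of ISI vectors, ms), and a `summary` data frame (columns `Ie`,
#'   `n_spikes`, `n_distinct`, `max_isi`, `mean_rate`, `silent`, `failed`).
#' @export
injection_scan <- function(params, I_range = c(-1, 5), n_levels = 25,
                           duration = 20000, transient = 10000, dt = 0.1,
                           spike_threshold = -20, rel_tol = 0.02,
                           kinetics = NULL, method = "table") {
  if (n_levels < 2) stop("n_levels must be at least 2")
  Ie <- seq(I_range[1], I_range[2], length.out = n_levels)
  isis <- vector("list", n_levels)
  summ <- data.frame(Ie = Ie, n_spikes = NA_integer_,
                     n_distinct = NA_integer_, max_isi = NA_real_,
                     mean_rate = NA_real_, silent = FALSE, failed = FALSE)
  retained <- (duration - transient) / 1000 # seconds
  for (li in seq_len(n_levels)) {
    tr <- tryCatch(
      stg_simulate(params, duration = duration, dt = dt,
                   transient = transient, Ie = Ie[li], kinetics = kinetics,
                   record_currents = FALSE, method = method),
      burstscape_integration_failure = function(e) NULL)
    if (is.null(tr)) {
      summ$failed[li] <- TRUE
      isis[[li]] <- numeric(0)
      next
    }
    S <- spike_times(tr, spike_threshold)
    v <- isi_values(S)
    isis[[li]] <- v
    summ$n_spikes[li] <- length(S)
    summ$silent[li] <- length(v) == 0
    if (length(v)) {
      summ$n_distinct[li] <- distinct_isi_count(v, rel_tol)
      summ$max_isi[li] <- max(v)
    }
    summ$mean_rate[li] <- length(S) / retained
  }
  structure(list(Ie = Ie, isis = isis, summary = summ),
            class = "isi_scan")
}

#' @export
print.isi_scan <- function(x, ...) {
  cat(sprintf("ISI scan: %d injected-current levels in [%g, %g] nA\n",
              length(x$Ie), min(x$Ie), max(x$Ie)))
  print(utils::head(x$summary, 10))
  if (length(x$Ie) > 10) cat("...\n")
  invisible(x)
}

#' Plot an ISI scan as a bifurcation diagram
#'
#' All ISI values per injected-current level, ISI on a log axis.
#'
#' @param x An `isi_scan`.
#' @param file Optional png/pdf output path.
#' @param ... Ignored.
#' @return `file`, invisibly.
#' @export
plot.isi_scan <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 700, height = 500),
           pdf = grDevices::pdf(file, width = 7, height = 5),
           stop("unsupported image format: ", ext))
    on.exit(grDevices::dev.off())
  }
  xs <- rep(x$Ie, vapply(x$isis, length, integer(1)))
  ys <- unlist(x$isis)
  if (!length(ys)) stop("scan produced no ISIs")
  graphics::plot(xs, ys, log = "y", pch = ".", cex = 2,
                 xlab = "injected current (nA)", ylab = "ISI (ms)")
  invisible(file)
}
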