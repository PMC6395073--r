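#' Histogram bin edges for membrane potential or current shares
#'
#' Default binning used by the sweep histograms: `n_bins` = 1001 bins over
#' (-70, 35) mV for the membrane potential, or over [0, 1] for current
#' shares.
#'
#' @param variable `"V"` or `"share"`.
#' @param n_bins Number of bins.
#' @param range Range covered by the bins.
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
stg_bin_edges <- function(variable = c("V", "share"), n_bins = 1001,
                          range = NULL) {
  variable <- match.arg(variable)
  if (is.null(range)) range <- if (variable == "V") c(-70, 35) else c(0, 1)
  seq(range[1], range[2], length.out = n_bins + 1)
}

#' Histogram of randomly sampled trace values
#'
#' Draws `n_samples` time stamps uniformly with replacement from a recorded
#' sequence (emulating sampling the solution at random times) and histograms
#' the sampled values. Bins are half-open `[lo, hi)` with the last bin
#' closed; values outside the edge range are counted in the first/last bin
#' and flagged with a warning. With `n_samples = NULL` every sample of the
#' sequence is used once (the difference is sampling noise only).
#'
#' @param x Numeric sequence (length >= 2).
#' @param edges Strictly increasing bin edges.
#' @param n_samples Number of random draws (default 2e6), or `NULL`.
#' @param seed Integer seed for the random time stamps.
#' @return Integer vector of counts (length `length(edges) - 1`) with
#'   attribute `clipped` giving the number of out-of-range samples.
#' @export
sample_histogram <- function(x, edges, n_samples = 2e6, seed = 1) {
  if (length(x) < 2) stop("sequence must have at least 2 samples")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (!is.null(n_samples)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    x <- x[sample.int(length(x), n_samples, replace = TRUE)]
  }
  hi <- edges[length(edges)] # last bin is closed: x == hi is in range
  n_clip <- sum(x < edges[1] | x > hi)
  if (n_clip > 0) {
    warning(sprintf("%d samples outside the bin range were clipped to edge bins",
                    n_clip))
    x <- pmin(pmax(x, edges[1]), hi)
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  attr(counts, "clipped") <- n_clip
  counts
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ridge-enhanced histogram map
#'
#' Applies the display transform log10(counts + 1) and differentiates it
#' along the bin (V) axis by central finite differences, separately for each
#' level row. Ridges of the underlying distribution (waveform extrema such
#' as spike amplitudes and troughs) appear as sign changes.
#'
#' @param counts levels x bins matrix of non-negative counts (a single
#'   histogram vector is treated as one row).
#' @return Real matrix of the same shape: d/dbin of log10(counts + 1).
#' @export
ridge_map <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  lp <- log10(counts + 1)
  nb <- ncol(lp)
  if (nb < 3) stop("need at least 3 bins")
  out <- matrix(0, nrow(lp), nb)
  out[, 2:(nb - 1)] <- (lp[, 3:nb] - lp[, 1:(nb - 2)]) / 2
  out[, 1] <- lp[, 2] - lp[, 1]
  out[, nb] <- lp[, nb] - lp[, nb - 1]
  out
}

#' Distribution of an observable under a graded conductance sweep
#'
#' For each decrement level, simulates the model with one maximal
#' conductance scaled by the level and histograms an observable over the
#' retained window: the membrane potential, or one current's share of the
#' total outward/inward current (the currentscape normalization). Row 1
#' corresponds to the first level (levels default to descending 1 -> 0 so
#' row 1 is the control).
#'
#' @param params An [stg_parameters()] object.
#' @param channel Channel whose conductance is swept (see [stg_channels()]).
#' @param observable `"V"` or `"share"`.
#' @param share_channel Channel whose share is histogrammed (defaults to
#'   `channel`); only used for `observable = "share"`.
#' @param share_sign `"out"` or `"in"`: which total the share refers to.
#' @param levels Decreasing scale factors in [0, 1]; default 11 levels 1..0.
#'   (The published maps use 1001 levels.)
#' @param duration,transient,dt Simulation protocol (ms). The default desk
#'   profile (30 s retained after a 30 s transient at dt = 0.01 ms) is
#'   scaled down from the published one (30 s after 120 s at dt = 0.001 ms),
#'   which is available as `stg_profile("published")`.
#' @param n_bins,range Histogram binning (see [stg_bin_edges()]).
#' @param n_samples Random samples per level (default 2e6); `NULL` uses all.
#' @param seed Seed for the random time stamps.
#' @param kinetics,method Passed to [stg_simulate()].
#' @return An object of class `sweep_histogram`: list with `counts`
#'   (levels x bins), `edges`, `levels`, `variable`, `failed` (per-level
#'   flag), `samples_per_level`, `seed`.
#' @export
sweep_distribution <- function(params, channel, observable = c("V", "share"),
                               share_channel = channel,
                               share_sign = c("out", "in"),
                               levels = seq(1, 0, length.out = 11),
                               duration = 60000, transient = 30000, dt = 0.01,
                               n_bins = 1001, range = NULL, n_samples = 2e6,
                               seed = 1, kinetics = NULL, method = "table") {
  observable <- match.arg(observable)
  share_sign <- match.arg(share_sign)
  ci <- match(channel, STG_CHANNELS)
  if (is.na(ci)) stop("unknown channel: ", channel)
  si <- match(share_channel, STG_CHANNELS)
  if (is.na(si)) stop("unknown share channel: ", share_channel)
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  edges <- stg_bin_edges(if (observable == "V") "V" else "share",
                         n_bins, range)
  counts <- matrix(0L, length(levels), n_bins)
  failed <- logical(length(levels))
  for (li in seq_along(levels)) {
    p <- params
    p$g[ci] <- p$g[ci] * levels[li]
    tr <- tryCatch(
      stg_simulate(p, duration = duration, dt = dt, transient = transient,
                   kinetics = kinetics, method = method,
                   record_currents = observable == "share"),
      burstscape_integration_failure = function(e) NULL)
    if (is.null(tr)) {
      failed[li] <- TRUE
      next
    }
    x <- if (observable == "V") tr$V else {
      sn <- split_and_normalize(tr$I)
      if (share_sign == "out") sn$C_out[si, ] else sn$C_in[si, ]
    }
    counts[li, ] <- suppressWarnings(
      sample_histogram(x, edges, n_samples = n_samples, seed = seed))
  }
  structure(list(counts = counts, edges = edges, levels = levels,
                 variable = observable, channel = channel,
                 share_channel = if (observable == "share") share_channel,
                 failed = failed,
                 samples_per_level = if (is.null(n_samples)) NA_real_
                                     else n_samples,
                 seed = seed),
            class = "sweep_histogram")
}

#' @export
print.sweep_histogram <- function(x, ...) {
  cat(sprintf("sweep histogram of %s: %d levels x %d bins (%d failed levels)\n",
              x$variable, length(x$levels), ncol(x$counts), sum(x$failed)))
  invisible(x)
}

#' Plot a sweep histogram as a ridge map
#'
#' Displays log10(p + 1) in gray scale or its V-derivative ridge enhancement
#' in a diverging palette, levels on the x axis and the observable on the y
#' axis.
#'
#' @param x A `sweep_histogram`.
#' @param ridges If `TRUE` plot the ridge-enhanced derivative map.
#' @param file Optional png/pdf output path.
#' @param ... Ignored.
#' @return `file`, invisibly.
#' @export
plot.sweep_histogram <- function(x, ridges = TRUE, file = NULL, ...) {
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 700, height = 600),
           pdf = grDevices::pdf(file, width = 7, height = 6),
           stop("unsupported image format: ", ext))
    on.exit(grDevices::dev.off())
  }
  mids <- (x$edges[-1] + x$edges[-length(x$edges)]) / 2
  z <- if (ridges) ridge_map(x$counts) else log10(x$counts + 1)
  col <- if (ridges) {
    grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(255)
  } else grDevices::gray.colors(255, start = 1, end = 0)
  zlim <- if (ridges) c(-1, 1) * max(abs(z)) else c(0, max(z))
  graphics::image(x = seq_along(x$levels), y = mids, z = z, zlim = zlim,
                  col = col, xlab = "level index (1 = control)",
                  ylab = if (x$variable == "V") "V (mV)" else "share",
                  useRaster = TRUE)
  invisible(file)
}
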