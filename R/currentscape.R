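#' Split currents by sign and normalize to shares
#'
#' Separates an 8 x N (or N x 8) current matrix into outward and inward
#' parts and normalizes each column by its total, yielding the per-time-step
#' percent contribution ("share") of each current. Outward shares are built
#' from the positive entries; inward shares from the magnitudes of the
#' negative entries.
#'
#' @param I Current matrix in nA, either 8 x N (channels in rows) or N x 8
#'   as recorded in an `stg_trace`; channel order `stg_channels()`.
#' @return A list with `C_out`, `C_in` (8 x N share matrices whose columns
#'   sum to 1 where the total is positive and to 0 otherwise), `n_out`,
#'   `n_in` (N-vectors of total outward/inward current, nA), and
#'   `empty_out`, `empty_in` (logical flags for zero-total columns).
#' @export
split_and_normalize <- function(I) {
  if (is.null(dim(I)) || !length(dim(I)) == 2) stop("I must be a matrix")
  if (ncol(I) == 8 && nrow(I) != 8) I <- t(I)
  if (nrow(I) != 8) stop("current matrix must have 8 channels")
  if (any(!is.finite(I))) stop("current matrix contains non-finite values")
  pos <- pmax(I, 0)
  neg <- pmax(-I, 0)
  n_out <- colSums(pos)
  n_in <- colSums(neg)
  div <- function(M, n) sweep(M, 2, ifelse(n > 0, n, 1), "/") *
    rep(as.numeric(n > 0), each = 8)
  list(C_out = div(pos, n_out), C_in = div(neg, n_in),
       n_out = n_out, n_in = n_in,
       empty_out = n_out == 0, empty_in = n_in == 0)
}

#' Rasterize share columns into a pixel index image
#'
#' Converts an 8 x N matrix of per-time-step shares into an R x N integer
#' image: each column is divided into contiguous vertical bands, one per
#' channel in fixed channel order, with band boundaries at the cumulative
#' shares scaled by the resolution R (pixel row i belongs to channel k when
#' the cumulative share boundary of channels < k lies at or below i and the
#' next boundary lies above it). Columns with zero total are filled with NA.
#'
#' @param shares 8 x N share matrix (columns sum to 1 or 0).
#' @param R Vertical resolution (number of pixel rows), default 2000.
#' @return R x N integer matrix with entries 1..8 (channel index) or NA.
#' @export
build_cs_matrix <- function(shares, R = 2000) {
  if (nrow(shares) != 8) stop("share matrix must have 8 rows")
  if (any(shares < 0) || any(shares > 1 + 1e-9)) {
    stop("shares must lie in [0, 1]")
  }
  n <- ncol(shares)
  cs <- matrix(NA_integer_, nrow = R, ncol = n)
  csum <- apply(shares, 2, cumsum) # 8 x n cumulative boundaries (fraction)
  tot <- csum[8, ]
  for (j in seq_len(n)) {
    if (tot[j] <= 0) next
    bounds <- floor(c(0, csum[, j]) * R) # 9 boundaries in pixel units
    # for unit-sum columns the final band absorbs the rounding remainder so
    # exactly R rows are assigned; sub-unit columns leave the top rows NA
    if (abs(tot[j] - 1) < 1e-9) bounds[9] <- R
    for (k in 1:8) {
      if (bounds[k + 1] > bounds[k]) {
        cs[(bounds[k] + 1):bounds[k + 1], j] <- k
      }
    }
  }
  cs
}

#' Currentscape of a simulated trace
#'
#' Computes the full currentscape decomposition of a trace: per-sign share
#' matrices, total inward/outward current envelopes, and the rasterized
#' R x N index image used for plotting.
#'
#' @param trace An `stg_trace` simulated with `record_currents = TRUE`, or
#'   a bare current matrix (N x 8 or 8 x N, nA).
#' @param R Vertical resolution of the index image.
#' @return An object of class `currentscape`.
#' @export
currentscape <- function(trace, R = 2000) {
  I <- if (inherits(trace, "stg_trace")) {
    if (is.null(trace$I)) stop("trace was recorded without currents")
    trace$I
  } else trace
  sn <- split_and_normalize(I)
  structure(c(sn,
              list(CS_out = build_cs_matrix(sn$C_out, R),
                   CS_in = build_cs_matrix(sn$C_in, R),
                   R = R,
                   channels = STG_CHANNELS,
                   V = if (inherits(trace, "stg_trace")) trace$V else NULL,
                   t = if (inherits(trace, "stg_trace")) trace_times(trace)
                       else seq_len(ncol(sn$C_out)))),
            class = "currentscape")
}

#' @export
print.currentscape <- function(x, ...) {
  cat(sprintf("currentscape: %d time steps, resolution R = %d\n",
              length(x$n_out), x$R))
  cat(sprintf("  total outward %.3g..%.3g nA, inward %.3g..%.3g nA\n",
              min(x$n_out), max(x$n_out), min(x$n_in), max(x$n_in)))
  invisible(x)
}

# fixed channel palette (one color per current, both signs)
stg_palette <- function() {
  c(Na = "#4c72b0", CaT = "#dd8452", CaS = "#55a868", A = "#c44e52",
    KCa = "#ff9900", Kd = "#8172b3", H = "#937860", leak = "#8c8c8c")
}

#' Render a currentscape
#'
#' Draws the standard stacked presentation: membrane potential (when
#' available), the total outward current envelope on a log scale, the
#' outward share image, the inward share image, and the total inward
#' current envelope on a log scale. Dotted reference lines are placed at
#' 5, 50 and 500 nA on the envelope panels. Zero-total columns render as
#' gaps.
#'
#' @param cs A [currentscape()] object.
#' @param file Output file (png or pdf, by extension); `NULL` draws on the
#'   current device.
#' @param width,height Device size in pixels (png) or inches (pdf).
#' @return `file` (or `NULL`), invisibly.
#' @export
render_currentscape <- function(cs, file = NULL, width = 900, height = 700) {
  if (length(cs$n_out) == 0) stop("zero-length trace")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = width, height = height),
           pdf = grDevices::pdf(file, width = width / 100, height = height / 100),
           stop("unsupported image format: ", ext))
    on.exit(grDevices::dev.off())
  }
  pal <- stg_palette()
  op <- graphics::par(no.readonly = TRUE)
  # restore par before any device teardown so no stray device is opened
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  hasV <- !is.null(cs$V)
  heights <- if (hasV) c(1.2, 0.7, 2, 2, 0.7) else c(0.7, 2, 2, 0.7)
  graphics::layout(matrix(seq_along(heights), ncol = 1), heights = heights)
  graphics::par(mar = c(0.4, 4, 0.4, 1), oma = c(3, 0, 1, 0), xaxs = "i")
  t <- cs$t
  if (hasV) {
    graphics::plot(t, cs$V, type = "l", xlab = "", ylab = "V (mV)",
                   xaxt = "n", bty = "n")
  }
  log_env <- function(n, flip = FALSE) {
    y <- log10(pmax(n, 1e-3))
    ylim <- c(log10(0.5), max(y, log10(600)))
    if (flip) ylim <- rev(ylim)
    graphics::plot(t, y, type = "n", xaxt = "n", yaxt = "n", bty = "n",
                   ylab = if (flip) "inward (nA)" else "outward (nA)",
                   ylim = ylim)
    graphics::polygon(c(t[1], t, t[length(t)]),
                      c(log10(0.5), y, log10(0.5)), col = "black")
    graphics::abline(h = log10(c(5, 50, 500)), lty = 3, col = "grey60")
    graphics::axis(2, at = log10(c(5, 50, 500)), labels = c(5, 50, 500),
                   las = 1)
  }
  img <- function(CS) {
    z <- t(CS)[, rev(seq_len(nrow(CS))), drop = FALSE] # time x rows, top first
    graphics::image(x = t, y = seq_len(ncol(z)), z = z, zlim = c(1, 8),
                    col = pal, xaxt = "n", yaxt = "n", xlab = "", ylab = "",
                    useRaster = TRUE, bty = "n")
  }
  log_env(cs$n_out)
  img(cs$CS_out)
  img(cs$CS_in)
  log_env(cs$n_in, flip = TRUE)
  graphics::axis(1)
  graphics::mtext("time (ms)", side = 1, line = 2)
  invisible(file)
}
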