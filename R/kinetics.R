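#' @useDynLib burstscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical channel order used everywhere in the package
STG_CHANNELS <- c("Na", "CaT", "CaS", "A", "KCa", "Kd", "H", "leak")
STG_GATED <- STG_CHANNELS[1:7]

#' Channel order of the eight-current model
#'
#' Returns the fixed channel ordering (Na, CaT, CaS, A, KCa, Kd, H, leak)
#' used by conductance vectors, recorded current matrices and currentscapes.
#'
#' @return Character vector of length 8.
#' @export
stg_channels <- function() STG_CHANNELS

.tau_forms <- c(sigmoid = 1L, biexp = 2L, product = 3L)

.parse_tau <- function(tau, where) {
  form <- .tau_forms[[tau$form]]
  if (is.null(form)) stop("unknown time-constant form in ", where, ": ", tau$form)
  par <- switch(tau$form,
    sigmoid = c(tau$offset, tau$amplitude, tau$v_offset, tau$slope, 0, 1),
    biexp   = c(tau$offset, tau$amplitude, tau$v1, tau$k1, tau$v2, tau$k2),
    product = c(tau$scale, tau$base, tau$v1, tau$k1, tau$v2, tau$k2)
  )
  c(form, par)
}

#' Load channel gating kinetics
#'
#' Reads the gating-kinetics configuration (activation/inactivation exponents,
#' steady-state sigmoids, time-constant functions and reversal identity for
#' the seven voltage-gated currents). The packaged default transcribes the
#' lobster STG channel kinetics of Liu et al. (1998).
#'
#' @param path Path to a YAML kinetics file, or `NULL` for the packaged
#'   default.
#' @return An object of class `stg_kinetics`: the parsed channel list plus a
#'   numeric matrix encoding used by the compiled integrator.
#' @export
stg_kinetics <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kinetics_liu1998.yaml",
                        package = "burstscape", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  chn <- cfg$channels
  if (!identical(names(chn), STG_GATED)) {
    stop("kinetics file must define channels ",
         paste(STG_GATED, collapse = ", "), " in that order")
  }
  mat <- matrix(0, nrow = 7, ncol = 22,
                dimnames = list(STG_GATED, NULL))
  reversal <- character(7)
  for (i in seq_along(STG_GATED)) {
    ch <- chn[[i]]
    nm <- STG_GATED[i]
    p <- as.integer(ch$p); q <- as.integer(ch$q)
    if (!p %in% c(0L, 1L, 3L, 4L)) stop("invalid activation exponent for ", nm)
    if (!q %in% c(0L, 1L)) stop("invalid inactivation exponent for ", nm)
    reversal[i] <- ch$reversal
    row <- numeric(22)
    row[1:2] <- c(p, q)
    row[3:4] <- c(ch$m_inf$v_half, ch$m_inf$k)
    ca_half <- ch$m_inf$ca_half
    row[5:6] <- if (is.null(ca_half)) c(0, 1) else c(1, ca_half)
    row[7:13] <- .parse_tau(ch$tau_m, paste0(nm, "/tau_m"))
    if (q > 0L) {
      row[14:15] <- c(ch$h_inf$v_half, ch$h_inf$k)
      row[16:22] <- .parse_tau(ch$tau_h, paste0(nm, "/tau_h"))
    } else {
      row[14:15] <- c(0, 1)
      row[16:22] <- c(1, 1, 0, 0, 1, 0, 1) # unused placeholder
    }
    mat[i, ] <- row
  }
  if (!identical(which(reversal == "nernst-calcium"), c(2L, 3L))) {
    stop("exactly the calcium channels (CaT, CaS) must use reversal 'nernst-calcium'")
  }
  kin <- structure(list(channels = chn, matrix = mat, reversal = reversal,
                        source = path,
                        cache = new.env(parent = emptyenv())),
                   class = "stg_kinetics")
  .validate_tau_positive(kin)
  kin
}

.validate_tau_positive <- function(kin) {
  V <- seq(-100, 60, by = 0.5)
  for (v in V) {
    r <- .stg_rates_cpp(kin$matrix, v, 5)
    if (any(r[, 2] <= 0, na.rm = TRUE) || any(r[, 4] <= 0, na.rm = TRUE))
      stop("non-positive time constant at V = ", v, " mV")
  }
  invisible(kin)
}

#' Gating steady states and time constants
#'
#' Evaluates the steady-state activation/inactivation and their time
#' constants for one channel at a given membrane potential and intracellular
#' calcium. For KCa the activation steady state is the voltage sigmoid
#' multiplied by the calcium saturation factor Ca/(Ca + K_half).
#'
#' @param kinetics An [stg_kinetics()] object.
#' @param channel Channel name, one of Na, CaT, CaS, A, KCa, Kd, H.
#' @param V Membrane potential (mV).
#' @param Ca Intracellular calcium (uM); required (> 0) for KCa.
#' @return A list with `m_inf`, `h_inf` (NA when the channel does not
#'   inactivate), `tau_m` and `tau_h` (ms).
#' @export
gate_steady_state <- function(kinetics, channel, V, Ca = 0.05) {
  i <- match(channel, STG_GATED)
  if (is.na(i)) stop("unknown channel: ", channel)
  ca_dep <- kinetics$matrix[i, 5] == 1
  if (ca_dep && !(Ca > 0)) stop("KCa requires a positive calcium concentration")
  r <- .stg_rates_cpp(kinetics$matrix, V, if (ca_dep) Ca else 1)
  list(m_inf = r[i, 1], h_inf = r[i, 3], tau_m = r[i, 2], tau_h = r[i, 4])
}

#' Calcium Nernst potential
#'
#' Reversal potential of the calcium currents, computed from the
#' intracellular and extracellular calcium concentrations as
#' `prefactor * ln(Ca_out / Ca)`. The default prefactor 12.2 mV corresponds
#' to RT/zF for a divalent ion near 10 degrees C, the usual crustacean
#' preparation temperature.
#'
#' @param Ca Intracellular calcium (uM).
#' @param Ca_out Extracellular calcium (uM), default 3000.
#' @param prefactor RT/zF in mV.
#' @return Reversal potential in mV.
#' @export
nernst_calcium <- function(Ca, Ca_out = 3000, prefactor = 12.2) {
  if (any(Ca <= 0) || any(Ca_out <= 0)) {
    stop("calcium concentrations must be positive")
  }
  prefactor * log(Ca_out / Ca)
}
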