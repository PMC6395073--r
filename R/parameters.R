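#' Model parameters for the eight-current STG neuron
#'
#' Bundles the eight maximal conductances, the calcium buffering time
#' constant and the cell constants (capacitance, calcium handling, fixed
#' reversal potentials) into a validated parameter object.
#'
#' @param g Named or ordered numeric vector of 8 maximal conductances (uS) in
#'   the order `stg_channels()`: Na, CaT, CaS, A, KCa, Kd, H, leak.
#' @param tau_ca Calcium buffering time constant (ms).
#' @param C Membrane capacitance (nF).
#' @param Ca0 Resting (steady-state) intracellular calcium (uM).
#' @param CaF Current-to-concentration factor (uM/nA).
#' @param Ca_out Extracellular calcium (uM).
#' @param E_Na,E_K,E_H,E_leak Fixed reversal potentials (mV).
#' @param nernst_prefactor RT/zF (mV) used for the dynamic calcium reversal.
#' @param label Optional model label carried as metadata.
#' @return An object of class `stg_parameters`.
#' @export
stg_parameters <- function(g, tau_ca, C = 10, Ca0 = 0.05, CaF = 0.94,
                           Ca_out = 3000, E_Na = 30, E_K = -80, E_H = -20,
                           E_leak = -50, nernst_prefactor = 12.2,
                           label = NULL) {
  if (length(g) != 8) stop("g must have 8 conductances (",
                           paste(STG_CHANNELS, collapse = ", "), ")")
  if (!is.null(names(g))) {
    if (!setequal(names(g), STG_CHANNELS)) stop("unrecognized conductance names")
    g <- g[STG_CHANNELS]
  } else {
    names(g) <- STG_CHANNELS
  }
  if (any(g < 0)) stop("maximal conductances must be non-negative")
  if (!(tau_ca > 0)) stop("tau_ca must be positive")
  if (!(C > 0)) stop("capacitance must be positive")
  if (!(Ca_out > 0)) stop("extracellular calcium must be positive")
  structure(list(g = g, tau_ca = tau_ca, C = C, Ca0 = Ca0, CaF = CaF,
                 Ca_out = Ca_out, E_Na = E_Na, E_K = E_K, E_H = E_H,
                 E_leak = E_leak, nernst_prefactor = nernst_prefactor,
                 label = label),
            class = "stg_parameters")
}

#' @export
print.stg_parameters <- function(x, ...) {
  cat("STG model parameters",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  g (uS):", paste(sprintf("%s=%g", names(x$g), x$g), collapse = " "), "\n")
  cat(sprintf("  tau_Ca=%g ms  C=%g nF  Ca0=%g uM  CaF=%g uM/nA  Ca_out=%g uM\n",
              x$tau_ca, x$C, x$Ca0, x$CaF, x$Ca_out))
  cat(sprintf("  E_Na=%g  E_K=%g  E_H=%g  E_leak=%g mV (E_Ca dynamic, RT/zF=%g mV)\n",
              x$E_Na, x$E_K, x$E_H, x$E_leak, x$nernst_prefactor))
  invisible(x)
}

# fixed reversal vector in channel order; Ca entries are placeholders (the
# integrator substitutes the Nernst potential dynamically)
.reversals <- function(p) {
  c(Na = p$E_Na, CaT = NA_real_, CaS = NA_real_, A = p$E_K, KCa = p$E_K,
    Kd = p$E_K, H = p$E_H, leak = p$E_leak)
}

#' Load a table of model parameter sets
#'
#' Reads a CSV table with one row per model (columns `label`, `g_Na` ...
#' `g_leak`, `tau_Ca`, optional `E`) and returns a named list of
#' [stg_parameters()] objects. With `path = "builtin"` the packaged table of
#' the eight published bursters (labels a-f, fig2, fig3) is used; their
#' reported objective values are retained as the `energy` attribute.
#'
#' @param path CSV file path, or `"builtin"`.
#' @param ... Passed on to [stg_parameters()] (e.g. `nernst_prefactor`).
#' @return Named list of `stg_parameters`.
#' @export
load_parameter_table <- function(path = "builtin", ...) {
  if (identical(path, "builtin")) {
    path <- system.file("extdata", "table1_models.csv",
                        package = "burstscape", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", paste0("g_", STG_CHANNELS), "tau_Ca")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("parameter table is missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    g <- as.numeric(tab[i, paste0("g_", STG_CHANNELS)])
    names(g) <- STG_CHANNELS
    p <- stg_parameters(g, tau_ca = tab$tau_Ca[i], label = tab$label[i], ...)
    if ("E" %in% names(tab)) attr(p, "energy") <- tab$E[i]
    p
  })
  names(out) <- tab$label
  out
}

#' Published burster parameter sets
#'
#' Convenience accessor for the packaged parameter table: `stg_models()`
#' returns all eight models, `stg_models("a")` one of them.
#'
#' @param label Optional model label (`"a"` ... `"f"`, `"fig2"`, `"fig3"`).
#' @param ... Passed on to [stg_parameters()].
#' @return A single `stg_parameters` object, or a named list of all of them.
#' @export
stg_models <- function(label = NULL, ...) {
  tab <- load_parameter_table("builtin", ...)
  if (is.null(label)) return(tab)
  if (!label %in% names(tab)) {
    stop("unknown model label '", label, "'; available: ",
         paste(names(tab), collapse = ", "))
  }
  tab[[label]]
}

#' Write a parameter table
#'
#' Inverse of [load_parameter_table()]: writes a list of parameter sets to a
#' CSV that round-trips at full double precision.
#'
#' @param models Named list of `stg_parameters`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(models, path) {
  rows <- lapply(names(models), function(nm) {
    p <- models[[nm]]
    row <- c(list(label = nm), as.list(p$g), list(tau_Ca = p$tau_ca))
    names(row) <- c("label", paste0("g_", STG_CHANNELS), "tau_Ca")
    e <- attr(p, "energy")
    if (!is.null(e)) row$E <- e
    as.data.frame(row, check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(format(tab, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
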