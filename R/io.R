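#' Write a trace to disk
#'
#' Writes a simulated trace as columnar CSV (t, V, I_Na..I_leak, Ca, Ie) or
#' as a compact binary RDS container for long traces, plus a JSON sidecar
#' holding the full parameter set, protocol and package version so the
#' artifact is reproducible from its sidecar alone.
#'
#' @param trace An `stg_trace`.
#' @param path Output path (`.csv` or `.rds`).
#' @param sidecar Path of the JSON sidecar; default `<path>.json`.
#' @param seed Optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = paste0(path, ".json"),
                        seed = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- data.frame(t = trace_times(trace), V = trace$V)
    if (!is.null(trace$I)) {
      I <- as.data.frame(trace$I)
      names(I) <- paste0("I_", STG_CHANNELS)
      df <- cbind(df, I)
    }
    df$Ca <- trace$Ca
    df$Ie <- if (length(trace$Ie) == 1) trace$Ie else NA_real_
    # %.17g round-trips doubles exactly
    df[] <- lapply(df, function(col) formatC(col, format = "g", digits = 17))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "rds") {
    saveRDS(trace, path)
  } else stop("unsupported trace format: ", ext)
  meta <- list(params = c(as.list(trace$params$g),
                          list(tau_Ca = trace$params$tau_ca,
                               C = trace$params$C, Ca0 = trace$params$Ca0,
                               CaF = trace$params$CaF,
                               Ca_out = trace$params$Ca_out,
                               E_Na = trace$params$E_Na,
                               E_K = trace$params$E_K,
                               E_H = trace$params$E_H,
                               E_leak = trace$params$E_leak,
                               nernst_prefactor = trace$params$nernst_prefactor,
                               label = trace$params$label)),
               dt = trace$dt, t0 = trace$t0,
               n_samples = length(trace$V),
               Ie = if (length(trace$Ie) == 1) trace$Ie else "schedule",
               method = trace$method, seed = seed,
               package_version = as.character(utils::packageVersion("burstscape")))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a CSV trace for the visualization-only path
#'
#' Reads a columnar trace file (columns t, V, I_Na..I_leak, optionally Ca,
#' Ie) into a minimal `stg_trace` usable by [currentscape()] and the
#' metric functions. The time column must be uniformly spaced.
#'
#' @param path CSV path.
#' @return An `stg_trace` (without parameters).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "V", paste0("I_", STG_CHANNELS))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace file is missing columns: ",
                         paste(miss, collapse = ", "))
  dts <- diff(df$t)
  if (max(abs(dts - dts[1])) > 1e-6 * abs(dts[1])) {
    stop("time column must be uniformly spaced")
  }
  I <- as.matrix(df[paste0("I_", STG_CHANNELS)])
  colnames(I) <- STG_CHANNELS
  structure(list(t0 = df$t[1] - dts[1], dt = dts[1], V = df$V, I = I,
                 Ca = df$Ca, Ie = if ("Ie" %in% names(df)) df$Ie[1] else 0,
                 params = NULL, final_state = NULL, method = "file"),
            class = "stg_trace")
}

# resolve a parameter set from CLI-ish arguments
.resolve_params <- function(model_label = NULL, params_file = NULL) {
  if (!is.null(params_file)) {
    tab <- load_parameter_table(params_file)
    if (!is.null(model_label)) return(tab[[model_label]])
    return(tab[[1]])
  }
  if (is.null(model_label)) stop("either a model label or a parameter file is required")
  stg_models(model_label)
}

.write_manifest <- function(out_dir, command, settings, seed) {
  manifest <- list(command = command, settings = settings, seed = seed,
                   package_version = as.character(utils::packageVersion("burstscape")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Command-line interface
#'
#' Dispatcher behind the `inst/cli/burstscape` script. Subcommands:
#' `simulate`, `score`, `evolve`, `currentscape`, `vdist-sweep`,
#' `share-sweep`, `isi-scan`, `decrement`, `delete`. Every run writes its
#' artifacts plus a JSON manifest with all resolved settings into
#' `--out-dir`.
#'
#' @param argv Character vector of command-line arguments (the subcommand
#'   followed by options, e.g. `c("simulate", "--model-label", "c")`).
#' @return Exit code (0 on success), invisibly.
#' @export
stg_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    .stg_cli_run(argv)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

.cli_opt <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for --", name)
  args[i[1] + 1]
}

.cli_num <- function(args, name, default = NULL) {
  v <- .cli_opt(args, name, NULL)
  if (is.null(v)) default else as.numeric(v)
}

.stg_cli_run <- function(argv) {
  if (!length(argv)) {
    stop("usage: burstscape <simulate|score|evolve|currentscape|vdist-sweep|",
         "share-sweep|isi-scan|decrement|delete> [options]")
  }
  cmd <- argv[1]
  args <- argv[-1]
  out_dir <- .cli_opt(args, "out-dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cli_num(args, "seed", 1))
  label <- .cli_opt(args, "model-label")
  pfile <- .cli_opt(args, "params")
  dt <- .cli_num(args, "dt", 0.1)
  duration <- .cli_num(args, "duration", 20000)
  transient <- .cli_num(args, "transient", 10000)
  fmt <- .cli_opt(args, "format", "csv")
  channel <- .cli_opt(args, "channel", "Na")
  profile <- stg_profile(.cli_opt(args, "profile", "desk"))
  settings <- list(model_label = label, params = pfile, dt = dt,
                   duration = duration, transient = transient,
                   channel = channel, format = fmt, profile = profile$name,
                   out_dir = out_dir)

  if (cmd == "simulate") {
    p <- .resolve_params(label, pfile)
    tr <- stg_simulate(p, duration = duration, dt = dt, transient = transient,
                       Ie = .cli_num(args, "ie", 0))
    f <- file.path(out_dir, paste0("trace_", label %||% "custom", ".",
                                   if (fmt == "rds") "rds" else "csv"))
    write_trace(tr, f, seed = seed)
    message("wrote ", f)
  } else if (cmd == "score") {
    p <- .resolve_params(label, pfile)
    sc <- score_parameters(p, burster_target(duration = duration,
                                             transient = transient, dt = dt))
    if (sc$discarded) {
      message(sprintf("discarded solution (%s); penalty score %g",
                      sc$reason, sc$score))
    } else {
      message(sprintf("E(g) = %.6g  [E_f = %.6g, E_dc = %.6g, E_sw = %.6g]",
                      sc$score, sc$terms["E_f"], sc$terms["E_dc"],
                      sc$terms["E_sw"]))
    }
    jsonlite::write_json(list(score = sc$score, terms = as.list(sc$terms),
                              discarded = sc$discarded),
                         file.path(out_dir, "score.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (cmd == "evolve") {
    cfg <- ga_config(population = as.integer(.cli_num(args, "pop", 100)),
                     generations = as.integer(.cli_num(args, "gens", 100)),
                     seed = seed)
    res <- evolve_models(burster_target(), cfg)
    out <- list(best = as.list(res$best), best_score = res$best_score,
                seed = seed)
    jsonlite::write_json(out, file.path(out_dir, "best_candidate.json"),
                         auto_unbox = TRUE, digits = NA)
    message(sprintf("best score %.6g", res$best_score))
  } else if (cmd == "currentscape") {
    p <- .resolve_params(label, pfile)
    tr <- stg_simulate(p, duration = duration, dt = dt, transient = transient)
    cs <- currentscape(tr)
    f <- file.path(out_dir, paste0("currentscape_", label %||% "custom",
                                   ".png"))
    render_currentscape(cs, f)
    message("wrote ", f)
  } else if (cmd %in% c("vdist-sweep", "share-sweep")) {
    p <- .resolve_params(label, pfile)
    sw <- sweep_distribution(
      p, channel,
      observable = if (cmd == "vdist-sweep") "V" else "share",
      levels = seq(1, 0, length.out = as.integer(.cli_num(args, "levels", 11))),
      duration = profile$dist_duration, transient = profile$dist_transient,
      dt = profile$dist_dt, seed = seed)
    f <- file.path(out_dir, paste0(cmd, "_", channel, ".png"))
    plot(sw, file = f)
    saveRDS(sw, file.path(out_dir, paste0(cmd, "_", channel, ".rds")))
    message("wrote ", f)
  } else if (cmd == "isi-scan") {
    p <- .resolve_params(label, pfile)
    sc <- injection_scan(p,
                         I_range = c(.cli_num(args, "ie-min", -1),
                                     .cli_num(args, "ie-max", 5)),
                         n_levels = as.integer(.cli_num(args, "levels", 25)),
                         duration = profile$scan_duration,
                         transient = profile$scan_transient,
                         dt = profile$scan_dt)
    utils::write.csv(sc$summary,
                     file.path(out_dir, "isi_scan_summary.csv"),
                     row.names = FALSE)
    plot(sc, file = file.path(out_dir, "isi_scan.png"))
    message("wrote ", file.path(out_dir, "isi_scan_summary.csv"))
  } else if (cmd %in% c("decrement", "delete")) {
    p <- .resolve_params(label, pfile)
    levels <- if (cmd == "delete") 0 else
      seq(1, 0, length.out = as.integer(.cli_num(args, "levels", 11)))
    sw <- decrement_traces(p, channel, levels = levels, duration = duration,
                           transient = transient, dt = dt,
                           keep_traces = FALSE)
    summ <- do.call(rbind, lapply(sw, function(s) {
      data.frame(level = s$level, failed = s$failed,
                 fb = if (!is.null(s$stats)) s$stats$mean_fb else NA,
                 dc = if (!is.null(s$stats)) s$stats$mean_dc else NA,
                 n_bursts = if (!is.null(s$stats)) s$stats$n_bursts else NA)
    }))
    utils::write.csv(summ, file.path(out_dir,
                                     paste0(cmd, "_", channel, ".csv")),
                     row.names = FALSE)
    message("wrote ", file.path(out_dir, paste0(cmd, "_", channel, ".csv")))
  } else stop("unknown subcommand: ", cmd)

  .write_manifest(out_dir, cmd, settings, seed)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
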