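# Experiment configs, result serialization and the one-call runner.
# Every experiment of the study is one run_experiment() invocation
# with a validated config (R list or YAML file); outputs are a tidy
# trace CSV plus a JSON manifest of parameters, derived constants and
# result features.  All models are deterministic; the config carries a
# reserved (unused) seed field for honest metadata.

.experiments <- c("ap_pulse", "ap_tonic", "clamp_tau", "bifurcation",
                  "firing_rate", "sd_threshold", "anoxia")

#' Validate an experiment configuration
#'
#' @param config A named list (or path to a YAML file) with fields
#'   `experiment` (one of `ap_pulse`, `ap_tonic`, `clamp_tau`,
#'   `bifurcation`, `firing_rate`, `sd_threshold`, `anoxia`),
#'   `genotype` (`"wild-type"`/`"mutant"`), optional `fold_change`
#'   (default 3), optional `rtol`/`atol`, optional experiment-specific
#'   fields (`I_app`, `hold_s`, ...), optional `out_dir` and a
#'   reserved `seed`.
#' @return The completed config list.
#' @export
experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$experiment) ||
      !config$experiment %in% .experiments)
    stop("unknown experiment; must be one of: ",
         paste(.experiments, collapse = ", "))
  if (is.null(config$genotype)) config$genotype <- "wild-type"
  if (!config$genotype %in% c("wild-type", "mutant"))
    stop("unknown genotype '", config$genotype,
         "'; use 'wild-type' or 'mutant'")
  defaults <- list(fold_change = 3, rtol = .default_rtol,
                   atol = .default_atol, seed = NULL, out_dir = NULL)
  modifyList(defaults, config)
}

#' Write a simulation trace as tidy CSV
#'
#' @param trace A trace data frame from any of the simulators.
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run one configured experiment
#'
#' Executes the experiment described by `config` and, if
#' `config$out_dir` is set, writes the trace CSV(s) and a JSON
#' manifest with the parameters, derived constants (flux conversion
#' factors, the tau_h anchor voltage) and the result features.
#' Outputs are deterministic: the same config yields byte-identical
#' files.
#'
#' @param config See [experiment_config()].
#' @return List with `result` (experiment-specific features), `trace`
#'   (when the experiment produces one) and `files` (paths written).
#' @export
run_experiment <- function(config) {
  cfg <- experiment_config(config)
  g <- cfg$genotype
  f <- cfg$fold_change
  res <- switch(cfg$experiment,
    ap_pulse = {
      sched <- make_pulse(cfg$amplitude %||% 3, cfg$duration_ms %||% 3,
                          cfg$onset_ms %||% 10)
      tr <- simulate_hh(sched, t_end_ms = cfg$t_end_ms %||% 50,
                        genotype = g, f = f, rtol = cfg$rtol,
                        atol = cfg$atol)
      list(trace = tr, features = ap_features(tr, sched))
    },
    ap_tonic = {
      sched <- make_constant_current(cfg$I_app %||% 12, "ms")
      tr <- simulate_hh(sched, t_end_ms = cfg$t_end_ms %||% 500,
                        genotype = g, f = f, rtol = cfg$rtol,
                        atol = cfg$atol)
      list(trace = tr, features = ap_features(tr))
    },
    clamp_tau = list(trace = NULL,
                     features = clamp_tau_ratios(
                       cfg$variant %||% "classical", f = f)),
    bifurcation = {
      b <- scan_hopf(genotype = g, f = f)
      list(trace = NULL,
           features = list(HB1 = b$HB1, HB2 = b$HB2,
                           rheobase = b$rheobase))
    },
    firing_rate = {
      grid <- cfg$I_grid %||% seq(6, 160, by = 2)
      list(trace = NULL,
           features = firing_rate_curve(grid, genotype = g, f = f))
    },
    sd_threshold = {
      thr <- find_sd_threshold(genotype = g, f = f)
      list(trace = thr$run$trace,
           features = list(minimal_hold_s = thr$threshold_s,
                           outcomes = as.list(thr$outcomes)))
    },
    anoxia = {
      d <- run_decapitation(genotype = g, f = f,
                            t_off_s = cfg$t_off_s %||% 5)
      list(trace = d$trace, features = d$features)
    })

  files <- character()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(cfg$out_dir,
                      paste0(cfg$experiment, "_", gsub("-", "", g)))
    if (!is.null(res$trace))
      files <- c(files, write_trace_csv(res$trace,
                                        paste0(stem, "_trace.csv")))
    manifest <- list(
      experiment = cfg$experiment, genotype = g, fold_change = f,
      rtol = cfg$rtol, atol = cfg$atol, seed = cfg$seed,
      derived = list(
        V_max_classical = locate_vmax("classical"),
        V_max_shifted = locate_vmax("shifted"),
        sd_conv_i = sd_parameters()$conv_i,
        sd_conv_e = sd_parameters()$conv_e),
      features = .simplify_features(res$features),
      package_version = as.character(utils::packageVersion("hhsd")))
    files <- c(files, .write_manifest(manifest,
                                      paste0(stem, "_manifest.json")))
  }
  list(result = res$features, trace = res$trace, files = files)
}

.simplify_features <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(x, .simplify_features))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
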