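#' Read model parameters from a JSON or YAML config file
#'
#' The file may override any subset of the defaults of
#' [model_parameters()]; recognised top-level keys are `membrane`, `vgcc`,
#' `pmca`, `ncx`, `leak_ca`, `flux_scale`, `ca_ss_basal`,
#' `ca_ss_activated`, `calibrate`, and `activation` (with `beta`,
#' `k_half`). A free-text `source` field documenting provenance of the
#' values is carried through but otherwise ignored.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A [model_parameters()] object.
#' @export
read_model_parameters <- function(path) {
  cfg <- read_config_file(path)
  act <- if (!is.null(cfg$activation)) {
    do.call(activation_model, cfg$activation)
  } else {
    activation_model(beta = 5, k_half = 1)
  }
  model_parameters(
    asn_activation = act,
    ca_ss_basal = cfg$ca_ss_basal %null% 0.25,
    ca_ss_activated = cfg$ca_ss_activated %null% 0.10,
    calibrate = cfg$calibrate %null% TRUE,
    membrane = cfg$membrane %null% list(),
    vgcc = cfg$vgcc %null% list(),
    pmca = cfg$pmca %null% list(),
    ncx = cfg$ncx %null% list(),
    leak_ca = cfg$leak_ca %null% list(),
    flux_scale = cfg$flux_scale %null% 0.15)
}

`%null%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run one pipeline stage from a configuration
#'
#' Unified entry point behind the command-line interface. The config names
#' a `stage` and its inputs/outputs; every run that writes an output also
#' writes a provenance record (`<out>.provenance.json`) echoing the
#' resolved config, package version and seed, so identical configs give
#' identical, attributable outputs.
#'
#' Stages: `fit_hill`, `fit_activation`, `free_ca`, `free_ca_invert`,
#' `simulate`, `dose_response`, `metrics`, `auc`, `psi_bin`, `synth`.
#'
#' @param config a named list, or the path of a JSON/YAML file holding
#'   one. Common fields: `stage`, `input`, `out`, `seed`, `params_file`.
#'   Stage-specific fields are documented in the package vignette.
#' @return The stage's result object, invisibly.
#' @examples
#' \donttest{
#' tmp <- tempfile(fileext = ".csv")
#' run_pipeline(list(stage = "synth", kind = "hill", seed = 1, out = tmp))
#' fit <- run_pipeline(list(stage = "fit_hill", input = tmp))
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_file(config)
  if (is.null(config$stage)) stop("config must name a `stage`")
  stage <- config$stage
  result <- switch(stage,
    synth = stage_synth(config),
    fit_hill = stage_fit_hill(config),
    fit_activation = stage_fit_activation(config),
    free_ca = stage_free_ca(config, invert = FALSE),
    free_ca_invert = stage_free_ca(config, invert = TRUE),
    simulate = stage_simulate(config),
    dose_response = stage_dose_response(config),
    metrics = stage_metrics(config),
    auc = stage_auc(config),
    psi_bin = stage_psi_bin(config),
    stop("unknown stage: ", stage)
  )
  if (!is.null(config$out)) write_provenance(config)
  invisible(result)
}

write_provenance <- function(config) {
  prov <- list(
    package = "pmcasyn",
    version = as.character(utils::packageVersion("pmcasyn")),
    stage = config$stage,
    seed = config$seed,
    config = config)
  jsonlite::write_json(prov, paste0(config$out, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

require_input <- function(config) {
  if (is.null(config$input)) stop("config needs an `input` path")
  if (!file.exists(config$input)) stop("input file not found: ", config$input)
  config$input
}

stage_synth <- function(config) {
  kind <- config$kind %null% stop("synth needs a `kind`")
  if (is.null(config$seed)) stop("synth needs a `seed`")
  obj <- switch(kind,
    hill = gen_hill_curve(do.call(hill_curve_spec,
             c(config$params %null% list(), list(seed = config$seed)))),
    activation = gen_activation_curve(do.call(activation_curve_spec,
             c(config$params %null% list(), list(seed = config$seed)))),
    psi = gen_psi_tables(do.call(psi_tables_spec,
             c(config$params %null% list(), list(seed = config$seed)))),
    trace = gen_ca_trace(do.call(ca_trace_spec,
             c(config$params %null% list(), list(seed = config$seed)))),
    stop("unknown synth kind: ", kind))
  if (!is.null(config$out)) {
    if (kind %in% c("hill", "activation")) {
      write_titration(obj, config$out)
    } else if (kind == "trace") {
      utils::write.csv(as.data.frame(obj), config$out, row.names = FALSE)
    } else {
      df <- merge(obj$expression, obj$psi, by = "tissue")
      utils::write.table(df, config$out, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  obj
}

fit_to_json <- function(fit, out) {
  rec <- unclass(fit)
  rec$fit <- NULL
  jsonlite::write_json(rec, out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
}

stage_fit_hill <- function(config) {
  curve <- read_titration(require_input(config))
  fit <- fit_hill(curve, fix_n = config$fix_n)
  if (!is.null(config$out)) fit_to_json(fit, config$out)
  fit
}

stage_fit_activation <- function(config) {
  curve <- read_titration(require_input(config), ligand_name = "aSN")
  fit <- fit_activation(curve)
  if (!is.null(config$out)) fit_to_json(fit, config$out)
  fit
}

stage_free_ca <- function(config, invert) {
  constants <- if (!is.null(config$constants))
    utils::read.csv(config$constants, stringsAsFactors = FALSE)
  else default_chelator_constants()
  buf <- buffer_system(
    total_ca = config$total_ca %null% 0,
    total_mg = config$total_mg %null% 0,
    total_egta = config$total_egta %null% 0,
    total_atp = config$total_atp %null% 0,
    ph = config$ph %null% 7.2,
    temperature_C = config$temperature_C %null% 37,
    constants = constants)
  res <- if (invert) {
    if (is.null(config$target_free_ca))
      stop("free_ca_invert needs `target_free_ca` (uM)")
    list(total_ca_uM = invert_free_ca(buf, config$target_free_ca),
         target_free_ca_uM = config$target_free_ca)
  } else {
    list(free_ca_uM = compute_free_ca(buf))
  }
  if (!is.null(config$out))
    jsonlite::write_json(res, config$out, auto_unbox = TRUE, digits = NA)
  res
}

resolve_params <- function(config) {
  if (!is.null(config$params_file)) read_model_parameters(config$params_file)
  else model_parameters()
}

resolve_protocol <- function(config) {
  kind <- switch(config$protocol %null% "single_pulse",
                 none = "none", pulse = "single_pulse",
                 single_pulse = "single_pulse",
                 train = "spike_train", spike_train = "spike_train",
                 stop("unknown protocol: ", config$protocol))
  args <- config[intersect(names(config),
                           c("pulse_amplitude", "pulse_duration",
                             "train_frequency", "train_duration", "onset"))]
  do.call(stimulus_protocol, c(list(kind = kind), args))
}

stage_simulate <- function(config) {
  sim <- simulate_presynapse(resolve_params(config),
                             resolve_protocol(config),
                             asn_conc = config$asn %null% 0,
                             t_end = config$t_end)
  if (!is.null(config$out))
    utils::write.csv(as.data.frame(sim), config$out, row.names = FALSE)
  sim
}

stage_dose_response <- function(config) {
  grid <- config$asn_grid %null% 10^seq(-2, 2, length.out = 25)
  ca <- asn_dose_response(resolve_params(config), sort(as.numeric(grid)))
  res <- data.frame(asn_uM = sort(as.numeric(grid)), ca_ss_uM = ca)
  if (!is.null(config$out))
    utils::write.csv(res, config$out, row.names = FALSE)
  res
}

stage_metrics <- function(config) {
  df <- utils::read.csv(require_input(config))
  if (!all(c("time_ms", "ca_uM") %in% names(df)))
    stop("metrics input needs `time_ms` and `ca_uM` columns")
  tr <- data.frame(time = df$time_ms, signal = df$ca_uM)
  pm <- peak_metrics(tr, baseline_end = config$baseline_end)
  if (!is.null(config$out))
    jsonlite::write_json(unclass(pm), config$out, auto_unbox = TRUE,
                         digits = NA)
  pm
}

stage_auc <- function(config) {
  df <- utils::read.csv(require_input(config))
  if (!all(c("time", "signal") %in% names(df)))
    stop("auc input needs `time` and `signal` columns")
  auc <- compute_auc(ca_trace(df$time, df$signal),
                     t_start = config$t0 %null% 2,
                     t_end = config$t1 %null% 12,
                     baseline_subtract = isTRUE(config$baseline_subtract))
  res <- list(auc = auc, t0 = config$t0 %null% 2, t1 = config$t1 %null% 12)
  if (!is.null(config$out))
    jsonlite::write_json(res, config$out, auto_unbox = TRUE, digits = NA)
  res
}

stage_psi_bin <- function(config) {
  if (is.null(config$gene)) stop("psi_bin needs a `gene`")
  path <- require_input(config)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  events <- config$events %null% setdiff(names(df), c("tissue", config$gene))
  tabs <- read_psi_expression(path, events = events, genes = config$gene)
  edges <- if (!is.null(config$edges)) as.numeric(config$edges)
           else seq(0, 190, 10)
  binned <- bin_psi_by_expression(tabs, gene = config$gene, events = events,
                                  edges = edges)
  if (!is.null(config$out))
    utils::write.csv(as.data.frame(binned), config$out, row.names = FALSE)
  binned
}
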