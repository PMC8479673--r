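# Pipeline orchestration: validate -> assess -> pmo -> sample-thermo ->
# sample-flux -> diagnose, with a serialized configuration snapshot.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default.  All defaults
#' are serialized next to the outputs for provenance.
#'
#' @param alpha confidence level of the thermodynamic space.
#' @param eps second-law margin (kJ/mol).
#' @param v_min minimum flux magnitude (mmol/gDW/h).
#' @param chains,steps MCMC geometry.
#' @param burn_in burn-in fraction.
#' @param n_retain retained energy draws per chain.
#' @param n_flux_total total flux draws.
#' @param n_orthants orthants included in the flux mixture (NULL = all).
#' @param theta z-score threshold for anomalies.
#' @param psrf_gate,ess_gate diagnostic gates.
#' @param seed integer seed.
#' @return a `pta_config` list.
#' @export
pta_config <- function(alpha = 0.95, eps = 0.1, v_min = 1e-6,
                       chains = 4, steps = 2000, burn_in = 0.2,
                       n_retain = 500, n_flux_total = 1000,
                       n_orthants = NULL, theta = 1,
                       psrf_gate = 1.1, ess_gate = 100, seed = 1) {
  cfg <- list(alpha = alpha, eps = eps, v_min = v_min, chains = chains,
              steps = steps, burn_in = burn_in, n_retain = n_retain,
              n_flux_total = n_flux_total, n_orthants = n_orthants,
              theta = theta, psrf_gate = psrf_gate, ess_gate = ess_gate,
              seed = seed)
  stopifnot(alpha > 0, alpha < 1, eps > 0, v_min > 0, chains >= 2,
            steps > 0, burn_in >= 0, burn_in < 1, theta > 0)
  structure(cfg, class = "pta_config")
}

#' Read a pipeline configuration from YAML/JSON
#' @param path YAML or JSON file with configuration overrides.
#' @return a `pta_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
    else yaml::read_yaml(path)
  do.call(pta_config, vals)
}

halt <- function(stage, message, data = NULL) {
  cond <- structure(
    class = c(paste0("pta_", stage, "_error"), "pta_pipeline_error",
              "error", "condition"),
    list(message = paste0("[", stage, "] ", message), call = NULL,
         stage = stage, data = data))
  stop(cond)
}

#' Run the full analysis pipeline
#'
#' Stages: model validation, structural assessment (halts on forced internal
#' cycles), probabilistic optimization, thermodynamic-space sampling, flux
#' sampling, diagnostics.  Stage outputs (TSV/JSON) plus a configuration
#' snapshot are written under `out_dir`; reruns with the same configuration
#' and seed produce byte-identical tables.
#'
#' @param network a `pta_network`, or a model file path.
#' @param priors a `pta_priors` (required unless `network` is a fixture
#'   list).
#' @param config a [pta_config()].
#' @param out_dir output directory (created); `NULL` skips file output.
#' @return list with the stage results (`network`, `assessment`, `pmo`,
#'   `samples`, `fluxes`, `diagnostics`, `direction_calls`, `artifacts`).
#' @export
run_pipeline <- function(network, priors = NULL, config = pta_config(),
                         out_dir = NULL) {
  if (is.character(network)) network <- load_network(network)
  if (is.list(network) && !inherits(network, "pta_network") &&
      !is.null(network$network)) {
    priors <- network$priors
    network <- network$network
  }
  if (is.null(priors)) halt("validate", "priors are required")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(NULL)
    path <- file.path(out_dir, name)
    writer(path)
    path
  }
  artifacts <- list()
  artifacts$config <- emit("config.yaml", function(p)
    yaml::write_yaml(unclass(config), p))

  # validate
  net <- tryCatch(validate_network(network),
                  error = function(e) halt("validate", conditionMessage(e)))
  if (!length(net$gamma))
    net <- tryCatch(select_thermo_reactions(net),
                    error = function(e) halt("validate", conditionMessage(e)))

  # structural assessment
  assessment <- tryCatch(assess_structure(net, v_min = config$v_min),
                         error = function(e)
                           halt("assess", conditionMessage(e)))
  artifacts$forced_cycles <- emit("forced_cycles.tsv", function(p)
    utils::write.table(assessment$forced_cycles, p, sep = "\t",
                       row.names = FALSE, quote = FALSE))
  if (!assessment$consistent)
    halt("assess",
         paste0(max(assessment$forced_cycles$cycle),
                " forced internal cycle(s) detected; ",
                "resolve the reported irreversibilities first"),
         data = assessment)

  # thermodynamic space + PMO
  space <- tryCatch(build_thermo_space(net, priors, alpha = config$alpha),
                    error = function(e) halt("pmo", conditionMessage(e)))
  fit <- solve_pmo(net, space, eps = config$eps, v_min = config$v_min)
  if (fit$status != "optimal")
    halt("pmo", "no thermodynamically feasible state at this confidence")
  anomalies <- classify_anomalies(fit, theta = config$theta)
  artifacts$pmo <- emit("pmo.json", function(p)
    jsonlite::write_json(list(objective = fit$objective,
                              signature = fit$signature,
                              t_star = fit$t_star[c("ln_c", "dg0", "dg")],
                              z = fit$z, anomalies = anomalies),
                         p, digits = NA, auto_unbox = TRUE))

  # thermodynamic sampling
  samples <- tryCatch(
    run_tfs(net, space, n_steps = config$steps, n_chains = config$chains,
            seed = config$seed, burn_in = config$burn_in,
            n_retain = config$n_retain, v_min = config$v_min,
            eps = config$eps),
    error = function(e) halt("sample-thermo", conditionMessage(e)))
  artifacts$orthants <- emit("orthants.tsv", function(p)
    utils::write.table(samples$orthants, p, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  artifacts$dg_samples <- emit("dg_samples.tsv", function(p)
    utils::write.table(tidy(samples), p, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  conc <- sample_concentrations(space, do.call(rbind, samples$dg),
                                seed = config$seed)
  artifacts$concentrations <- emit("ln_c_samples.tsv", function(p) {
    lnc <- as.data.frame(conc$ln_c)
    names(lnc) <- net$metabolite_ids
    utils::write.table(lnc, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  # flux sampling
  fluxes <- tryCatch(
    sample_flux_mixture(net, samples$orthants,
                        n_total = config$n_flux_total,
                        n_orthants = config$n_orthants,
                        seed = config$seed, v_min = config$v_min),
    error = function(e) halt("sample-flux", conditionMessage(e)))
  artifacts$fluxes <- emit("flux_samples.tsv", function(p)
    utils::write.table(fluxes$samples, p, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  calls <- call_directions(fluxes)
  artifacts$directions <- emit("direction_calls.tsv", function(p)
    utils::write.table(calls, p, sep = "\t", row.names = FALSE,
                       quote = FALSE))

  # diagnostics
  diagnostics <- diagnose_samples(samples, psrf_gate = config$psrf_gate,
                                  ess_gate = config$ess_gate)
  artifacts$diagnostics <- emit("diagnostics.json", function(p)
    jsonlite::write_json(list(table = diagnostics$table,
                              pass = diagnostics$pass),
                         p, digits = NA, auto_unbox = TRUE))

  list(network = net, space = space, assessment = assessment, pmo = fit,
       anomalies = anomalies, samples = samples, concentrations = conc,
       fluxes = fluxes, direction_calls = calls,
       diagnostics = diagnostics, artifacts = artifacts)
}
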