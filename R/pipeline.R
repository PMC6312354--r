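#' Run the full inference pipeline from a YAML configuration
#'
#' Binds the stages into one reproducible workflow: load (or simulate)
#' data, variational model selection, complete Bayesian inference on the
#' selected subset, goodness-of-fit and posterior predictive checks. The
#' run directory receives `ensemble.json`, `draws.csv`,
#' `diagnostics.json` and `fitqc.json`; every report embeds the config
#' hash, the seed and the package version, and the log records each
#' pruning iteration's L, set size and culled ids.
#'
#' Config schema (YAML): `scenario` one of `saxs`, `saxs+energies`,
#' `saxs+cs`, `saxs+cs+energies`; `data:` with `saxs`, `profiles` and,
#' as the scenario requires, `energies`, `cs_exp`, `cs_pred`,
#' `cs_pred_err`; optional `select:` (`w_cut`, `patience`,
#' `max_restarts`, `n_steps`) and `mcmc:` (`n_iter`, `n_chains`)
#' overrides.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param out_dir Output run directory (created if missing).
#' @param seed Integer seed governing every stochastic stage.
#' @return Invisibly, a list with `ensemble`, `draws`, `fitqc`,
#'   `diagnostics`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  scen <- config$scenario %||% NA_character_
  scenarios <- c("saxs", "saxs+energies", "saxs+cs", "saxs+cs+energies")
  if (!isTRUE(scen %in% scenarios))
    problems <- c(problems, paste0("scenario: must be one of ",
                                   paste(scenarios, collapse = ", ")))
  need <- c("saxs", "profiles")
  if (isTRUE(grepl("energies", scen))) need <- c(need, "energies")
  if (isTRUE(grepl("cs", scen))) need <- c(need, "cs_exp", "cs_pred")
  for (field in need)
    if (is.null(config$data[[field]]))
      problems <- c(problems,
                    paste0("data.", field, ": required for scenario '",
                           scen, "'"))
  if (length(problems) > 0L)
    abort(paste0("invalid configuration:\n  ",
                 paste(problems, collapse = "\n  ")))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curve <- read_saxs_curve(config$data$saxs)
  library <- read_profile_matrix(config$data$profiles, curve)
  cs_data <- NULL
  if (grepl("cs", scen)) {
    preds <- read_cs_predictions(config$data$cs_pred,
                                 config$data$cs_pred_err)
    aligned <- align_cs(read_cs_table(config$data$cs_exp), preds)
    cs_data <- aligned$cs_data
    library$cs_pred <- aligned$cs_pred
    library$cs_pred_err <- aligned$cs_pred_err
    library$cs_labels <- aligned$cs_data$label
  }
  if (grepl("energies", scen))
    library$energies <- setNames(read_energies(config$data$energies, library),
                                 library$ids)

  sc <- config$select %||% list()
  sel_cfg <- selection_config(
    w_cut = sc$w_cut %||% 0.01, patience = sc$patience %||% 10,
    max_restarts = sc$max_restarts %||% 3,
    n_steps = sc$n_steps %||% 5000, seed = seed)
  model <- select_ensemble(curve, library, cs_data, sel_cfg)

  sub <- subset_library(library, model$member_ids)
  espec <- if (grepl("energies", scen))
    energy_prior(sub$energies, u_ref = model$u_ref)
  mc <- config$mcmc %||% list()
  draws <- sample_posterior(
    curve, sub, cs_data, espec,
    mcmc_config(n_iter = mc$n_iter %||% 2000,
                n_chains = mc$n_chains %||% 4, seed = seed + 1L),
    init = list(weights = model$weights, lambda = model$lambda_hat))
  ppc <- posterior_predictive(draws, sub, curve, n_rep = 200,
                              seed = seed + 2L)
  qc <- fit_quality(model)

  meta <- list(package_version = as.character(packageVersion("saxsemble")),
               config_hash = cfg_hash, seed = seed, scenario = scen)
  write_json <- function(x, file)
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  write_json(c(meta, list(
    members = model$member_ids, weights = model$weights,
    L_value = model$L_value, lambda = model$lambda_hat,
    u_ref = model$u_ref,
    jsd_vs_posterior_mean = ensemble_uncertainty(draws),
    jsd_vs_vbi = ensemble_uncertainty(
      draws, setNames(model$weights, model$member_ids)[colnames(draws$w_draws)]),
    log = purrr::pmap(model$history, function(pass, iteration, L, n_members,
                                              culled)
      list(pass = pass, iteration = iteration, L = L,
           n_members = n_members, culled = culled)))),
    "ensemble.json")
  draw_tbl <- as.data.frame(draws$w_draws)
  draw_tbl$lambda <- draws$lambda_draws
  if (!is.null(draws$uref_draws)) draw_tbl$u_ref <- draws$uref_draws
  draw_tbl$chain <- draws$chain_ids
  write.csv(draw_tbl, file.path(out_dir, "draws.csv"), row.names = FALSE)
  write_json(c(meta, list(diagnostics = draws$diagnostics,
                          accept_rates = draws$accept_rates,
                          ppc_coverage = ppc$coverage)),
             "diagnostics.json")
  write_json(c(meta, as.list(qc)), "fitqc.json")
  invisible(list(ensemble = model, draws = draws, fitqc = qc,
                 diagnostics = draws$diagnostics, out_dir = out_dir))
}
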