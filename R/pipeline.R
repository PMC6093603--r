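#' Run the complete analysis pipeline
#'
#' Fixture (or user inputs) to Monte-Carlo projections to landscape
#' metrics to utilities to costs to the benefit-per-cost ranking, in one
#' call.  Deterministic for `config$seed`.
#'
#' @param config a run configuration ([default_config()] or
#'   [load_config()]).
#' @param inputs optional list (`elevation`, `landcover`, `site_set`);
#'   defaults to [make_synthetic_estuary()] at the configured fixture
#'   shape and seed.
#' @param services,weights,multipliers,cost_table valuation and costing
#'   inputs (package defaults when omitted).
#' @param window late-horizon window for the secondary ranking
#'   (default `c(2085, 2100)` when inside the run years).
#' @return List: `inputs`, `stacks`, `metrics`, `utilities`, `costs`,
#'   `persistent`, `ranking`, `ranking_windowed`.
#' @export
run_analysis <- function(config = default_config(), inputs = NULL,
                         services = default_services(),
                         weights = load_weights(),
                         multipliers = NULL,
                         cost_table = default_cost_table(),
                         window = c(2085, 2100)) {
  validate_config(config)
  if (is.null(inputs)) {
    fx <- config$fixture
    inputs <- make_synthetic_estuary(fx$n_rows, fx$n_cols, fx$cell_size,
                                     seed = config$seed,
                                     n_sites = fx$n_sites %||% 2)
  }
  stacks <- run_monte_carlo(config, inputs)
  metrics <- compute_metrics(stacks, inputs$site_set)
  util <- evaluate_utilities(metrics, services, weights, multipliers,
                             start_year = config$start_year)
  costs <- compute_all_costs(stacks, inputs$site_set, cost_table,
                             initial_landcover = inputs$landcover)
  pm <- NULL
  if ("PROTECT" %in% names(stacks)) {
    pm_rows <- lapply(names(stacks), function(sk) {
      d <- expected_persistent_marsh(stacks[[sk]], stacks[["PROTECT"]],
                                     inputs$site_set$site_mask)
      cbind(strategy = sk, d)
    })
    pm <- do.call(rbind, pm_rows)
  }
  ranking <- benefit_per_cost(util$Z, costs, pm = pm)
  rw <- NULL
  if (!is.null(window) && window[1] <= max(config$years) &&
      window[2] >= min(config$years))
    rw <- windowed_ranking(util, costs, window, pm = pm)
  list(inputs = inputs, stacks = stacks, metrics = metrics,
       utilities = util, costs = costs, persistent = pm,
       ranking = ranking, ranking_windowed = rw)
}
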