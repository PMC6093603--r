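#' Default run configuration
#'
#' Output years every 5 years from 2016 to 2100, 50 realizations, all
#' five strategies, default uncertainty distributions, Table-derived
#' stakeholder service weights, uniform time weights and equal
#' realization weights.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    years = seq(2016, 2100, by = 5),
    start_year = 2016,
    n_realizations = 50,
    seed = 42L,
    strategies = c("PROTECT", "MIGRATE_UNDEVELOPED", "MIGRATE_DEVELOPED",
                   "EDGE_RESTORE_1974", "THIN_LAYER"),
    distributions = default_distributions(),
    strategy_options = list(deposition_thickness = 0.20,
                            deposition_reach = 60,
                            restore_elevation = 0),
    fixture = list(n_rows = 64, n_cols = 64, cell_size = 5, n_sites = 2)
  ), class = "run_config")
}

validate_config <- function(cfg) {
  if (length(cfg$years) < 1 || any(diff(cfg$years) <= 0))
    stop("config validation error: 'years' must be strictly increasing")
  if (cfg$start_year != cfg$years[1])
    stop("config validation error: 'start_year' must equal the first year")
  if (cfg$n_realizations < 1)
    stop("config validation error: 'n_realizations' must be >= 1")
  if (!is.null(cfg$fixture$cell_size) && cfg$fixture$cell_size <= 0)
    stop("config validation error: 'fixture$cell_size' must be positive")
  bad <- setdiff(cfg$strategies,
                 c("PROTECT", "MIGRATE_UNDEVELOPED", "MIGRATE_DEVELOPED",
                   "EDGE_RESTORE_1974", "THIN_LAYER"))
  if (length(bad))
    stop("config validation error: unknown strategy: ",
         paste(bad, collapse = ", "))
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Missing fields take the [default_config()] values; unknown top-level
#' keys are ignored with a warning.  The configuration is validated
#' eagerly (years strictly increasing, positive cell size, known
#' strategy names, `n_realizations >= 1`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  known <- names(cfg)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  for (key in intersect(names(raw), known)) {
    if (key == "distributions") {
      for (p in names(raw$distributions))
        cfg$distributions[[p]] <- as_dist_spec(raw$distributions[[p]])
    } else if (key %in% c("fixture", "strategy_options")) {
      for (p in names(raw[[key]])) cfg[[key]][[p]] <- raw[[key]][[p]]
    } else {
      cfg[[key]] <- raw[[key]]
    }
  }
  cfg$years <- as.numeric(cfg$years)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_realizations <- as.integer(cfg$n_realizations)
  validate_config(cfg)
}
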