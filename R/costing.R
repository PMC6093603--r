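#' Default cost table
#'
#' Intervention units are the published NYC Parks estimates: thin-layer
#' deposition $550,000 per acre ($1.36M/ha) and marsh-edge restoration
#' $624,000 per acre ($1.54M/ha), with 1 acre = 0.4047 ha.  Land
#' acquisition uses the midpoint of a (low, high) $/ha pair per
#' ownership class, marked up 20% for market inefficiencies; parkland is
#' free by assumption.  The per-class dollar ranges below are
#' illustrative placeholders (the study's class-level appraisals are not
#' public).
#'
#' @return A `cost_table` list.
#' @export
default_cost_table <- function() {
  structure(list(
    land_costs = data.frame(
      class = c("PARKS", "OTHER_PUBLIC", "PRIVATE_DEVELOPED",
                "PRIVATE_UNDEVELOPED"),
      low = c(0, 2e5, 4e6, 1e6),
      high = c(0, 6e5, 8e6, 3e6),
      stringsAsFactors = FALSE),
    thin_layer_unit = 550000,     # $ per acre
    edge_restore_unit = 624000,   # $ per acre
    markup = 0.20,
    acre_to_ha = 0.4047,
    developed_restoration = TRUE,
    footprint_quantile = NULL     # NULL = expected footprint; else P >= q mask
  ), class = "cost_table")
}

#' Load a cost table from CSV
#'
#' The CSV holds the per-ownership-class rows (`class`, `low`, `high` in
#' $/ha); scalar units can be overridden via `...`.
#'
#' @param path CSV path, or `NULL` for [default_cost_table()].
#' @param ... overrides for the scalar fields (e.g. `markup = 0`).
#' @return A `cost_table`.
#' @export
load_cost_table <- function(path = NULL, ...) {
  ct <- default_cost_table()
  if (!is.null(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("class", "low", "high") %in% names(df)))
      stop("cost table CSV needs columns class, low, high")
    ct$land_costs <- df
  }
  dots <- list(...)
  for (k in names(dots)) ct[[k]] <- dots[[k]]
  lc <- ct$land_costs
  if (any(lc$low > lc$high)) stop("cost table: low > high")
  if (any(lc$class == "PARKS" & (lc$low != 0 | lc$high != 0)))
    stop("cost table: PARKS land must have zero migration cost")
  ct
}

#' Expected marsh-migration footprint by site and ownership class
#'
#' Per cell, the probability (realization fraction) that the cell is dry
#' at the start and in a marsh category at the final year under the
#' strategy, minus the same probability under the baseline.  The
#' expected area is the probability-weighted cell area, grouped by site
#' and ownership class.  If `quantile` is given, a hard mask
#' `P >= quantile` is monetised instead of the expectation.
#'
#' @param stacks strategy stacks (list over realizations).
#' @param baseline_stacks baseline (no-action) stacks.
#' @param site_set site set with `site_mask` and `ownership_mask`.
#' @param marsh_codes codes counted as marsh.
#' @param quantile optional probability threshold in (0, 1].
#' @return Data frame `site`, `class`, `area_ha`.
#' @export
migration_footprint <- function(stacks, baseline_stacks, site_set,
                                marsh_codes = MARSH_CODES,
                                quantile = NULL) {
  final_key <- utils::tail(names(stacks[[1]]$states), 1)
  conv_prob <- function(stks) {
    acc <- NULL
    for (stk in stks) {
      start_cov <- stk$states[[1]]$landcover$values
      end_cov <- stk$states[[final_key]]$landcover$values
      conv <- (start_cov %in% DRY_CODES) & (end_cov %in% marsh_codes)
      acc <- if (is.null(acc)) conv + 0 else acc + conv
    }
    acc / length(stks)
  }
  p <- conv_prob(stacks) - conv_prob(baseline_stacks)
  p <- pmax(p, 0)
  if (!is.null(quantile)) p <- (p >= quantile) + 0
  cell_ha <- site_set$site_mask$cell_size^2 / 1e4
  site <- site_set$site_mask$values
  own <- site_set$ownership_mask$values
  sites <- sort(unique(site[site > 0]))
  out <- expand.grid(site = sites, class = names(OWNERSHIP_CLASSES),
                     stringsAsFactors = FALSE)
  out$area_ha <- mapply(function(s, cl) {
    sel <- site == s & own == OWNERSHIP_CLASSES[[cl]]
    sum(p[sel]) * cell_ha
  }, out$site, out$class)
  out
}

#' Land-acquisition cost of a migration footprint
#'
#' Sum over ownership classes of area times the midpoint of the
#' (low, high) $/ha estimate, marked up by `markup`.  Parkland
#' contributes zero.
#'
#' @param footprint data frame `class`, `area_ha` (optionally `site`).
#' @param cost_table a [default_cost_table()]-style list.
#' @return Total dollars.
#' @export
land_cost <- function(footprint, cost_table = default_cost_table()) {
  lc <- cost_table$land_costs
  idx <- match(footprint$class, lc$class)
  if (anyNA(idx)) stop("unknown ownership class: ",
                       paste(unique(footprint$class[is.na(idx)]),
                             collapse = ", "))
  mid <- (lc$low[idx] + lc$high[idx]) / 2
  sum(footprint$area_ha * mid) * (1 + cost_table$markup)
}

#' Cost of a physical intervention over an area
#'
#' `cost = (area_ha / acre_to_ha) * unit_per_acre` — converts hectares
#' to acres and applies the per-acre unit estimate.
#'
#' @param area_ha treated area in hectares.
#' @param unit_per_acre dollars per acre.
#' @param acre_to_ha hectares per acre (default 0.4047).
#' @return Dollars.
#' @export
intervention_cost <- function(area_ha, unit_per_acre, acre_to_ha = 0.4047) {
  stopifnot(area_ha >= 0)
  (area_ha / acre_to_ha) * unit_per_acre
}

# Eligible thin-layer area (ha) per site from the initial land cover.
thin_layer_area_by_site <- function(landcover, site_set, reach = 60) {
  elig <- thin_layer_eligibility(landcover, landcover$cell_size, reach)
  site <- site_set$site_mask$values
  sites <- sort(unique(site[site > 0]))
  cell_ha <- landcover$cell_size^2 / 1e4
  data.frame(site = sites,
             area_ha = vapply(sites, function(s)
               sum(elig[site == s]) * cell_ha, 0))
}

# Restored area (ha) per site under edge restoration.
edge_restore_area_by_site <- function(landcover, site_set) {
  fp <- site_set$footprint_1974$values
  cov <- landcover$values
  eligible <- fp == 1 &
    cov %in% c(CATEGORIES[["OPEN_WATER"]], CATEGORIES[["LOW_TIDAL"]])
  site <- site_set$site_mask$values
  sites <- sort(unique(site[site > 0]))
  cell_ha <- landcover$cell_size^2 / 1e4
  data.frame(site = sites,
             area_ha = vapply(sites, function(s)
               sum(eligible[site == s]) * cell_ha, 0))
}

#' Total cost of one strategy at one site
#'
#' No-action (PROTECT) costs nothing.  Migration strategies are charged
#' the land cost of their expected migration footprint (and, for the
#' developed-land strategy, a physical-restoration charge on converted
#' developed land at the edge-restoration unit).  Thin-layer deposition
#' and edge restoration are charged their per-acre intervention units on
#' the treated area.
#'
#' @param site site id.
#' @param strategy strategy kind (string) or [strategy_config()].
#' @param stacks stacks of the strategy (list over realizations).
#' @param baseline baseline (PROTECT) stacks.
#' @param site_set site set.
#' @param cost_table a `cost_table`.
#' @param initial_landcover the unmodified initial land-cover grid.
#' @return A one-row data frame (site, strategy, land, intervention,
#'   total dollars).
#' @export
strategy_cost <- function(site, strategy, stacks, baseline, site_set,
                          cost_table = default_cost_table(),
                          initial_landcover = NULL) {
  kind <- if (inherits(strategy, "strategy_config")) strategy$kind else strategy
  reach <- if (inherits(strategy, "strategy_config"))
    strategy$deposition_reach else 60
  land <- 0; interv <- 0
  if (kind %in% c("MIGRATE_UNDEVELOPED", "MIGRATE_DEVELOPED")) {
    if (is.null(baseline)) stop("migration costing needs the PROTECT baseline")
    fp <- migration_footprint(stacks, baseline, site_set,
                              quantile = cost_table$footprint_quantile)
    fp <- fp[fp$site == site, ]
    land <- land_cost(fp, cost_table)
    if (kind == "MIGRATE_DEVELOPED" && isTRUE(cost_table$developed_restoration)) {
      dev_ha <- sum(fp$area_ha[fp$class == "PRIVATE_DEVELOPED"])
      interv <- intervention_cost(dev_ha, cost_table$edge_restore_unit,
                                  cost_table$acre_to_ha)
    }
  } else if (kind == "THIN_LAYER") {
    lc <- if (is.null(initial_landcover))
      stacks[[1]]$states[[1]]$landcover else initial_landcover
    ar <- thin_layer_area_by_site(lc, site_set, reach)
    interv <- intervention_cost(ar$area_ha[ar$site == site],
                                cost_table$thin_layer_unit,
                                cost_table$acre_to_ha)
  } else if (kind == "EDGE_RESTORE_1974") {
    lc <- if (is.null(initial_landcover))
      stacks[[1]]$states[[1]]$landcover else initial_landcover
    ar <- edge_restore_area_by_site(lc, site_set)
    interv <- intervention_cost(ar$area_ha[ar$site == site],
                                cost_table$edge_restore_unit,
                                cost_table$acre_to_ha)
  }
  data.frame(site = site, strategy = kind, land_cost = land,
             intervention_cost = interv, total = land + interv,
             stringsAsFactors = FALSE)
}

#' Costs for every (site, strategy) pair of an ensemble
#'
#' @param stacks named list of stack lists from [run_monte_carlo()]
#'   (must include `PROTECT`).
#' @param site_set site set.
#' @param cost_table a `cost_table`.
#' @param initial_landcover the unmodified initial land cover (needed so
#'   thin-layer and edge-restoration areas are judged before the
#'   intervention modifies the state).
#' @return Data frame of cost records.
#' @export
compute_all_costs <- function(stacks, site_set,
                              cost_table = default_cost_table(),
                              initial_landcover = NULL) {
  sites <- sort(unique(site_set$site_mask$values[
    site_set$site_mask$values > 0]))
  baseline <- stacks[["PROTECT"]]
  rows <- list(); k <- 0L
  for (sk in names(stacks)) {
    for (s in sites) {
      k <- k + 1L
      rows[[k]] <- strategy_cost(s, sk, stacks[[sk]], baseline, site_set,
                                 cost_table, initial_landcover)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
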