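#' Land state at one time step
#'
#' @param year calendar year of the state.
#' @param landcover [marsh_grid()] of category codes (see [CATEGORIES]).
#' @param elevation [marsh_grid()] of elevation in metres relative to the
#'   initial mean-tide-level datum.
#' @return A `land_state` list.
#' @export
land_state <- function(year, landcover, elevation) {
  assert_coregistered(landcover, elevation)
  structure(list(year = year, landcover = landcover, elevation = elevation),
            class = "land_state")
}

#' Adaptation strategy configuration
#'
#' The five strategies:
#' \describe{
#'   \item{PROTECT}{armor all dry land; no marsh transgression onto dry
#'     land (the no-action base case).}
#'   \item{MIGRATE_UNDEVELOPED}{allow migration onto undeveloped dry land
#'     (developed land stays armored).}
#'   \item{MIGRATE_DEVELOPED}{allow migration onto all dry land.}
#'   \item{EDGE_RESTORE_1974}{restore the historical (1974) marsh
#'     footprint that is now open water or tidal flat to marsh at mean
#'     tide level; dry land stays armored.}
#'   \item{THIN_LAYER}{one-time deposition of `deposition_thickness` m of
#'     sediment on regularly-flooded marsh within `deposition_reach` m of
#'     open water or dry land; dry land stays armored.}
#' }
#'
#' @param kind one of the five strategy names above.
#' @param deposition_thickness sediment lift in metres (default 0.20).
#' @param deposition_reach sprayer reach in metres (default 60).
#' @param restore_elevation elevation assigned to restored cells, metres
#'   relative to the current mean tide level (default 0 = MTL).
#' @return A `strategy_config` list.
#' @export
strategy_config <- function(kind,
                            deposition_thickness = 0.20,
                            deposition_reach = 60,
                            restore_elevation = 0) {
  kind <- match.arg(kind, c("PROTECT", "MIGRATE_UNDEVELOPED",
                            "MIGRATE_DEVELOPED", "EDGE_RESTORE_1974",
                            "THIN_LAYER"))
  if (kind == "THIN_LAYER" &&
      (deposition_thickness <= 0 || deposition_reach <= 0))
    stop("THIN_LAYER needs positive deposition_thickness and deposition_reach")
  structure(list(kind = kind,
                 deposition_thickness = deposition_thickness,
                 deposition_reach = deposition_reach,
                 restore_elevation = restore_elevation),
            class = "strategy_config")
}

# Dry cells armored under a given strategy, judged from the prior cover.
armored_mask <- function(landcover_values, kind) {
  switch(kind,
         PROTECT = ,
         EDGE_RESTORE_1974 = ,
         THIN_LAYER = landcover_values %in% DRY_CODES,
         MIGRATE_UNDEVELOPED = landcover_values == CATEGORIES[["DRY_DEVELOPED"]],
         MIGRATE_DEVELOPED = rep(FALSE, length(landcover_values)),
         stop("unknown strategy kind: ", kind)) |>
    matrix(nrow(landcover_values), ncol(landcover_values))
}

#' Classify land cover from elevation bands
#'
#' Elevation bands relative to the current local mean tide level:
#' below `-mhhw` open water; `[-mhhw, 0)` tidal flat; `[0, mhhw)`
#' regularly-flooded saltmarsh; `[mhhw, mhhw + salt_boundary_offset)`
#' irregularly-flooded transitional marsh; at or above the salt boundary
#' dry land (keeping the prior developed/undeveloped status).  Armored
#' dry cells keep their prior category regardless of elevation.  Unless
#' `allow_upband` is set (after an intervention raises elevations), a
#' cell's category can only move seaward (down-band) relative to `prior`.
#'
#' @param z_rel elevation matrix, metres above current local MTL.
#' @param mhhw mean higher high water above MTL (m).
#' @param salt_boundary_offset salt boundary above MHHW (m).
#' @param prior prior category matrix.
#' @param armored logical matrix of armored cells (default none).
#' @param allow_upband allow landward (up-band) reclassification.
#' @return Integer matrix of category codes.
#' @export
classify_landcover <- function(z_rel, mhhw, salt_boundary_offset, prior,
                               armored = NULL, allow_upband = FALSE) {
  stopifnot(mhhw > 0, salt_boundary_offset > 0)
  boundary <- mhhw + salt_boundary_offset
  band <- matrix(CATEGORIES[["OPEN_WATER"]], nrow(z_rel), ncol(z_rel))
  band[z_rel >= -mhhw] <- CATEGORIES[["LOW_TIDAL"]]
  band[z_rel >= 0] <- CATEGORIES[["SALTMARSH"]]
  band[z_rel >= mhhw] <- CATEGORIES[["TRANSITIONAL"]]
  dry <- z_rel >= boundary
  band[dry] <- ifelse(prior[dry] == CATEGORIES[["DRY_DEVELOPED"]],
                      CATEGORIES[["DRY_DEVELOPED"]],
                      CATEGORIES[["DRY_UNDEVELOPED"]])
  out <- if (allow_upband) band else pmin(band, prior)
  if (!is.null(armored)) {
    keep <- armored & (prior %in% DRY_CODES)
    out[keep] <- prior[keep]
  }
  storage.mode(out) <- "integer"
  out
}

#' Classify a single cell (scalar convenience wrapper)
#'
#' @param z_rel elevation above current local MTL (m).
#' @param draw a parameter draw supplying `mhhw` and
#'   `salt_boundary_offset`.
#' @param armored is the cell armored?
#' @param prior prior category code.
#' @return A category code.
#' @export
classify_cell <- function(z_rel, draw, armored = FALSE,
                          prior = CATEGORIES[["SALTMARSH"]]) {
  classify_landcover(matrix(z_rel, 1, 1), draw$mhhw,
                     draw$salt_boundary_offset,
                     prior = matrix(as.integer(prior), 1, 1),
                     armored = matrix(armored, 1, 1))[1, 1]
}

#' Accretion feedback over a time interval
#'
#' Marsh cells (saltmarsh and transitional) build elevation at a rate
#' that decreases linearly with elevation within the marsh platform:
#' `dz = dt * (a_max - (a_max - a_min) * clamp(z/boundary, 0, 1))`
#' (rates in mm/yr, converted to metres).  Lower marsh accretes fastest —
#' the feedback that partially offsets collapse losses.  Non-marsh cells
#' are unchanged.
#'
#' @param state a [land_state()].
#' @param draw parameter draw supplying `accretion_max`, `accretion_min`,
#'   `mhhw`, `salt_boundary_offset`.
#' @param dt interval length in years, `> 0`.
#' @param mtl current local mean tide level (m above the initial datum).
#' @return Updated elevation [marsh_grid()].
#' @export
apply_accretion <- function(state, draw, dt, mtl = 0) {
  stopifnot(dt > 0)
  elev <- state$elevation$values
  cover <- state$landcover$values
  boundary <- draw$mhhw + draw$salt_boundary_offset
  z_rel <- elev - mtl
  frac <- pmin(pmax(z_rel / boundary, 0), 1)
  rate_mm <- draw$accretion_max - (draw$accretion_max - draw$accretion_min) * frac
  marsh <- cover %in% MARSH_CODES
  elev[marsh] <- elev[marsh] + dt * rate_mm[marsh] / 1000
  grid_with(state$elevation, elev)
}

#' Marsh-collapse elevation losses at category transitions
#'
#' When a cell converts to a wetter marsh category, rapid decomposition
#' of sub-surface biomass removes elevation capital: transitional
#' (irregularly-flooded) to saltmarsh (regularly-flooded) costs
#' `draw$collapse_ifm_rfm` metres (default mean 0.07 m), saltmarsh to
#' tidal flat costs `draw$collapse_rfm_flat` (default mean 0.19 m).
#' Applied once per transition event; all other cells unchanged.
#'
#' @param prev_cover,new_cover category matrices before/after the step.
#' @param elevation elevation [marsh_grid()].
#' @param draw parameter draw supplying the two collapse losses.
#' @return Updated elevation [marsh_grid()].
#' @export
apply_collapse <- function(prev_cover, new_cover, elevation, draw) {
  elev <- elevation$values
  t2s <- prev_cover == CATEGORIES[["TRANSITIONAL"]] &
    new_cover == CATEGORIES[["SALTMARSH"]]
  s2f <- prev_cover == CATEGORIES[["SALTMARSH"]] &
    new_cover == CATEGORIES[["LOW_TIDAL"]]
  elev[t2s] <- elev[t2s] - draw$collapse_ifm_rfm
  elev[s2f] <- elev[s2f] - draw$collapse_rfm_flat
  grid_with(elevation, elev)
}

#' Thin-layer deposition eligibility mask
#'
#' A saltmarsh cell is eligible when the Euclidean centre-to-centre
#' distance to the nearest open-water or dry cell is at most `reach`
#' (threshold inclusive) — the area a high-pressure sprayer can cover
#' from a barge or truck.  Computed exactly by dilating the target mask
#' with every integer cell offset inside the reach radius.
#'
#' @param landcover category matrix or [marsh_grid()].
#' @param cell_size metres per cell.
#' @param reach sprayer reach in metres.
#' @return Logical matrix of eligible cells.
#' @export
thin_layer_eligibility <- function(landcover, cell_size, reach = 60) {
  cover <- if (inherits(landcover, "marsh_grid")) landcover$values else landcover
  nr <- nrow(cover); nc <- ncol(cover)
  target <- cover == CATEGORIES[["OPEN_WATER"]] | cover %in% DRY_CODES
  r_cells <- floor(reach / cell_size)
  near <- matrix(FALSE, nr, nc)
  for (di in -r_cells:r_cells) {
    for (dj in -r_cells:r_cells) {
      if (sqrt(di^2 + dj^2) * cell_size > reach) next
      if (max(1, 1 - di) > min(nr, nr - di) ||
          max(1, 1 - dj) > min(nc, nc - dj)) next  # offset exceeds grid
      src_i <- max(1, 1 - di):min(nr, nr - di)
      src_j <- max(1, 1 - dj):min(nc, nc - dj)
      near[src_i, src_j] <- near[src_i, src_j] |
        target[src_i + di, src_j + dj]
    }
  }
  (cover == CATEGORIES[["SALTMARSH"]]) & near
}

#' Apply thin-layer deposition at the initial year
#'
#' Adds `strategy$deposition_thickness` m to every eligible saltmarsh
#' cell (see [thin_layer_eligibility()]), then reclassifies the modified
#' cells (allowing up-band movement, since elevation was raised).
#'
#' @param state initial [land_state()].
#' @param strategy a `THIN_LAYER` [strategy_config()].
#' @param draw parameter draw (for reclassification datums).
#' @return Modified [land_state()].
#' @export
apply_thin_layer <- function(state, strategy, draw) {
  stopifnot(strategy$kind == "THIN_LAYER")
  elig <- thin_layer_eligibility(state$landcover,
                                 state$landcover$cell_size,
                                 strategy$deposition_reach)
  elev <- state$elevation$values
  elev[elig] <- elev[elig] + strategy$deposition_thickness
  cover <- state$landcover$values
  band <- classify_landcover(elev, draw$mhhw, draw$salt_boundary_offset,
                             prior = cover, allow_upband = TRUE)
  cover[elig] <- band[elig]
  land_state(state$year,
             grid_with(state$landcover, cover),
             grid_with(state$elevation, elev))
}

#' Apply marsh-edge restoration to the historical footprint
#'
#' Cells inside the 1974 marsh footprint that are currently open water
#' or tidal flat are regraded to the current mean tide level and set to
#' saltmarsh.  All other cells are unchanged.
#'
#' @param state initial [land_state()].
#' @param site_set site set holding `footprint_1974`.
#' @param strategy an `EDGE_RESTORE_1974` [strategy_config()].
#' @param mtl current local mean tide level (m above initial datum).
#' @return Modified [land_state()].
#' @export
apply_edge_restoration <- function(state, site_set, strategy, mtl = 0) {
  stopifnot(strategy$kind == "EDGE_RESTORE_1974")
  fp <- site_set$footprint_1974$values
  if (!any(fp == 1, na.rm = TRUE)) {
    warning("1974 footprint is empty; edge restoration is a no-op")
    return(state)
  }
  cover <- state$landcover$values
  elev <- state$elevation$values
  eligible <- fp == 1 &
    cover %in% c(CATEGORIES[["OPEN_WATER"]], CATEGORIES[["LOW_TIDAL"]])
  elev[eligible] <- mtl + strategy$restore_elevation
  cover[eligible] <- CATEGORIES[["SALTMARSH"]]
  land_state(state$year,
             grid_with(state$landcover, cover),
             grid_with(state$elevation, elev))
}

#' One simulation step between two output years
#'
#' Composition order: accretion over the interval, then the new local
#' mean tide level from the SLR trajectory, then reclassification with
#' strategy-dependent armoring, then collapse losses for the transitions
#' that occurred.  Deterministic given its inputs.
#'
#' @param state [land_state()] at `from_year`.
#' @param draw parameter draw.
#' @param strategy [strategy_config()].
#' @param site_set site set (unused here, kept for interface symmetry).
#' @param from_year,to_year step interval, `to_year > from_year`.
#' @param start_year simulation start year (anchors the SLR trajectory).
#' @return [land_state()] at `to_year`.
#' @export
step_state <- function(state, draw, strategy, site_set,
                       from_year, to_year, start_year = from_year) {
  stopifnot(to_year > from_year)
  mtl_from <- slr_trajectory(draw$slr_2100, start_year, from_year)
  mtl_to <- slr_trajectory(draw$slr_2100, start_year, to_year)
  elev <- apply_accretion(state, draw, dt = to_year - from_year,
                          mtl = mtl_from)
  prior <- state$landcover$values
  armored <- armored_mask(prior, strategy$kind)
  z_rel <- elev$values - mtl_to
  new_cover <- classify_landcover(z_rel, draw$mhhw,
                                  draw$salt_boundary_offset,
                                  prior = prior, armored = armored)
  elev <- apply_collapse(prior, new_cover, elev, draw)
  land_state(to_year, grid_with(state$landcover, new_cover), elev)
}

# Build the (possibly intervention-modified) initial state for a strategy.
initial_state <- function(landcover, elevation, site_set, strategy, draw,
                          start_year) {
  st <- land_state(start_year, landcover, elevation)
  if (strategy$kind == "THIN_LAYER")
    st <- apply_thin_layer(st, strategy, draw)
  if (strategy$kind == "EDGE_RESTORE_1974")
    st <- apply_edge_restoration(st, site_set, strategy, mtl = 0)
  st
}

#' Run the Monte-Carlo ensemble for every strategy
#'
#' Draws `config$n_realizations` Latin-Hypercube parameter sets, builds a
#' spatially autocorrelated elevation-error field per realization, and
#' projects every strategy forward over `config$years`.  Realization `j`
#' of every strategy uses the same parameter draw and error field
#' (common random numbers), so strategy contrasts are not sampling noise.
#' Deterministic for a given `config$seed`.
#'
#' @param config a run configuration (see [default_config()]).
#' @param inputs list with `elevation` and `landcover` [marsh_grid()]s
#'   and a `site_set` (as from [make_synthetic_estuary()]).
#' @return Named list (by strategy kind) of lists of projection stacks;
#'   each stack is `list(strategy, j, draw, states)` with one
#'   [land_state()] per output year.
#' @export
run_monte_carlo <- function(config, inputs) {
  years <- config$years
  start_year <- config$start_year
  stopifnot(years[1] == start_year, config$n_realizations >= 1)
  assert_coregistered(inputs$elevation, inputs$landcover)
  draws <- latin_hypercube_sample(config$distributions,
                                  n = config$n_realizations,
                                  seed = config$seed)
  strategies <- config$strategies
  if (is.character(strategies))
    strategies <- lapply(strategies, strategy_config)
  names(strategies) <- vapply(strategies, `[[`, "", "kind")

  out <- lapply(strategies, function(s) vector("list", length(draws)))
  for (j in seq_along(draws)) {
    draw <- draws[[j]]
    err <- correlated_error_field(dim(inputs$elevation$values),
                                  inputs$elevation$cell_size,
                                  sd = draw$elev_error_sd,
                                  corr_length = draw$elev_corr_length,
                                  seed = sub_seed(config$seed, j, salt = 1L))
    elev_j <- grid_with(inputs$elevation,
                        inputs$elevation$values + err$values)
    for (sk in names(strategies)) {
      strategy <- strategies[[sk]]
      st <- initial_state(inputs$landcover, elev_j, inputs$site_set,
                          strategy, draw, start_year)
      states <- vector("list", length(years))
      names(states) <- as.character(years)
      states[[1]] <- st
      for (k in seq_along(years)[-1]) {
        st <- step_state(st, draw, strategy, inputs$site_set,
                         from_year = years[k - 1], to_year = years[k],
                         start_year = start_year)
        states[[k]] <- st
      }
      out[[sk]][[j]] <- structure(
        list(strategy = sk, j = j, draw = draw, states = states),
        class = "projection_stack")
    }
  }
  out
}

#' Per-cell probability of marsh presence at a year
#'
#' Fraction of realizations whose land-cover category at `year` is in
#' `marsh_codes`.
#'
#' @param stacks list of projection stacks for one strategy.
#' @param year an output year present in every stack.
#' @param marsh_codes category codes counted as marsh
#'   (default [MARSH_CODES]).
#' @return A [marsh_grid()] of fractions in `[0, 1]`.
#' @export
probability_map <- function(stacks, year, marsh_codes = MARSH_CODES) {
  key <- as.character(year)
  if (!key %in% names(stacks[[1]]$states))
    stop("year ", year, " absent from projection stacks")
  tmpl <- stacks[[1]]$states[[key]]$landcover
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  for (stk in stacks) {
    cov <- stk$states[[key]]$landcover$values
    acc <- acc + (cov %in% marsh_codes)
  }
  grid_with(tmpl, acc / length(stacks))
}

#' Incremental probability of marsh presence versus a baseline
#'
#' @param map_strategy,map_baseline co-registered probability maps.
#' @return A [marsh_grid()] of cellwise differences in `[-1, 1]`.
#' @export
incremental_probability <- function(map_strategy, map_baseline) {
  assert_coregistered(map_strategy, map_baseline)
  grid_with(map_strategy, map_strategy$values - map_baseline$values)
}
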