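#' Benefit-per-cost ranking of (site, strategy) pairs
#'
#' Benefit is the aggregated utility gain over the no-action baseline,
#' `Z(strategy) - Z(PROTECT)`, per site; the ranking statistic is
#' benefit per million dollars of strategy cost.  Zero-cost rows with
#' positive benefit are flagged `UNBOUNDED` and listed first (no-action
#' itself has zero benefit and ratio 0).  Ties break by lower cost, then
#' site name.
#'
#' @param z_table data frame `strategy`, `site`, `Z` (from
#'   [aggregate_z()] / [evaluate_utilities()]).
#' @param costs data frame `site`, `strategy`, `total` (from
#'   [compute_all_costs()]).
#' @param pm optional data frame `site`, `strategy`, `persistent_ha`
#'   adding a persistent-marsh-per-$M column.
#' @param baseline baseline strategy name (default `"PROTECT"`).
#' @return A ranking data frame sorted by `benefit_per_musd`.
#' @export
benefit_per_cost <- function(z_table, costs, pm = NULL,
                             baseline = "PROTECT") {
  zb <- z_table[z_table$strategy == baseline, c("site", "Z")]
  if (!nrow(zb)) stop("missing baseline strategy '", baseline,
                      "' in utility table")
  names(zb)[2] <- "Z_baseline"
  tab <- merge(z_table, zb, by = "site")
  tab$benefit <- tab$Z - tab$Z_baseline
  tab <- merge(tab, costs[, c("site", "strategy", "total")],
               by = c("site", "strategy"))
  names(tab)[names(tab) == "total"] <- "cost"
  tab$unbounded <- tab$cost == 0 & tab$benefit > 0
  tab$benefit_per_musd <- ifelse(tab$cost > 0,
                                 tab$benefit / (tab$cost / 1e6), 0)
  if (!is.null(pm)) {
    tab <- merge(tab, pm, by = c("site", "strategy"), all.x = TRUE)
    tab$pm_per_musd <- ifelse(tab$cost > 0,
                              tab$persistent_ha / (tab$cost / 1e6), 0)
  }
  ord <- order(-tab$unbounded, -tab$benefit_per_musd, tab$cost, tab$site)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Ranking restricted to a late-horizon time window
#'
#' Recomputes the time aggregation Q with the time weights zeroed
#' outside `window` and renormalised, re-takes the expectation over
#' realizations, and ranks.  Rankings may legitimately differ from the
#' full-horizon table when, e.g., restored marsh decays late in the
#' century.
#'
#' @param util a `utility_table` from [evaluate_utilities()].
#' @param costs cost table rows as in [benefit_per_cost()].
#' @param window `c(first, last)` years within the run years.
#' @param ... passed to [benefit_per_cost()].
#' @return A ranking data frame.
#' @export
windowed_ranking <- function(util, costs, window, ...) {
  q_tab <- aggregate_q(util$W, window = window)
  z_tab <- aggregate_z(q_tab, z = util$z)
  benefit_per_cost(z_tab, costs, ...)
}

#' Expected utility time series per site
#'
#' Expected W over realizations per (site, year) for one strategy,
#' scaled so the cross-site start-year mean is exactly 100 units.
#'
#' @param util a `utility_table`.
#' @param strategy strategy kind.
#' @return Data frame `site`, `year`, `utility`.
#' @export
utility_time_series <- function(util, strategy = "PROTECT") {
  w <- util$W[util$W$strategy == strategy, ]
  if (!nrow(w)) stop("strategy '", strategy, "' absent from utility table")
  ts <- stats::aggregate(W ~ site + year, data = w, FUN = mean)
  start_mean <- mean(ts$W[ts$year == util$start_year])
  ts$utility <- ts$W * 100 / start_mean
  ts[order(ts$site, ts$year), c("site", "year", "utility")]
}

#' Expected aggregated land cover over time for one site
#'
#' Mean category areas over realizations, in hectares and acres
#' (1 acre = 0.4047 ha).
#'
#' @param stacks stack list for one strategy.
#' @param site site id.
#' @param site_set site set.
#' @param acre_to_ha hectares per acre.
#' @return Data frame `year`, `category`, `area_ha`, `area_acres`.
#' @export
expected_landcover_series <- function(stacks, site, site_set,
                                      acre_to_ha = 0.4047) {
  acc <- NULL
  for (stk in stacks) {
    for (st in stk$states) {
      ar <- category_areas(st$landcover, site_set$site_mask)
      ar <- ar[ar$site == site, ]
      ar$year <- st$year
      acc <- if (is.null(acc)) ar else rbind(acc, ar)
    }
  }
  out <- stats::aggregate(area_ha ~ year + category, data = acc, FUN = mean)
  out$area_acres <- out$area_ha / acre_to_ha
  out[order(out$year, out$category), ]
}

#' Per-service constituents of the aggregated utility
#'
#' The contribution `w_i * S~_i` of each service to W per site, at one
#' year (start year by default), expected over realizations for one
#' strategy.  Contributions sum to W per site.
#'
#' @param util a `utility_table`.
#' @param strategy strategy kind.
#' @param year evaluation year (default the start year).
#' @return Data frame `site`, `service`, `contribution`.
#' @export
service_constituents <- function(util, strategy = "PROTECT", year = NULL) {
  if (is.null(year)) year <- util$start_year
  s <- util$S[util$S$strategy == strategy & util$S$year == year, ]
  if (!nrow(s)) stop("no records for strategy '", strategy,
                     "' at year ", year)
  s$contribution <- s$S_norm * util$weights[s$service]
  out <- stats::aggregate(contribution ~ site + service, data = s,
                          FUN = mean)
  out[order(out$site, out$service), ]
}
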