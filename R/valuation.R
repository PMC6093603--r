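#' Default stakeholder service weights
#'
#' The NYC stakeholder-survey relative ranks of the eleven ecosystem
#' services (percentages as printed, summing to 99.9% due to rounding;
#' renormalised to 1 by [load_weights()] / [evaluate_utilities()]).
#'
#' @return Data frame with columns `service`, `weight_pct`.
#' @export
default_weights <- function() {
  data.frame(
    service = c("carbon_sequestration", "nitrogen_sequestration",
                "phosphorus_sequestration", "dry_land_recreation",
                "marsh_recreation", "underserved_natural_areas",
                "nekton_habitat", "habitat_connectivity",
                "flood_protection", "cultural_historic",
                "natural_area_preservation"),
    weight_pct = c(7.6, 8.2, 7.5, 4.5, 4.5, 8.1, 13.6, 17.7, 14.0, 5.5, 8.7),
    stringsAsFactors = FALSE)
}

#' Load stakeholder weights from CSV
#'
#' Expects columns `service` and `weight_pct` (or `weight`).  Weights
#' are renormalised to sum to exactly 1; the adjustment is reported via
#' a message when it exceeds numerical noise.
#'
#' @param path CSV path, or `NULL` for the shipped defaults.
#' @return Named numeric vector of weights summing to 1.
#' @export
load_weights <- function(path = NULL) {
  df <- if (is.null(path)) default_weights() else
    utils::read.csv(path, stringsAsFactors = FALSE)
  w <- if (!is.null(df$weight_pct)) df$weight_pct else df$weight
  if (any(w < 0)) stop("service weights must be non-negative")
  total <- sum(w)
  if (abs(total - 1) > 1e-9 && abs(total - 100) > 1e-6)
    message(sprintf("renormalising service weights (sum %.4g -> 1)", total))
  stats::setNames(w / total, df$service)
}

#' Default (illustrative) service definitions
#'
#' The per-category coefficients used in the NYC application were
#' stakeholder-derived and are not public; these defaults are
#' illustrative linear forms keyed to the eleven default services.
#' Sequestration services scale with marsh area; habitat services use
#' the marsh/open-water edge; flood protection uses marsh width;
#' recreation uses dry undeveloped (or marsh) area.
#'
#' @return Data frame with one row per service: per-category area
#'   coefficients (per ha), `edge` (per m) and `width` (per m)
#'   coefficients.
#' @export
default_services <- function() {
  svc <- default_weights()$service
  z <- stats::setNames(rep(0, length(svc)), svc)
  df <- data.frame(service = svc,
                   OPEN_WATER = z, LOW_TIDAL = z, SALTMARSH = z,
                   TRANSITIONAL = z, DRY_UNDEVELOPED = z, DRY_DEVELOPED = z,
                   edge = z, width = z, row.names = NULL,
                   stringsAsFactors = FALSE)
  set <- function(s, col, v) df[df$service == s, col] <<- v
  set("carbon_sequestration", c("SALTMARSH", "TRANSITIONAL"), c(2.0, 1.5))
  set("nitrogen_sequestration", c("SALTMARSH", "TRANSITIONAL"), c(2.5, 1.8))
  set("phosphorus_sequestration", c("SALTMARSH", "TRANSITIONAL"), c(1.2, 0.9))
  set("dry_land_recreation", "DRY_UNDEVELOPED", 1.0)
  set("marsh_recreation", c("SALTMARSH", "TRANSITIONAL"), c(0.5, 1.0))
  set("underserved_natural_areas",
      c("SALTMARSH", "TRANSITIONAL", "DRY_UNDEVELOPED"), c(1, 1, 1))
  set("nekton_habitat", c("LOW_TIDAL", "SALTMARSH"), c(0.5, 1.0))
  set("nekton_habitat", "edge", 0.02)
  set("habitat_connectivity", c("SALTMARSH", "TRANSITIONAL"), c(1, 1))
  set("habitat_connectivity", "edge", 0.01)
  set("flood_protection", "width", 0.05)
  set("flood_protection", c("SALTMARSH", "TRANSITIONAL"), c(0.5, 0.5))
  set("cultural_historic", c("SALTMARSH", "TRANSITIONAL", "DRY_UNDEVELOPED"),
      c(0.8, 0.8, 0.4))
  set("natural_area_preservation",
      c("LOW_TIDAL", "SALTMARSH", "TRANSITIONAL", "DRY_UNDEVELOPED"),
      c(0.5, 1, 1, 0.5))
  df
}

#' Load service definitions from CSV
#'
#' @param path CSV with columns `service`, the six category names,
#'   `edge`, `width`; `NULL` for [default_services()].
#' @return Service definition data frame.
#' @export
load_services <- function(path = NULL) {
  if (is.null(path)) return(default_services())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("service", names(CATEGORIES), "edge", "width")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("services table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Raw ecosystem-service value of one metric record
#'
#' `S = (sum_i s_i A_i + edge_coef * interface + width_coef * width) * V`:
#' a linear landscape-feature function times the site multiplier V
#' (relative site quality, constant in time).
#'
#' @param record one row of a [compute_metrics()] table (needs the
#'   `area_*`, `interface_m`, `width_m` columns).
#' @param svc one row of a service definition table.
#' @param V site multiplier (default 1).
#' @return Scalar service value.
#' @export
service_value <- function(record, svc, V = 1) {
  s <- sum(vapply(names(CATEGORIES), function(cat) {
    svc[[cat]] * record[[paste0("area_", cat)]]
  }, 0))
  s <- s + svc$edge * record$interface_m + svc$width * record$width_m
  s * V
}

# Vectorised service values over a whole metrics table -> long table.
compute_service_values <- function(metrics, services = default_services(),
                                   multipliers = NULL) {
  out <- list()
  for (i in seq_len(nrow(services))) {
    svc <- services[i, ]
    s <- rep(0, nrow(metrics))
    for (cat in names(CATEGORIES))
      s <- s + svc[[cat]] * metrics[[paste0("area_", cat)]]
    s <- s + svc$edge * metrics$interface_m + svc$width * metrics$width_m
    V <- rep(1, nrow(metrics))
    if (!is.null(multipliers)) {
      key <- multipliers[multipliers$service == svc$service, ]
      if (nrow(key)) {
        idx <- match(metrics$site, key$site)
        V <- ifelse(is.na(idx), 1, key$V[idx])
      }
    }
    out[[i]] <- data.frame(strategy = metrics$strategy,
                           realization = metrics$realization,
                           year = metrics$year, site = metrics$site,
                           service = svc$service, S = s * V,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalise service values by their initial cross-site means
#'
#' Each service is scaled by its initial average value across all sites
#' (computed on the no-action initial condition and reused for every
#' strategy), yielding non-dimensional values whose cross-site start-year
#' mean is 1.  Services with a zero initial mean are dropped with a
#' warning (the normalisation is undefined).
#'
#' @param s_table long table from `compute_service_values()`.
#' @param start_year first output year.
#' @param baseline_strategy strategy defining the initial condition
#'   (default `"PROTECT"`).
#' @return List: `table` (with added `S_norm` column) and `constants`
#'   (named vector of initial means).
#' @export
normalize_services <- function(s_table, start_year,
                               baseline_strategy = "PROTECT") {
  base <- s_table[s_table$year == start_year &
                    s_table$strategy == baseline_strategy, ]
  if (!nrow(base)) stop("no start-year records for baseline strategy '",
                        baseline_strategy, "'")
  const <- tapply(base$S, base$service, mean)
  dead <- names(const)[const == 0]
  if (length(dead)) {
    warning("dropping services with zero initial mean: ",
            paste(dead, collapse = ", "))
    s_table <- s_table[!s_table$service %in% dead, ]
    const <- const[!names(const) %in% dead]
  }
  s_table$S_norm <- s_table$S / as.numeric(const[s_table$service])
  list(table = s_table, constants = const)
}

#' Weighted aggregation over services
#'
#' `W = sum_i w_i S~_i` per (strategy, realization, year, site).  With
#' the weights summing to 1 and Eq-style normalisation, the cross-site
#' start-year mean of W is exactly 1.
#'
#' @param snorm_table normalised long table (`S_norm` column).
#' @param w named weight vector summing to 1.
#' @return Data frame with column `W`.
#' @export
aggregate_w <- function(snorm_table, w) {
  miss <- setdiff(unique(snorm_table$service), names(w))
  if (length(miss)) stop("missing weight for service: ",
                         paste(miss, collapse = ", "))
  snorm_table$wS <- snorm_table$S_norm * w[snorm_table$service]
  out <- stats::aggregate(wS ~ strategy + realization + year + site,
                          data = snorm_table, FUN = sum)
  names(out)[names(out) == "wS"] <- "W"
  out
}

#' Weighted aggregation over output years
#'
#' `Q = sum_k q_k W_k` per (strategy, realization, site).  `q` defaults
#' to uniform (a plain time average); a window restricts and
#' renormalises `q` to `[window[1], window[2]]`.  A geometric discount
#' is available via `discount` (annual rate; weights proportional to
#' `(1 - discount)^(year - start)`).
#'
#' @param w_table output of [aggregate_w()].
#' @param q optional named (by year) weight vector; must sum to 1.
#' @param window optional `c(first, last)` year window.
#' @param discount optional annual discount rate in `[0, 1)`.
#' @return Data frame with column `Q`.
#' @export
aggregate_q <- function(w_table, q = NULL, window = NULL, discount = NULL) {
  years <- sort(unique(w_table$year))
  if (is.null(q)) {
    q <- stats::setNames(rep(1, length(years)), years)
    if (!is.null(discount)) {
      stopifnot(discount >= 0, discount < 1)
      q <- stats::setNames((1 - discount)^(years - years[1]), years)
    }
  } else {
    if (length(q) != length(years))
      stop("time-weight vector length does not match the output years")
    if (is.null(names(q))) names(q) <- years
  }
  if (!is.null(window)) {
    keep <- years >= window[1] & years <= window[2]
    if (!any(keep)) stop("empty time window")
    q[!keep] <- 0
  }
  q <- q / sum(q)
  w_table$qW <- w_table$W * q[as.character(w_table$year)]
  out <- stats::aggregate(qW ~ strategy + realization + site,
                          data = w_table, FUN = sum)
  names(out)[names(out) == "qW"] <- "Q"
  out
}

#' Weighted aggregation over Monte-Carlo realizations
#'
#' `Z = sum_j z_j Q_j` per (strategy, site): the expectation of Q under
#' the realization weights.  Defaults to equal weights.  Restricting to
#' a band of SLR outcomes (e.g. draws with 1.0–1.5 m by 2100) is done by
#' zero weights outside the band, renormalised.
#'
#' @param q_table output of [aggregate_q()].
#' @param z optional weight vector over realizations (recycled in
#'   realization order; renormalised to sum 1).
#' @return Data frame with column `Z`.
#' @export
aggregate_z <- function(q_table, z = NULL) {
  reals <- sort(unique(q_table$realization))
  if (is.null(z)) z <- rep(1 / length(reals), length(reals))
  if (length(z) != length(reals))
    stop("realization-weight vector length does not match realizations")
  if (sum(z) <= 0) stop("realization weights sum to zero")
  z <- z / sum(z)
  q_table$zQ <- q_table$Q * z[match(q_table$realization, reals)]
  out <- stats::aggregate(zQ ~ strategy + site, data = q_table, FUN = sum)
  names(out)[names(out) == "zQ"] <- "Z"
  out
}

#' Full valuation pipeline
#'
#' Metrics to raw service values S, Eq-style normalisation to S~,
#' stakeholder aggregation to W, time aggregation to Q, and expectation
#' over realizations to Z.
#'
#' @param metrics table from [compute_metrics()].
#' @param services service definitions (default [default_services()]).
#' @param weights named service weights (default [load_weights()]).
#' @param multipliers optional data frame (`site`, `service`, `V`).
#' @param start_year first output year (defaults to the minimum present).
#' @param q,window,discount passed to [aggregate_q()].
#' @param z passed to [aggregate_z()].
#' @return List with `S`, `W`, `Q`, `Z` tables, `constants`, `weights`,
#'   and `start_year`, of class `utility_table`.
#' @export
evaluate_utilities <- function(metrics, services = default_services(),
                               weights = load_weights(),
                               multipliers = NULL, start_year = NULL,
                               q = NULL, window = NULL, discount = NULL,
                               z = NULL) {
  if (is.null(start_year)) start_year <- min(metrics$year)
  weights <- weights / sum(weights)
  s_tab <- compute_service_values(metrics, services, multipliers)
  nrm <- normalize_services(s_tab, start_year)
  w_tab <- aggregate_w(nrm$table, weights)
  q_tab <- aggregate_q(w_tab, q = q, window = window, discount = discount)
  z_tab <- aggregate_z(q_tab, z = z)
  structure(list(S = nrm$table, W = w_tab, Q = q_tab, Z = z_tab,
                 constants = nrm$constants, weights = weights,
                 start_year = start_year, z = z),
            class = "utility_table")
}
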