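#' Land-cover area per site and category
#'
#' Areas are cell counts times `cell_size^2`, reported in hectares.
#' Nodata cells (and cells outside any site) are excluded.
#'
#' @param landcover [marsh_grid()] of category codes.
#' @param site_mask [marsh_grid()] of positive integer site ids.
#' @param cell_size metres per cell (defaults to the grid's).
#' @return Data frame with columns `site`, `category`, `area_ha`,
#'   zero-filled over all six categories for every site.
#' @export
category_areas <- function(landcover, site_mask,
                           cell_size = landcover$cell_size) {
  assert_coregistered(landcover, site_mask)
  cov <- landcover$values; site <- site_mask$values
  ok <- cov != landcover$nodata & site > 0
  sites <- sort(unique(site[site > 0]))
  out <- expand.grid(site = sites, category = names(CATEGORIES),
                     stringsAsFactors = FALSE)
  cnt <- table(factor(site[ok], levels = sites),
               factor(category_name(cov[ok]), levels = names(CATEGORIES)))
  out$area_ha <- as.vector(cnt) * cell_size^2 / 1e4
  out
}

#' Marsh / open-water interface length per site
#'
#' Counts 4-adjacent cell-edge pairs with a marsh cell (saltmarsh or
#' transitional) on one side and open water on the other, times the cell
#' size.  Edges crossing a site boundary are credited to the marsh
#' cell's site.
#'
#' @inheritParams category_areas
#' @return Data frame with columns `site`, `interface_m`.
#' @export
interface_length <- function(landcover, site_mask,
                             cell_size = landcover$cell_size) {
  assert_coregistered(landcover, site_mask)
  cov <- landcover$values; site <- site_mask$values
  nr <- nrow(cov); nc <- ncol(cov)
  marsh <- matrix(cov %in% MARSH_CODES, nr, nc)
  water <- cov == CATEGORIES[["OPEN_WATER"]]
  sites <- sort(unique(site[site > 0]))
  counts <- stats::setNames(numeric(length(sites)), sites)
  tally <- function(m, w, s) {
    hits <- m & w & s > 0
    if (any(hits))
      counts <<- counts + as.numeric(table(factor(s[hits], levels = sites)))
  }
  # vertical edges: marsh cell above/below an open-water neighbour
  tally(marsh[-nr, , drop = FALSE], water[-1, , drop = FALSE],
        site[-nr, , drop = FALSE])
  tally(marsh[-1, , drop = FALSE], water[-nr, , drop = FALSE],
        site[-1, , drop = FALSE])
  # horizontal edges
  tally(marsh[, -nc, drop = FALSE], water[, -1, drop = FALSE],
        site[, -nc, drop = FALSE])
  tally(marsh[, -1, drop = FALSE], water[, -nc, drop = FALSE],
        site[, -1, drop = FALSE])
  data.frame(site = sites, interface_m = as.numeric(counts) * cell_size)
}

#' Marsh width per site
#'
#' A hydraulic width: total marsh area (m^2) divided by the marsh /
#' open-water interface length (m); zero when there is no interface.
#' Exactly the band depth for a rectangular marsh fringe along a
#' straight shore, and rotation-invariant.
#'
#' @inheritParams category_areas
#' @return Data frame with columns `site`, `width_m`.
#' @export
marsh_width <- function(landcover, site_mask,
                        cell_size = landcover$cell_size) {
  ar <- category_areas(landcover, site_mask, cell_size)
  marsh_ha <- stats::aggregate(area_ha ~ site,
                               data = ar[ar$category %in%
                                           category_name(MARSH_CODES), ],
                               FUN = sum)
  il <- interface_length(landcover, site_mask, cell_size)
  m <- merge(marsh_ha, il, by = "site")
  m$width_m <- ifelse(m$interface_m > 0, m$area_ha * 1e4 / m$interface_m, 0)
  m[, c("site", "width_m")]
}

#' Landscape metrics for a whole Monte-Carlo ensemble
#'
#' One row per (strategy, realization, year, site): per-category areas
#' (wide, in ha), marsh/open-water interface length and marsh width.
#'
#' @param stacks named list of stack lists, as from [run_monte_carlo()].
#' @param site_set site set holding `site_mask`.
#' @return A tidy data frame of metric records.
#' @export
compute_metrics <- function(stacks, site_set) {
  site_mask <- site_set$site_mask
  rows <- list(); ri <- 0L
  for (sk in names(stacks)) {
    for (stk in stacks[[sk]]) {
      for (st in stk$states) {
        ar <- category_areas(st$landcover, site_mask)
        wide <- stats::reshape(ar, idvar = "site", timevar = "category",
                               direction = "wide")
        names(wide) <- sub("^area_ha\\.", "area_", names(wide))
        il <- interface_length(st$landcover, site_mask)
        wd <- marsh_width(st$landcover, site_mask)
        rec <- merge(merge(wide, il, by = "site"), wd, by = "site")
        rec <- cbind(strategy = sk, realization = stk$j, year = st$year, rec)
        ri <- ri + 1L
        rows[[ri]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persistence-weighted marsh area relative to a baseline
#'
#' Integrates marsh area over the planning horizon with a left-Riemann
#' rule over the output years, normalised by the horizon length, and
#' subtracts the same integral for the baseline (no-action) stack.  A
#' constant marsh of area A present for a fraction f of the horizon
#' scores f * A, so a marsh persisting 10 of 80 years is worth one
#' eighth of one persisting all 80.
#'
#' @param stack,baseline_stack projection stacks sharing output years.
#' @param site_mask [marsh_grid()] of site ids.
#' @param horizon `c(start, end)` years (default first output year to
#'   2100).
#' @param marsh_codes category codes counted as marsh.
#' @return Data frame with columns `site`, `persistent_ha`.
#' @export
persistent_marsh <- function(stack, baseline_stack, site_mask,
                             horizon = NULL, marsh_codes = MARSH_CODES) {
  years <- as.numeric(names(stack$states))
  if (!identical(names(stack$states), names(baseline_stack$states)))
    stop("stack and baseline do not share output years")
  if (is.null(horizon)) horizon <- c(years[1], 2100)
  span <- horizon[2] - horizon[1]
  pm_of <- function(stk) {
    acc <- NULL
    for (k in seq_along(years)) {
      if (years[k] >= horizon[2]) break
      dt <- min(if (k < length(years)) years[k + 1] else horizon[2],
                horizon[2]) - max(years[k], horizon[1])
      if (dt <= 0) next
      st <- stk$states[[k]]
      ar <- category_areas(st$landcover, site_mask)
      m <- stats::aggregate(area_ha ~ site,
                            data = ar[ar$category %in%
                                        category_name(marsh_codes), ],
                            FUN = sum)
      m$w <- m$area_ha * dt / span
      acc <- if (is.null(acc)) m[, c("site", "w")] else {
        acc$w <- acc$w + m$w; acc
      }
    }
    acc
  }
  a <- pm_of(stack); b <- pm_of(baseline_stack)
  data.frame(site = a$site, persistent_ha = a$w - b$w)
}

#' Expected persistent marsh for a strategy ensemble
#'
#' Mean of [persistent_marsh()] over realizations, optionally with
#' non-uniform realization weights.
#'
#' @param stacks,baseline_stacks lists of stacks (same length).
#' @param site_mask site id grid.
#' @param z optional realization weights (default equal, normalised).
#' @param ... passed to [persistent_marsh()].
#' @return Data frame with columns `site`, `persistent_ha`.
#' @export
expected_persistent_marsh <- function(stacks, baseline_stacks, site_mask,
                                      z = NULL, ...) {
  n <- length(stacks)
  if (is.null(z)) z <- rep(1 / n, n) else z <- z / sum(z)
  acc <- NULL
  for (j in seq_len(n)) {
    pm <- persistent_marsh(stacks[[j]], baseline_stacks[[j]], site_mask, ...)
    if (is.null(acc)) {
      acc <- pm; acc$persistent_ha <- acc$persistent_ha * z[j]
    } else acc$persistent_ha <- acc$persistent_ha + pm$persistent_ha * z[j]
  }
  acc
}
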