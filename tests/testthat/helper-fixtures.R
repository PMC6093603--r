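# Shared fixtures: tiny deterministic draws, grids and configs.

# A fully deterministic parameter draw at the default central values.
mean_draw <- function(slr_2100 = 0, mhhw = 0.7, salt_boundary_offset = 0.3,
                      accretion_max = 0, accretion_min = 0,
                      collapse_ifm_rfm = 0.07, collapse_rfm_flat = 0.19,
                      elev_error_sd = 0, elev_corr_length = 0) {
  list(slr_2100 = slr_2100, mhhw = mhhw,
       salt_boundary_offset = salt_boundary_offset,
       accretion_max = accretion_max, accretion_min = accretion_min,
       collapse_ifm_rfm = collapse_ifm_rfm,
       collapse_rfm_flat = collapse_rfm_flat,
       elev_error_sd = elev_error_sd, elev_corr_length = elev_corr_length,
       j = 1L, sub_seed = 1L)
}

# Point-mass distribution set so Monte-Carlo runs are deterministic.
point_distributions <- function(slr_2100 = 0.5, accretion = 0,
                                elev_error_sd = 0) {
  list(
    slr_2100 = dist_spec("point", value = slr_2100),
    mhhw = dist_spec("point", value = 0.7),
    salt_boundary_offset = dist_spec("point", value = 0.3),
    accretion_max = dist_spec("point", value = accretion),
    accretion_min = dist_spec("point", value = accretion),
    collapse_ifm_rfm = dist_spec("point", value = 0.07),
    collapse_rfm_flat = dist_spec("point", value = 0.19),
    elev_error_sd = dist_spec("point", value = elev_error_sd),
    elev_corr_length = dist_spec("point", value = 0))
}

# A small run configuration for fast end-to-end tests.
small_config <- function(seed = 11L, n_realizations = 2L,
                         years = seq(2016, 2096, by = 20),
                         strategies = c("PROTECT", "MIGRATE_UNDEVELOPED",
                                        "MIGRATE_DEVELOPED",
                                        "EDGE_RESTORE_1974", "THIN_LAYER"),
                         distributions = default_distributions()) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$n_realizations <- n_realizations
  cfg$years <- years
  cfg$start_year <- years[1]
  cfg$strategies <- strategies
  cfg$distributions <- distributions
  cfg$fixture$n_rows <- 24
  cfg$fixture$n_cols <- 24
  cfg
}

# A uniform single-site site set co-registered with a cover grid.
uniform_site_set <- function(cover_grid, site = 1,
                             ownership = OWNERSHIP_CLASSES[["PARKS"]]) {
  d <- dim(cover_grid$values)
  g <- function(v) marsh_grid(matrix(v, d[1], d[2]), cover_grid$cell_size)
  list(site_mask = g(site), ownership_mask = g(ownership),
       footprint_1974 = g(0))
}

# Brute-force per-cell area counting oracle.
oracle_category_areas <- function(cover, site, cell_size) {
  sites <- sort(unique(site[site > 0]))
  out <- expand.grid(site = sites, category = names(CATEGORIES),
                     stringsAsFactors = FALSE)
  out$area_ha <- mapply(function(s, cat) {
    n <- 0
    for (i in seq_len(nrow(cover))) for (j in seq_len(ncol(cover)))
      if (site[i, j] == s && cover[i, j] == CATEGORIES[[cat]]) n <- n + 1
    n * cell_size^2 / 1e4
  }, out$site, out$category)
  out
}

# Exhaustive 4-adjacency marsh/water edge enumeration oracle.
oracle_interface <- function(cover, site, cell_size) {
  nr <- nrow(cover); nc <- ncol(cover)
  sites <- sort(unique(site[site > 0]))
  len <- stats::setNames(numeric(length(sites)), sites)
  is_marsh <- function(v) v %in% MARSH_CODES
  is_water <- function(v) v == CATEGORIES[["OPEN_WATER"]]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 > nr || j2 > nc) next
      a <- cover[i, j]; b <- cover[i2, j2]
      if (is_marsh(a) && is_water(b) && site[i, j] > 0)
        len[as.character(site[i, j])] <- len[as.character(site[i, j])] + 1
      if (is_water(a) && is_marsh(b) && site[i2, j2] > 0)
        len[as.character(site[i2, j2])] <- len[as.character(site[i2, j2])] + 1
    }
  }
  data.frame(site = sites, interface_m = as.numeric(len) * cell_size)
}

# All-pairs Euclidean distance oracle for thin-layer eligibility.
oracle_thin_layer <- function(cover, cell_size, reach) {
  nr <- nrow(cover); nc <- ncol(cover)
  out <- matrix(FALSE, nr, nc)
  targets <- which(cover == CATEGORIES[["OPEN_WATER"]] |
                     cover %in% c(CATEGORIES[["DRY_UNDEVELOPED"]],
                                  CATEGORIES[["DRY_DEVELOPED"]]),
                   arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (cover[i, j] != CATEGORIES[["SALTMARSH"]]) next
    if (nrow(targets) == 0) next
    dmin <- min(sqrt((targets[, 1] - i)^2 + (targets[, 2] - j)^2)) * cell_size
    out[i, j] <- dmin <= reach
  }
  out
}

# Minimal hand-built projection stack from a list of cover matrices.
toy_stack <- function(covers, years, cell_size = 5, strategy = "TOY",
                      j = 1L) {
  states <- lapply(seq_along(years), function(k) {
    g <- marsh_grid(covers[[k]], cell_size)
    list(year = years[k], landcover = g,
         elevation = marsh_grid(covers[[k]] * 0, cell_size))
  })
  names(states) <- years
  structure(list(strategy = strategy, j = j, draw = NULL, states = states),
            class = "projection_stack")
}
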