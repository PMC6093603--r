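#' Generate a synthetic estuary fixture
#'
#' Builds a small test landscape emulating an urban estuary: elevation
#' slopes from open water (below the low-tide datum) in the west up to
#' dry land in the east, cut by a meandering tidal channel, with smooth
#' spatially correlated topographic noise.  Land cover is assigned from
#' elevation with the same band rules as the simulator
#' ([classify_landcover()] at the default tidal datums), ownership is
#' blocked randomly into the four cost classes, sites split the domain
#' into alongshore bands, and a historical (1974) marsh footprint covers
#' a strip of current tidal flat / open water adjacent to today's marsh.
#' Deterministic for a given seed.
#'
#' @param n_rows,n_cols grid shape, both `>= 8`.
#' @param cell_size metres per cell (default 5).
#' @param seed integer seed.
#' @param n_sites number of alongshore site bands (default 2).
#' @param mhhw,salt_boundary_offset tidal datums used for the band
#'   classification (defaults match [default_distributions()]).
#' @return List with `elevation` and `landcover` [marsh_grid()]s and
#'   `site_set` (a list of `site_mask`, `ownership_mask`,
#'   `footprint_1974` grids).
#' @export
make_synthetic_estuary <- function(n_rows = 64, n_cols = 64, cell_size = 5,
                                   seed = 1L, n_sites = 2,
                                   mhhw = 0.7, salt_boundary_offset = 0.3) {
  if (n_rows < 8 || n_cols < 8)
    stop("degenerate fixture shape: need n_rows, n_cols >= 8")
  x <- (col(matrix(0, n_rows, n_cols)) - 0.5) / n_cols   # 0 (west) .. 1 (east)
  elev <- -2 + 5 * x
  # meandering channel depresses elevation
  centre <- n_rows / 2 + 0.2 * n_rows * sin(2 * pi * 1.5 * x)
  rr <- row(matrix(0, n_rows, n_cols))
  # steep-banked channel: quartic profile so open water abuts marsh directly
  elev <- elev - 2.5 * exp(-((rr - centre) / (n_rows / 10))^4)
  noise <- correlated_error_field(c(n_rows, n_cols), cell_size,
                                  sd = 0.15, corr_length = 4 * cell_size,
                                  seed = sub_seed(seed, 1L, salt = 11L))
  elev <- elev + noise$values

  # ownership: coarse random blocks of the four classes
  block <- 8L
  nbr <- ceiling(n_rows / block); nbc <- ceiling(n_cols / block)
  block_classes <- with_seed(sub_seed(seed, 2L, salt = 13L),
                             matrix(sample(OWNERSHIP_CLASSES, nbr * nbc,
                                           replace = TRUE), nbr, nbc))
  own <- block_classes[cbind(as.vector((rr - 1) %/% block + 1),
                             as.vector((col(rr) - 1) %/% block + 1))]
  own <- matrix(own, n_rows, n_cols)

  # dry cells on privately developed blocks are developed dry land
  prior_dev <- matrix(CATEGORIES[["DRY_UNDEVELOPED"]], n_rows, n_cols)
  prior_dev[own == OWNERSHIP_CLASSES[["PRIVATE_DEVELOPED"]]] <-
    CATEGORIES[["DRY_DEVELOPED"]]
  cover <- classify_landcover(elev, mhhw, salt_boundary_offset,
                              prior = prior_dev, allow_upband = TRUE)

  # sites: alongshore (row) bands
  site <- matrix(pmin(((rr - 1) %/% ceiling(n_rows / n_sites)) + 1, n_sites),
                 n_rows, n_cols)

  # 1974 footprint: current low-tidal/open-water cells adjacent (within
  # 2 cells, 4-neighbourhood) to today's marsh
  marsh <- matrix(cover %in% MARSH_CODES, n_rows, n_cols)
  nearm <- marsh
  for (rep_i in 1:2) {
    grown <- nearm
    grown[-1, ] <- grown[-1, ] | nearm[-n_rows, ]
    grown[-n_rows, ] <- grown[-n_rows, ] | nearm[-1, ]
    grown[, -1] <- grown[, -1] | nearm[, -n_cols]
    grown[, -n_cols] <- grown[, -n_cols] | nearm[, -1]
    nearm <- grown
  }
  fp <- (cover %in% c(CATEGORIES[["OPEN_WATER"]], CATEGORIES[["LOW_TIDAL"]])) &
    nearm
  fp <- matrix(as.numeric(fp), n_rows, n_cols)

  g <- function(v) marsh_grid(v, cell_size)
  list(elevation = g(elev),
       landcover = g(cover),
       site_set = list(site_mask = g(site),
                       ownership_mask = g(own),
                       footprint_1974 = g(fp)))
}
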