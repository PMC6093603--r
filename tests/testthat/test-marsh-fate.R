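test_that("elevation bands classify as expected", {
  d <- mean_draw()
  expect_identical(classify_cell(d$mhhw / 2, d), CATEGORIES[["SALTMARSH"]])
  expect_identical(classify_cell(-d$mhhw - 1e-9, d),
                   CATEGORIES[["OPEN_WATER"]])
  expect_identical(classify_cell(-0.1, d), CATEGORIES[["LOW_TIDAL"]])
  expect_identical(classify_cell(0.8, d, prior = CATEGORIES[["TRANSITIONAL"]]),
                   CATEGORIES[["TRANSITIONAL"]])
  # armored developed dry land never converts, even deeply inundated
  expect_identical(classify_cell(-0.5, d, armored = TRUE,
                                 prior = CATEGORIES[["DRY_DEVELOPED"]]),
                   CATEGORIES[["DRY_DEVELOPED"]])
  # unarmored dry land at marsh elevation converts (migration)
  expect_identical(classify_cell(0.3, d, armored = FALSE,
                                 prior = CATEGORIES[["DRY_UNDEVELOPED"]]),
                   CATEGORIES[["SALTMARSH"]])
})

test_that("raising elevation never moves a cell to a lower band", {
  d <- mean_draw()
  set.seed(9)
  for (rep in 1:200) {
    z <- runif(1, -1.5, 1.5)
    dz <- runif(1, 0, 0.5)
    lo <- classify_cell(z, d, prior = CATEGORIES[["DRY_UNDEVELOPED"]])
    hi <- classify_cell(z + dz, d, prior = CATEGORIES[["DRY_UNDEVELOPED"]])
    expect_gte(hi, lo)
  }
})

test_that("accretion follows the elevation-dependent rate law", {
  d <- mean_draw(accretion_max = 6, accretion_min = 6)
  cover <- matrix(CATEGORIES[["SALTMARSH"]], 3, 3)
  elev <- matrix(seq(0, 0.8, length.out = 9), 3, 3)
  st <- land_state(2016, marsh_grid(cover, 5), marsh_grid(elev, 5))
  out <- apply_accretion(st, d, dt = 5)
  expect_equal(out$values, elev + 5 * 6 / 1000)  # constant-rate limit

  d2 <- mean_draw(accretion_max = 8, accretion_min = 2)
  out2 <- apply_accretion(st, d2, dt = 1)
  # z = 0 cell gains a_max, boundary cell gains close to a_min
  expect_equal(out2$values[1, 1] - elev[1, 1], 8 / 1000)
  bnd <- d2$mhhw + d2$salt_boundary_offset
  # brute-force per-cell oracle
  for (i in 1:3) for (j in 1:3) {
    fr <- min(max(elev[i, j] / bnd, 0), 1)
    expect_equal(out2$values[i, j] - elev[i, j],
                 (8 - (8 - 2) * fr) / 1000)
  }
  # non-marsh cells unchanged
  cover[1, 1] <- CATEGORIES[["OPEN_WATER"]]
  st3 <- land_state(2016, marsh_grid(cover, 5), marsh_grid(elev, 5))
  expect_equal(apply_accretion(st3, d2, dt = 1)$values[1, 1], elev[1, 1])
})

test_that("marsh collapse removes elevation capital per transition", {
  d <- mean_draw()
  prev <- matrix(c(CATEGORIES[["TRANSITIONAL"]], CATEGORIES[["SALTMARSH"]],
                   CATEGORIES[["SALTMARSH"]], CATEGORIES[["OPEN_WATER"]]),
                 2, 2)
  new <- matrix(c(CATEGORIES[["SALTMARSH"]], CATEGORIES[["LOW_TIDAL"]],
                  CATEGORIES[["SALTMARSH"]], CATEGORIES[["OPEN_WATER"]]),
                2, 2)
  elev <- marsh_grid(matrix(1, 2, 2), 5)
  out <- apply_collapse(prev, new, elev, d)
  expect_equal(out$values[1, 1], 1 - 0.07)  # transitional -> saltmarsh
  expect_equal(out$values[2, 1], 1 - 0.19)  # saltmarsh -> tidal flat
  expect_equal(out$values[1, 2], 1)         # no transition
  expect_equal(out$values[2, 2], 1)
  # no transitions at all: elevation unchanged
  expect_equal(apply_collapse(prev, prev, elev, d)$values,
               matrix(1, 2, 2))
})

test_that("thin-layer deposition lifts eligible low marsh by 20 cm", {
  d <- mean_draw()
  cover <- matrix(CATEGORIES[["SALTMARSH"]], 5, 40)
  cover[, 1] <- CATEGORIES[["OPEN_WATER"]]
  elev <- matrix(0.10, 5, 40)
  st <- land_state(2016, marsh_grid(cover, 5), marsh_grid(elev, 5))
  out <- apply_thin_layer(st, strategy_config("THIN_LAYER"), d)
  # column 2 is 5 m from water: lifted to 0.30
  expect_equal(out$elevation$values[3, 2], 0.30)
  # column 13 is exactly 60 m from water: threshold inclusive, lifted
  expect_equal(out$elevation$values[3, 13], 0.30)
  # column 14 is 65 m away: unchanged
  expect_equal(out$elevation$values[3, 14], 0.10)
  expect_equal(out$elevation$values[3, 40], 0.10)

  # eligibility mask equals the all-pairs brute-force oracle on 12x12
  set.seed(21)
  rc <- matrix(sample(CATEGORIES, 144, replace = TRUE), 12, 12)
  expect_identical(thin_layer_eligibility(rc, 5, 25),
                   oracle_thin_layer(rc, 5, 25))
})

test_that("edge restoration regrades the 1974 footprint to MTL marsh", {
  cover <- matrix(CATEGORIES[["OPEN_WATER"]], 4, 4)
  cover[2, 2] <- CATEGORIES[["LOW_TIDAL"]]
  cover[3, 3] <- CATEGORIES[["DRY_UNDEVELOPED"]]
  elev <- matrix(-1, 4, 4); elev[3, 3] <- 2
  st <- land_state(2016, marsh_grid(cover, 5), marsh_grid(elev, 5))
  ss <- uniform_site_set(st$landcover)
  fp <- matrix(0, 4, 4); fp[1, 1] <- 1; fp[2, 2] <- 1; fp[3, 3] <- 1
  ss$footprint_1974 <- marsh_grid(fp, 5)
  out <- apply_edge_restoration(st, ss, strategy_config("EDGE_RESTORE_1974"))
  expect_identical(out$landcover$values[1, 1],
                   as.numeric(CATEGORIES[["SALTMARSH"]]))
  expect_equal(out$elevation$values[1, 1], 0)  # current MTL
  expect_identical(out$landcover$values[2, 2],
                   as.numeric(CATEGORIES[["SALTMARSH"]]))
  # dry footprint cell untouched
  expect_identical(out$landcover$values[3, 3], cover[3, 3] + 0)
  # restored count: exactly the qualifying footprint cells
  restored <- sum(out$landcover$values != cover &
                    matrix(TRUE, 4, 4))
  expect_identical(restored, 2L + 0L + 0L)

  ss$footprint_1974 <- marsh_grid(matrix(0, 4, 4), 5)
  expect_warning(out2 <- apply_edge_restoration(
    st, ss, strategy_config("EDGE_RESTORE_1974")), "empty")
  expect_identical(out2$landcover$values, st$landcover$values)
})

test_that("a zero-forcing step is a fixed point and conserves area", {
  est <- make_synthetic_estuary(16, 16, 5, seed = 4)
  d <- mean_draw(slr_2100 = 0, accretion_max = 0, accretion_min = 0)
  st <- land_state(2016, est$landcover, est$elevation)
  out <- step_state(st, d, strategy_config("PROTECT"), est$site_set,
                    2016, 2021, start_year = 2016)
  expect_identical(out$landcover$values + 0, st$landcover$values + 0)
  expect_equal(out$elevation$values, st$elevation$values)

  # under forcing, category areas re-partition but total cell count holds
  d2 <- mean_draw(slr_2100 = 1.5, accretion_max = 4, accretion_min = 1)
  st2 <- st
  for (yr in seq(2021, 2096, 25)) {
    st2 <- step_state(st2, d2, strategy_config("MIGRATE_DEVELOPED"),
                      est$site_set, st2$year, yr, start_year = 2016)
    expect_identical(sum(!is.na(st2$landcover$values)), 256L)
    ar <- category_areas(st2$landcover, est$site_set$site_mask)
    expect_equal(sum(ar$area_ha), 256 * 25 / 1e4)
  }
})

test_that("armoring blocks marsh transgression onto dry land", {
  est <- make_synthetic_estuary(24, 24, 5, seed = 8)
  dry0 <- est$landcover$values %in% DRY_CODES
  d <- mean_draw(slr_2100 = 1.8, accretion_max = 3, accretion_min = 1)
  run_one <- function(kind) {
    st <- land_state(2016, est$landcover, est$elevation)
    for (yr in seq(2026, 2096, 10))
      st <- step_state(st, d, strategy_config(kind), est$site_set,
                       st$year, yr, start_year = 2016)
    st
  }
  protect <- run_one("PROTECT")
  migrate <- run_one("MIGRATE_UNDEVELOPED")
  # no marsh ever appears on initially-dry cells under PROTECT
  expect_identical(sum(protect$landcover$values[dry0] %in% MARSH_CODES), 0L)
  # but migration creates marsh on some initially-dry cells
  expect_gt(sum(migrate$landcover$values[dry0] %in% MARSH_CODES), 0)
  # developed dry land stays armored under MIGRATE_UNDEVELOPED
  dev0 <- est$landcover$values == CATEGORIES[["DRY_DEVELOPED"]]
  expect_true(all(migrate$landcover$values[dev0] ==
                    CATEGORIES[["DRY_DEVELOPED"]]))
})

test_that("Monte-Carlo runs share draws across strategies and are reproducible", {
  cfg <- small_config(seed = 31L, n_realizations = 2L,
                      strategies = c("PROTECT", "MIGRATE_UNDEVELOPED"))
  est <- make_synthetic_estuary(16, 16, 5, seed = 31)
  a <- run_monte_carlo(cfg, est)
  b <- run_monte_carlo(cfg, est)
  expect_identical(a, b)
  # common random numbers: identical draws per realization across strategies
  expect_identical(a$PROTECT[[2]]$draw, a$MIGRATE_UNDEVELOPED[[2]]$draw)
  # PROTECT never converts dry to marsh, exhaustive scan of all outputs
  dry0 <- est$landcover$values %in% DRY_CODES
  for (stk in a$PROTECT) for (st in stk$states)
    expect_identical(sum(st$landcover$values[dry0] %in% MARSH_CODES), 0L)
})

test_that("point-mass Monte-Carlo equals a single deterministic run", {
  cfg <- small_config(seed = 5L, n_realizations = 1L,
                      strategies = "PROTECT",
                      distributions = point_distributions(slr_2100 = 1.0))
  est <- make_synthetic_estuary(16, 16, 5, seed = 5)
  stacks <- run_monte_carlo(cfg, est)
  d <- latin_hypercube_sample(point_distributions(slr_2100 = 1.0),
                              n = 1, seed = 5)[[1]]
  st <- land_state(cfg$start_year, est$landcover, est$elevation)
  for (k in seq_along(cfg$years)[-1]) {
    st <- step_state(st, d, strategy_config("PROTECT"), est$site_set,
                     cfg$years[k - 1], cfg$years[k],
                     start_year = cfg$start_year)
    expect_identical(stacks$PROTECT[[1]]$states[[k]]$landcover$values + 0,
                     st$landcover$values + 0)
  }
})

test_that("probability maps count marsh fractions and difference cleanly", {
  mk <- function(center) {
    cov <- matrix(CATEGORIES[["OPEN_WATER"]], 2, 2)
    cov[1, 1] <- center
    toy_stack(list(cov), years = 2085)
  }
  stacks <- list(mk(CATEGORIES[["SALTMARSH"]]),
                 mk(CATEGORIES[["TRANSITIONAL"]]),
                 mk(CATEGORIES[["SALTMARSH"]]),
                 mk(CATEGORIES[["OPEN_WATER"]]))
  pm <- probability_map(stacks, 2085)
  expect_equal(pm$values[1, 1], 0.75)
  expect_equal(pm$values[2, 2], 0)
  expect_error(probability_map(stacks, 2090), "absent")

  base <- probability_map(stacks[1:2], 2085)
  inc <- incremental_probability(pm, base)
  expect_equal(inc$values, pm$values - base$values)
  inc_rev <- incremental_probability(base, pm)
  expect_equal(inc$values, -inc_rev$values)
  small <- marsh_grid(matrix(0, 3, 3), 5)
  expect_error(incremental_probability(pm, small), "co-registered")
})
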