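#' Default uncertainty distributions for the Monte-Carlo engine
#'
#' The sea-level-rise scenario range spans 0.47 m to 2.01 m by 2100
#' (uniform, since only the bounds of the plausible scenarios are fixed).
#' Marsh-collapse elevation losses are truncated normals centred at the
#' observed means of 0.07 m (irregularly-flooded to regularly-flooded
#' marsh) and 0.19 m (regularly-flooded marsh to tidal flat), sd 0.03 m,
#' truncated at zero.  Tidal datums, accretion rates and the elevation
#' error model default to values typical of a microtidal urban estuary.
#'
#' @return Named list of [dist_spec()] objects, one per uncertain input.
#' @export
default_distributions <- function() {
  list(
    slr_2100            = dist_spec("uniform", min = 0.47, max = 2.01),
    mhhw                = dist_spec("point", value = 0.7),
    salt_boundary_offset = dist_spec("point", value = 0.3),
    accretion_max       = dist_spec("uniform", min = 6, max = 10),   # mm/yr
    accretion_min       = dist_spec("uniform", min = 1, max = 3),    # mm/yr
    collapse_ifm_rfm    = dist_spec("truncated-normal", mean = 0.07,
                                    sd = 0.03, bounds = c(0, Inf)),
    collapse_rfm_flat   = dist_spec("truncated-normal", mean = 0.19,
                                    sd = 0.03, bounds = c(0, Inf)),
    elev_error_sd       = dist_spec("point", value = 0.05),
    elev_corr_length    = dist_spec("point", value = 30)
  )
}

# Evaluate expr with a locally-set RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-realization sub-seed from the master seed (kept well
# inside 32-bit integer range).
sub_seed <- function(seed, j, salt = 0L) {
  as.integer((as.numeric(seed) * 2654435 + j * 97003 + salt * 131) %%
               2147483629)
}

#' Latin-Hypercube sample of the uncertain parameters
#'
#' Draws `n` joint parameter sets.  For every parameter the `n` draws
#' occupy the `n` equal-probability strata of its distribution exactly
#' once (stratified uniforms from [lhs::randomLHS()] pushed through the
#' inverse CDF); strata are permuted independently across parameters.
#' If a draw has `accretion_max < accretion_min` the two are swapped so
#' the accretion feedback stays well-ordered.
#'
#' @param distributions named list of [dist_spec()]s
#'   (default [default_distributions()]).
#' @param n number of draws (realizations), `n >= 1`.
#' @param seed integer seed; the sample is a pure function of it.
#' @return List of `n` parameter draws; each is a named list of scalars
#'   plus `j` (realization index) and `sub_seed`.
#' @export
latin_hypercube_sample <- function(distributions = default_distributions(),
                                   n, seed = 1L) {
  stopifnot(n >= 1)
  distributions <- lapply(distributions, as_dist_spec)
  k <- length(distributions)
  u <- with_seed(seed, lhs::randomLHS(as.integer(n), k))
  draws <- vector("list", n)
  vals <- matrix(NA_real_, n, k, dimnames = list(NULL, names(distributions)))
  for (jj in seq_len(k))
    vals[, jj] <- dist_quantile(distributions[[jj]], u[, jj])
  for (j in seq_len(n)) {
    d <- as.list(vals[j, ])
    if (!is.null(d$accretion_max) && !is.null(d$accretion_min) &&
        d$accretion_max < d$accretion_min) {
      tmp <- d$accretion_max; d$accretion_max <- d$accretion_min
      d$accretion_min <- tmp
    }
    d$j <- j
    d$sub_seed <- sub_seed(seed, j)
    draws[[j]] <- d
  }
  draws
}

# Mirror an out-of-range index back into [1, n] (reflection without
# repeating the edge sample; degenerates to 1 when n == 1).
mirror_index <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  p <- 2L * n - 2L
  k <- (k - 1L) %% p
  ifelse(k < n, k + 1L, 2L * n - 1L - k)
}

# 1-D convolution with reflected edges (keeps length).
conv1d_reflect <- function(x, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  padded <- x[mirror_index((1L - h):(n + h), n)]
  out <- stats::convolve(padded, rev(kernel), type = "open")
  out[(2 * h + 1):(2 * h + n)]
}

#' Spatially autocorrelated elevation-error field
#'
#' White Gaussian noise smoothed by a separable Gaussian kernel whose
#' scale is `corr_length` (in metres), then recentred and rescaled so the
#' field has mean 0 and standard deviation `sd` exactly.
#' `corr_length = 0` degenerates to independent noise; `sd = 0` returns a
#' zero grid.
#'
#' @param shape integer vector `c(nrows, ncols)`.
#' @param cell_size metres per cell edge.
#' @param sd target standard deviation (m), `>= 0`.
#' @param corr_length spatial correlation scale (m), `>= 0`.
#' @param seed integer seed.
#' @return A [marsh_grid()] of elevation errors in metres.
#' @export
correlated_error_field <- function(shape, cell_size, sd, corr_length, seed) {
  stopifnot(sd >= 0, corr_length >= 0, length(shape) == 2)
  nr <- shape[1]; nc <- shape[2]
  if (sd == 0)
    return(marsh_grid(matrix(0, nr, nc), cell_size))
  z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  if (corr_length > 0) {
    sigma <- corr_length / cell_size   # kernel scale in cells
    h <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(seq(-h, h), sd = sigma)
    kern <- kern / sum(kern)
    for (i in seq_len(nr)) z[i, ] <- conv1d_reflect(z[i, ], kern)
    for (j in seq_len(nc)) z[, j] <- conv1d_reflect(z[, j], kern)
  }
  z <- z - mean(z)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z * (sd / s)
  marsh_grid(z, cell_size)
}

#' Sea-level trajectory anchored at 2100
#'
#' Accelerating (quadratic) sea-level offset: `offset(t) = slr_2100 * tau^2`
#' with `tau = (t - start_year) / (2100 - start_year)`.  Zero at the start
#' year, equal to `slr_2100` at 2100, monotone non-decreasing in between.
#'
#' @param slr_2100 total rise by 2100 (m), `>= 0`.
#' @param start_year simulation start year.
#' @param years numeric vector of years in `[start_year, 2100]`.
#' @return Numeric vector of sea-level offsets (m above the initial MTL).
#' @export
slr_trajectory <- function(slr_2100, start_year, years) {
  stopifnot(slr_2100 >= 0)
  if (any(years > 2100)) stop("trajectory year beyond 2100")
  if (any(years < start_year)) stop("trajectory year before start_year")
  tau <- (years - start_year) / (2100 - start_year)
  slr_2100 * tau^2
}

#' Lag-1 spatial autocorrelation of a grid
#'
#' Pearson correlation between horizontally and vertically adjacent cell
#' pairs, pooled.  A convenience diagnostic for
#' [correlated_error_field()].
#'
#' @param grid a [marsh_grid()] or numeric matrix.
#' @return Scalar correlation.
#' @export
lag1_autocorrelation <- function(grid) {
  v <- if (inherits(grid, "marsh_grid")) grid$values else grid
  a <- c(v[-nrow(v), ], v[, -ncol(v)])
  b <- c(v[-1, ], v[, -1])
  stats::cor(a, b)
}
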