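#' Distribution specifications for uncertain parameters
#'
#' Each uncertain input is described by a small list
#' `list(family, params, bounds)`.  Supported families:
#' \describe{
#'   \item{point}{`params = list(value)` — a degenerate (certain) input.}
#'   \item{uniform}{`params = list(min, max)`.}
#'   \item{triangular}{`params = list(min, mode, max)`.}
#'   \item{truncated-normal}{`params = list(mean, sd)` with `bounds =
#'     c(lower, upper)` (defaults `c(0, Inf)`), renormalised on the
#'     truncation interval.}
#' }
#'
#' @param family distribution family name.
#' @param ... family parameters (see above).
#' @param bounds optional length-2 truncation bounds.
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(family, ..., bounds = NULL) {
  known <- c("point", "uniform", "triangular", "truncated-normal")
  if (length(family) != 1L || !family %in% known)
    stop("unsupported distribution family: ", family,
         " (supported: ", paste(known, collapse = ", "), ")")
  spec <- list(family = family, params = list(...), bounds = bounds)
  class(spec) <- "dist_spec"
  dist_quantile(spec, 0.5)  # eager validation
  spec
}

#' Quantile (inverse CDF) of a distribution specification
#'
#' The Latin-Hypercube sampler pushes stratified uniforms through this.
#'
#' @param spec a [dist_spec()].
#' @param p probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
dist_quantile <- function(spec, p) {
  stopifnot(all(p >= 0 & p <= 1))
  pr <- spec$params
  switch(spec$family,
    "point" = rep(as.numeric(pr$value %||% pr[[1]]), length(p)),
    "uniform" = {
      lo <- as.numeric(pr$min %||% pr[[1]]); hi <- as.numeric(pr$max %||% pr[[2]])
      if (hi < lo) stop("uniform: max < min")
      lo + p * (hi - lo)
    },
    "triangular" = {
      a <- as.numeric(pr$min %||% pr[[1]])
      c_ <- as.numeric(pr$mode %||% pr[[2]])
      b <- as.numeric(pr$max %||% pr[[3]])
      if (!(a <= c_ && c_ <= b)) stop("triangular: need min <= mode <= max")
      fc <- if (b > a) (c_ - a) / (b - a) else 0.5
      q <- ifelse(p < fc,
                  a + sqrt(pmax(p, 0) * (b - a) * (c_ - a)),
                  b - sqrt(pmax(1 - p, 0) * (b - a) * (b - c_)))
      as.numeric(q)
    },
    "truncated-normal" = {
      m <- as.numeric(pr$mean %||% pr[[1]]); s <- as.numeric(pr$sd %||% pr[[2]])
      if (s < 0) stop("truncated-normal: sd < 0")
      b <- spec$bounds %||% c(0, Inf)
      if (s == 0) return(rep(pmin(pmax(m, b[1]), b[2]), length(p)))
      plo <- stats::pnorm(b[1], m, s); phi <- stats::pnorm(b[2], m, s)
      stats::qnorm(plo + p * (phi - plo), m, s)
    },
    stop("unsupported distribution family: ", spec$family))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a config entry (list with $family etc., or a bare number meaning a
# point mass) into a dist_spec.
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_spec("point", value = x))
  if (is.list(x) && !is.null(x$family)) {
    do.call(dist_spec, c(list(family = x$family),
                         as.list(x$params),
                         list(bounds = unlist(x$bounds) %||% NULL)))
  } else stop("cannot interpret distribution spec")
}
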