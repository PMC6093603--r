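#' Land-cover category codes
#'
#' The simulator works on six aggregated land-cover categories, ordered from
#' wettest to driest.  `SALTMARSH` is regularly-flooded (low) marsh, between
#' mean tide level (MTL) and mean higher high water (MHHW); `TRANSITIONAL`
#' is irregularly-flooded (high) marsh between MHHW and the salt boundary;
#' `LOW_TIDAL` covers non-vegetated beaches and tidal flats.
#'
#' @format Named integer vector of length six.
#' @export
CATEGORIES <- c(OPEN_WATER = 1L, LOW_TIDAL = 2L, SALTMARSH = 3L,
                TRANSITIONAL = 4L, DRY_UNDEVELOPED = 5L, DRY_DEVELOPED = 6L)

#' Ownership class codes used by the cost model
#'
#' @format Named integer vector of length four.
#' @export
OWNERSHIP_CLASSES <- c(PARKS = 1L, OTHER_PUBLIC = 2L,
                       PRIVATE_DEVELOPED = 3L, PRIVATE_UNDEVELOPED = 4L)

#' Default set of codes counted as marsh
#'
#' Regularly-flooded plus irregularly-flooded marsh.
#' @export
MARSH_CODES <- c(3L, 4L)

DRY_CODES <- c(5L, 6L)

category_name <- function(code) names(CATEGORIES)[match(code, CATEGORIES)]
ownership_name <- function(code) names(OWNERSHIP_CLASSES)[match(code, OWNERSHIP_CLASSES)]
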