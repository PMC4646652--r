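#' Land-cover classes, objectives, landowner types and policy alternatives
#'
#' The simulator works with three land-cover classes, five management
#' objectives, three landowner archetypes and seven policy alternatives.
#' These helpers return the canonical level names, in the fixed order used
#' throughout the package (tables, CSV output, tie-breaking).
#'
#' Land-cover integer codes (used in grids and ASCII raster files) are
#' 1 = GRASSLAND, 2 = AGRICULTURE, 3 = FOREST.
#'
#' @return A character vector of level names.
#' @examples
#' land_covers()
#' policy_alternatives()
#' @name enums
NULL

#' @rdname enums
#' @export
land_covers <- function() c("GRASSLAND", "AGRICULTURE", "FOREST")

#' @rdname enums
#' @export
objectives <- function() {
  c("BIRDS", "CARBON", "WATER_QUALITY", "FINANCIAL_PROFIT", "BIODIVERSITY")
}

#' @rdname enums
#' @export
landowner_types <- function() {
  c("PROFIT_MAXIMIZING_PRODUCER", "SMALL_SCALE_FARMER", "CONSERVATIONIST")
}

#' @rdname enums
#' @export
policy_alternatives <- function() {
  c("OUTREACH_MARKETING", "REGULATORY_ENFORCEMENT", "PUBLIC_LAND_ACQUISITION",
    "BEST_MANAGEMENT_PRACTICES", "ECOSYSTEM_SERVICES_PAYMENTS",
    "ECONOMIC_INCENTIVES", "STATUS_QUO")
}

#' @rdname enums
#' @export
landscape_roles <- function() c("BREEDING", "STOPOVER", "WINTERING")

# match a value against an enumeration, with a useful error
match_enum <- function(x, levels, what) {
  if (length(x) != 1L || is.na(x) || !x %in% levels) {
    stop(sprintf("unknown %s '%s'; must be one of: %s",
                 what, paste(x, collapse = ","), paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  x
}
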