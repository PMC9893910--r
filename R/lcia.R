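# Life-cycle impact characterization: inventory -> midpoints -> endpoint
# damages -> normalized per-person scores.
#
#   Q_j = (T x M)_j     midpoint j from inventory flow T and factor M
#   D_j = (Q x E)_j     endpoint damage from midpoint and damage factor E
#   R   = D / N         dimensionless per-person score via normalization N
#
# Midpoints here are freshwater eutrophication (kg P-eq), marine
# eutrophication (kg N-eq) and water consumption (m3; the total water
# footprint passed through with an implicit factor of 1). Emissions are
# assumed discharged to freshwater (the lake); marine eutrophication of
# freshwater emissions uses the freshwater-compartment marine factors,
# reflecting long-term indirect transport even though nothing is
# discharged to the sea directly.

MIDPOINT_CATEGORIES <- c("freshwater_eutrophication", "marine_eutrophication",
                         "water_consumption")

#' Characterize an inventory into midpoint indicators
#'
#' Multiplies each pollutant load by its characterization factor and sums
#' per category and (scenario, year); appends the water-consumption
#' midpoint as the supplied water footprint unchanged.
#'
#' @param loads data frame of emitted loads with columns `scenario`,
#'   `year`, `pollutant`, `load_kg_yr` (land-use resolution is summed
#'   out; an empty frame or `NULL` yields zero eutrophication midpoints).
#' @param wf data frame with columns `scenario`, `year`, `wf_m3`: total
#'   water footprint per scenario-year, or `NULL` for none.
#' @param factors midpoint factor table, see [default_midpoint_factors()].
#' @param compartment emission compartment of the loads; `"freshwater"`
#'   (default) or `"marine"`.
#' @param strict error on a pollutant with no factor for the compartment
#'   (default); if `FALSE`, unmapped flows are dropped with a message.
#' @return data frame with columns `scenario`, `year`, `category`, `value`
#' @export
#' @examples
#' characterize(data.frame(scenario = "base", year = 2007L,
#'                         pollutant = "NO3", load_kg_yr = 100))
characterize <- function(loads = NULL, wf = NULL,
                         factors = default_midpoint_factors(),
                         compartment = "freshwater", strict = TRUE) {
  fac <- factors[factors$emission_compartment == compartment, , drop = FALSE]
  out <- list()
  if (!is.null(loads) && nrow(loads)) {
    if (any(loads$load_kg_yr < 0)) stop_domain("loads must be >= 0")
    unmapped <- setdiff(unique(loads$pollutant), fac$pollutant)
    if (length(unmapped)) {
      if (strict)
        stop_config("no midpoint factor (compartment '%s') for: %s",
                    compartment, paste(unmapped, collapse = ", "))
      message("dropping unmapped inventory flows: ",
              paste(unmapped, collapse = ", "))
      loads <- loads[!loads$pollutant %in% unmapped, , drop = FALSE]
    }
    if (nrow(loads)) {
      m <- merge(loads, fac[, c("pollutant", "category", "factor")],
                 by = "pollutant")
      m$value <- m$load_kg_yr * m$factor
      agg <- stats::aggregate(value ~ scenario + year + category, data = m,
                              FUN = sum)
      # categories with no contributing flow are still reported as zero
      grid <- unique(loads[, c("scenario", "year")])
      full <- merge(grid,
                    data.frame(category = c("freshwater_eutrophication",
                                            "marine_eutrophication")))
      agg <- merge(full, agg, all.x = TRUE)
      agg$value[is.na(agg$value)] <- 0
      out$loads <- agg
    }
  }
  if (!is.null(wf) && nrow(wf)) {
    if (any(wf$wf_m3 < 0)) stop_domain("water footprint must be >= 0")
    out$wf <- data.frame(scenario = wf$scenario, year = wf$year,
                         category = "water_consumption", value = wf$wf_m3,
                         stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scenario = character(), year = integer(),
                      category = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scenario, res$year, res$category), ]
}

#' Convert midpoints into endpoint damages
#'
#' Applies the endpoint damage factors to every midpoint result, yielding
#' one damage row per endpoint pathway and (scenario, year): human health
#' from water consumption (DALY), terrestrial / freshwater / marine
#' ecosystem damages (species.yr).
#'
#' @param midpoints output of [characterize()]
#' @param factors endpoint factor table, see [default_endpoint_factors()]
#' @return data frame with columns `scenario`, `year`, `endpoint_row`,
#'   `endpoint_group`, `damage`, `normalization`
#' @export
to_endpoints <- function(midpoints, factors = default_endpoint_factors()) {
  missing_fac <- setdiff(unique(midpoints$category), factors$midpoint_category)
  if (length(missing_fac))
    stop_config("no endpoint factor for midpoint categor%s: %s",
                if (length(missing_fac) > 1) "ies" else "y",
                paste(missing_fac, collapse = ", "))
  m <- merge(midpoints, factors, by.x = "category", by.y = "midpoint_category")
  m$damage <- m$value * m$factor
  res <- m[, c("scenario", "year", "endpoint_row", "endpoint_group",
               "damage", "normalization")]
  rownames(res) <- NULL
  res[order(res$scenario, res$year, res$endpoint_row), ]
}

#' Normalize endpoint damages into per-person scores
#'
#' Divides each damage by its global normalization reference and sums the
#' dimensionless scores per endpoint group: `r_health` (human health) and
#' `r_ecosystem` (terrestrial + freshwater + marine rows).
#'
#' @param damages output of [to_endpoints()]
#' @return a list with `rows` (per-row normalized values) and `groups`
#'   (per scenario-year `r_health` and `r_ecosystem` sums)
#' @export
normalize_endpoints <- function(damages) {
  if (any(damages$normalization <= 0))
    stop_config("normalization references must be > 0")
  damages$normalized <- damages$damage / damages$normalization
  grp <- stats::aggregate(normalized ~ scenario + year + endpoint_group,
                          data = damages, FUN = sum)
  wide <- merge(
    stats::setNames(grp[grp$endpoint_group == "human_health",
                        c("scenario", "year", "normalized")],
                    c("scenario", "year", "r_health")),
    stats::setNames(grp[grp$endpoint_group == "ecosystem",
                        c("scenario", "year", "normalized")],
                    c("scenario", "year", "r_ecosystem")),
    by = c("scenario", "year"), all = TRUE)
  wide$r_health[is.na(wide$r_health)] <- 0
  wide$r_ecosystem[is.na(wide$r_ecosystem)] <- 0
  list(rows = damages, groups = wide[order(wide$scenario, wide$year), ])
}
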