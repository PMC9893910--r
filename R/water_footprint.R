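# Green, blue and grey water footprints of agricultural production.
#
# Green water is rain-fed evapotranspiration, blue water the additional
# evapotranspiration under irrigation, and grey water the volume needed to
# dilute the exported pollutant load down to the water-quality standard:
#
#   WF   = GnWF + BWF + GWF
#   GnWF = 10 * ETa                      [m3/ha, ETa in mm]
#   BWF  = 10 * (ETb - ETa)              [m3/ha]
#   GWF  = max_i( L_i / (Cmax_i - Cnat_i) )   [m3/yr, L in kg/yr]
#
# The factor 10 converts a water depth in mm over one hectare to m3.

#' Green water footprint
#'
#' Rain-fed component: `10 * et_a` m3 per hectare, where `et_a` is the
#' growing-season evapotranspiration (mm) without irrigation.
#'
#' @param et_a evapotranspiration without irrigation, mm (vectorized)
#' @return green water footprint, m3/ha
#' @export
#' @examples
#' green_wf(500)  # 5000 m3/ha
green_wf <- function(et_a) {
  check_num(et_a, "et_a")
  if (any(et_a < 0)) stop_domain("et_a must be >= 0")
  10 * et_a
}

#' Blue water footprint
#'
#' Irrigation component: `10 * (et_b - et_a)` m3 per hectare, where
#' `et_b` is total evapotranspiration under irrigation. Zero for
#' rain-fed records (`et_b == et_a`).
#'
#' @param et_b total evapotranspiration under irrigation, mm
#' @param et_a evapotranspiration without irrigation, mm
#' @return blue water footprint, m3/ha
#' @export
blue_wf <- function(et_b, et_a) {
  check_num(et_b, "et_b"); check_num(et_a, "et_a")
  if (any(et_a < 0)) stop_domain("et_a must be >= 0")
  if (any(et_b < et_a))
    stop_domain("et_b < et_a: inconsistent evapotranspiration inputs")
  10 * (et_b - et_a)
}

#' Grey water footprint
#'
#' Dilution volume of the worst pollutant: the maximum over pollutants of
#' `load / (c_max - c_nat)`, with loads in kg/yr and concentrations in
#' mg/L (= g/m3), giving m3/yr. Returns 0 when all loads are zero or no
#' loads are supplied.
#'
#' @param loads either a named numeric vector of loads (kg/yr, names are
#'   pollutants) or a data frame with columns `pollutant` and `load_kg_yr`.
#' @param standards data frame with columns `pollutant`, `c_max_mg_l`,
#'   `c_nat_mg_l`; defaults to the bundled TN/TP standards.
#' @return grey water footprint, m3/yr
#' @export
#' @examples
#' grey_wf(c(TN = 1176, TP = 20))  # TN dominates: 1,069,090.9 m3/yr
grey_wf <- function(loads, standards = default_water_quality_standards()) {
  if (is.data.frame(loads)) {
    pol <- loads$pollutant
    load <- loads$load_kg_yr
  } else {
    pol <- names(loads)
    load <- as.numeric(loads)
  }
  if (length(load) == 0) return(0)
  if (is.null(pol)) stop_config("loads must be named by pollutant")
  if (any(load < 0)) stop_domain("pollutant loads must be >= 0")
  i <- match(pol, standards$pollutant)
  if (anyNA(i))
    stop_config("no water-quality standard for pollutant(s): %s",
                paste(unique(pol[is.na(i)]), collapse = ", "))
  dc <- standards$c_max_mg_l[i] - standards$c_nat_mg_l[i]
  if (any(dc <= 0))
    stop_config("c_max must exceed c_nat for every standard")
  # kg/yr -> g/yr; mg/L == g/m3, so g/yr / (g/m3) = m3/yr
  max(load * 1000 / dc)
}

#' Water footprint per ton of production
#'
#' @param wf_total total water footprint of a land use, m3
#' @param production production mass, ton
#' @return m3/ton
#' @export
wf_per_ton <- function(wf_total, production) {
  check_num(wf_total, "wf_total"); check_num(production, "production")
  if (any(production <= 0))
    stop_domain("production must be > 0 to express a per-ton footprint")
  wf_total / production
}

#' Per-land-use water footprint table
#'
#' Computes green, blue and grey water footprints for every
#' (scenario, land use, year) of a dataset. Green and blue components are
#' per-hectare values scaled by the land-use area; the grey component is
#' the dilution volume of that land use's TN/TP loads (nitrogen species
#' summed into TN, phosphorus species into TP). The invariant
#' `total = green + blue + grey` holds row-wise.
#'
#' @param ds a [scenario_dataset()] with ET (and optionally load) tables
#' @param standards water-quality standards for the grey component
#' @return data frame with columns `scenario`, `lu_name`, `year`,
#'   `green_m3`, `blue_m3`, `grey_m3`, `total_m3`, `basis`
#' @export
water_footprint_table <- function(ds,
                                  standards = default_water_quality_standards()) {
  stopifnot(inherits(ds, "scenario_dataset"))
  et <- ds$et
  if (!nrow(et)) stop_validation("dataset has no ET records")
  area <- ds$land_use$area_ha[match(paste(et$scenario, et$lu_name),
                                    paste(ds$land_use$scenario,
                                          ds$land_use$lu_name))]
  if (anyNA(area))
    stop_validation("ET records reference land uses missing from the land-use table")
  out <- data.frame(scenario = et$scenario, lu_name = et$lu_name,
                    year = et$year,
                    green_m3 = green_wf(et$et_a_mm) * area,
                    blue_m3 = blue_wf(et$et_b_mm, et$et_a_mm) * area,
                    stringsAsFactors = FALSE)
  out$grey_m3 <- vapply(seq_len(nrow(out)), function(r) {
    sel <- ds$loads$scenario == out$scenario[r] &
      ds$loads$lu_name == out$lu_name[r] & ds$loads$year == out$year[r]
    if (!any(sel)) return(0)
    grey_wf(aggregate_tn_tp(ds$loads[sel, , drop = FALSE]), standards)
  }, numeric(1))
  out$total_m3 <- out$green_m3 + out$blue_m3 + out$grey_m3
  out$basis <- "per_landuse"
  out
}

# Sum species loads into TN / TP aggregates (mass as-is, no stoichiometric
# N- or P-content conversion); rows already labelled TN/TP pass through.
aggregate_tn_tp <- function(loads) {
  tn <- sum(loads$load_kg_yr[loads$pollutant %in% c(N_SPECIES, "TN")])
  tp <- sum(loads$load_kg_yr[loads$pollutant %in% c(P_SPECIES, "TP")])
  c(TN = tn, TP = tp)
}
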