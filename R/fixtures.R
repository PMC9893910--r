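# Bundled reference data: land-use outputs of the calibrated watershed model
# for the three management scenarios, the characterization and damage factor
# tables, water-quality standards, and the study's reported endpoint averages.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "basinfef", mustWork = FALSE)
  if (!nzchar(path)) {
    # allow running from a source checkout (pkgload / devtools)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop_config("bundled fixture not found: %s", file)
  path
}

read_extdata <- function(file) {
  utils::read.csv(extdata(file), stringsAsFactors = FALSE)
}

#' Bundled study fixtures
#'
#' Loads the package's bundled reference tables for the semi-arid lake
#' basin study system: per-scenario land-use outputs (yields, water footprint per ton,
#' nutrition production) for the base, BMP1 and BMP2 scenarios; the
#' eutrophication midpoint characterization factors; the endpoint damage
#' and normalization factors; TN/TP water-quality standards; the reported
#' multi-year average normalized endpoint values per scenario; scenario
#' definitions; and named constants (weights, nutrition baseline, global
#' population, farm area, reported load ranges).
#'
#' @return a list with elements `land_use_outputs`, `midpoint_factors`,
#'   `endpoint_factors`, `standards`, `endpoint_averages`, `scenarios`
#'   and `constants`.
#' @export
fef_fixtures <- function() {
  list(
    land_use_outputs = read_extdata("landuse_outputs.csv"),
    midpoint_factors = read_extdata("midpoint_factors.csv"),
    endpoint_factors = read_extdata("endpoint_factors.csv"),
    standards = read_extdata("water_quality_standards.csv"),
    endpoint_averages = read_extdata("endpoint_averages.csv"),
    scenarios = read_extdata("scenarios.csv"),
    constants = fef_constants()
  )
}

#' Study constants
#'
#' Named constants used throughout the accounting: EPI fixed weights
#' (health 0.4, ecosystem 0.6), the entropy weights reported for the
#' 2007-2013 series (health 0.56, ecosystem 0.44), the malnutrition
#' baseline (2,000 cal/day/person), global population (7.75e9), the
#' farming area of the study basin (2,000 ha), and the reported annual
#' N and P load ranges delivered to the lake (kg/yr).
#'
#' @return a named list
#' @export
fef_constants <- function() {
  list(
    epi_w_health = 0.4,
    epi_w_ecosystem = 0.6,
    entropy_w_health = 0.56,
    entropy_w_ecosystem = 0.44,
    nutrition_baseline_cal_day = 2000,
    population = 7.75e9,
    farm_area_ha = 2000,
    n_load_range_kg_yr = c(1176, 3985),
    p_load_range_kg_yr = c(20, 82),
    year_days = 365
  )
}

#' Default TN/TP water-quality standards
#'
#' Maximum allowable (`c_max_mg_l`) and natural background
#' (`c_nat_mg_l`) concentrations for total nitrogen (1.5 / 0.4 mg/L) and
#' total phosphorus (0.035 / 0.01 mg/L), the global limits for keeping
#' lakes out of a eutrophic state, used as the dilution standard of the
#' grey water footprint.
#'
#' @return data frame with columns `pollutant`, `c_max_mg_l`, `c_nat_mg_l`
#' @export
default_water_quality_standards <- function() {
  read_extdata("water_quality_standards.csv")
}

#' Default midpoint characterization factors
#'
#' Eutrophication characterization factors (kg P-eq or kg N-eq per kg
#' emitted) per pollutant and emission compartment. Note the bundled
#' phosphate-to-freshwater factor is 33 kg P-eq/kg as tabulated in the
#' source coefficient set; the mass-fraction value would be ~0.33.
#' Override via the `factors` argument of [characterize()] if a
#' different coefficient set applies.
#'
#' @return data frame with columns `pollutant`, `emission_compartment`,
#'   `category`, `factor`, `unit`
#' @export
default_midpoint_factors <- function() {
  read_extdata("midpoint_factors.csv")
}

#' Default endpoint damage and normalization factors
#'
#' Conversion factors from midpoint units into endpoint damages (DALY for
#' human health, species.yr for ecosystems) and the per-row global
#' normalization references.
#'
#' @return data frame with columns `endpoint_row`, `midpoint_category`,
#'   `endpoint_group`, `factor`, `factor_unit`, `normalization`
#' @export
default_endpoint_factors <- function() {
  read_extdata("endpoint_factors.csv")
}
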