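# Data model and I/O for basin-model outputs: land-use records, annual
# pollutant load series and evapotranspiration series, grouped per scenario.

POLLUTANTS <- c("NO3", "NO2", "NH3", "PO4", "P", "TN", "TP")
N_SPECIES <- c("NO3", "NO2", "NH3")
P_SPECIES <- c("PO4", "P")

LAND_USE_COLS <- c("scenario", "lu_name", "irrigated", "area_ha",
                   "yield_ton_ha", "caloric_cal_kg")
LOAD_COLS <- c("scenario", "lu_name", "year", "pollutant", "load_kg_yr")
ET_COLS <- c("scenario", "lu_name", "year", "et_a_mm", "et_b_mm")

# multiplicative factors to kg / mm / ha / (ton/ha)
UNIT_FACTORS <- list(
  load = c("kg/yr" = 1, "ton/yr" = 1000, "g/yr" = 1e-3),
  et   = c("mm" = 1, "m" = 1000),
  area = c("ha" = 1, "km2" = 100, "m2" = 1e-4),
  yield = c("ton/ha" = 1, "kg/ha" = 1e-3)
)

#' Assemble a validated scenario dataset
#'
#' Bundles the three tables a basin-model export provides — land-use
#' records, annual pollutant loads delivered to the receiving water, and
#' annual evapotranspiration with (`et_b_mm`) and without (`et_a_mm`)
#' irrigation — into a single validated object keyed by
#' (scenario, land use, year).
#'
#' @param land_use data frame with columns `scenario`, `lu_name`,
#'   `irrigated` (logical), `area_ha`, `yield_ton_ha`, `caloric_cal_kg`
#'   and optionally `nutrition_mcal_yr` (computed from yield, area and
#'   caloric value when absent) and `wf_m3_ton`.
#' @param loads data frame with columns `scenario`, `lu_name`, `year`,
#'   `pollutant` (one of NO3, NO2, NH3, PO4, P, TN, TP) and `load_kg_yr`.
#' @param et data frame with columns `scenario`, `lu_name`, `year`,
#'   `et_a_mm`, `et_b_mm`.
#' @return An object of class `scenario_dataset`: a list with elements
#'   `land_use`, `loads`, `et`.
#' @export
scenario_dataset <- function(land_use, loads = NULL, et = NULL) {
  land_use <- validate_land_use(land_use)
  loads <- validate_loads(loads)
  et <- validate_et(et)
  structure(list(land_use = land_use, loads = loads, et = et),
            class = "scenario_dataset")
}

#' @export
print.scenario_dataset <- function(x, ...) {
  cat("<scenario_dataset>\n")
  cat("  scenarios:", paste(sort(unique(x$land_use$scenario)), collapse = ", "), "\n")
  cat("  land uses:", length(unique(x$land_use$lu_name)), "\n")
  if (nrow(x$loads))
    cat("  load rows:", nrow(x$loads), " years:",
        paste(range(x$loads$year), collapse = "-"), "\n")
  if (nrow(x$et)) cat("  ET rows:  ", nrow(x$et), "\n")
  invisible(x)
}

empty_loads <- function() {
  data.frame(scenario = character(), lu_name = character(),
             year = integer(), pollutant = character(),
             load_kg_yr = numeric(), stringsAsFactors = FALSE)
}

empty_et <- function() {
  data.frame(scenario = character(), lu_name = character(), year = integer(),
             et_a_mm = numeric(), et_b_mm = numeric(), stringsAsFactors = FALSE)
}

validate_land_use <- function(land_use) {
  need <- setdiff(LAND_USE_COLS, names(land_use))
  if (length(need))
    stop_config("land-use table is missing required column(s): %s",
                paste(need, collapse = ", "))
  land_use$irrigated <- as.logical(land_use$irrigated)
  if (anyNA(land_use$irrigated))
    stop_validation("land-use column 'irrigated' has non-logical values")
  for (col in c("area_ha", "yield_ton_ha", "caloric_cal_kg")) {
    bad <- which(!is.na(land_use[[col]]) & land_use[[col]] < 0)
    if (length(bad))
      stop_validation("negative %s at land-use row %d", col, bad[1])
  }
  key <- paste(land_use$scenario, land_use$lu_name)
  if (anyDuplicated(key))
    stop_validation("duplicate (scenario, land use) key: %s",
                    key[anyDuplicated(key)])
  if (is.null(land_use$nutrition_mcal_yr))
    land_use$nutrition_mcal_yr <- NA_real_
  miss <- is.na(land_use$nutrition_mcal_yr)
  # nutrition [MCal/yr] = yield [ton/ha] x area [ha] x 1000 [kg/ton]
  #                       x caloric value [cal/kg] / 1e6 [cal/MCal]
  land_use$nutrition_mcal_yr[miss] <- with(land_use[miss, , drop = FALSE],
    yield_ton_ha * area_ha * 1000 * caloric_cal_kg / 1e6)
  if (anyNA(land_use$nutrition_mcal_yr))
    stop_validation(
      "land-use row %d has neither nutrition_mcal_yr nor computable inputs",
      which(is.na(land_use$nutrition_mcal_yr))[1])
  land_use
}

validate_loads <- function(loads) {
  if (is.null(loads) || !nrow(loads)) return(empty_loads())
  need <- setdiff(LOAD_COLS, names(loads))
  if (length(need))
    stop_config("load table is missing required column(s): %s",
                paste(need, collapse = ", "))
  unknown <- setdiff(unique(loads$pollutant), POLLUTANTS)
  if (length(unknown))
    stop_validation("unknown pollutant(s) in load table: %s",
                    paste(unknown, collapse = ", "))
  bad <- which(is.na(loads$load_kg_yr) | loads$load_kg_yr < 0)
  if (length(bad))
    stop_validation("negative or missing load at load-table row %d", bad[1])
  key <- paste(loads$scenario, loads$lu_name, loads$year, loads$pollutant)
  dup <- anyDuplicated(key)
  if (dup)
    stop_validation("duplicate (scenario, land use, year, pollutant) key: %s",
                    key[dup])
  loads$year <- as.integer(loads$year)
  loads[LOAD_COLS]
}

validate_et <- function(et) {
  if (is.null(et) || !nrow(et)) return(empty_et())
  need <- setdiff(ET_COLS, names(et))
  if (length(need))
    stop_config("ET table is missing required column(s): %s",
                paste(need, collapse = ", "))
  bad <- which(is.na(et$et_a_mm) | et$et_a_mm < 0)
  if (length(bad))
    stop_validation("negative or missing et_a_mm at ET-table row %d", bad[1])
  bad <- which(is.na(et$et_b_mm) | et$et_b_mm < et$et_a_mm)
  if (length(bad))
    stop_validation("et_b_mm below et_a_mm at ET-table row %d", bad[1])
  et$year <- as.integer(et$year)
  key <- paste(et$scenario, et$lu_name, et$year)
  dup <- anyDuplicated(key)
  if (dup)
    stop_validation("duplicate (scenario, land use, year) key in ET table: %s",
                    key[dup])
  et[ET_COLS]
}

apply_column_map <- function(df, map, what) {
  if (is.null(map)) return(df)
  for (canon in names(map)) {
    src <- map[[canon]]
    if (!src %in% names(df))
      stop_config("%s table: mapped column '%s' (for '%s') not found",
                  what, src, canon)
    names(df)[names(df) == src] <- canon
  }
  df
}

convert_unit <- function(x, unit, kind, what) {
  factors <- UNIT_FACTORS[[kind]]
  if (!unit %in% names(factors))
    stop_config("%s: unsupported unit '%s' (supported: %s)",
                what, unit, paste(names(factors), collapse = ", "))
  x * factors[[unit]]
}

#' Read basin-model scenario tables from delimited files
#'
#' Reads the land-use, load and ET tables from CSV files, renames columns
#' through a user-supplied column map, applies declared unit conversions
#' and returns a validated [scenario_dataset()]. HRU-level load rows (same
#' scenario, land use, year, pollutant) are summed to land-use level.
#'
#' @param land_use,loads,et paths to CSV files; `loads` and `et` may be
#'   `NULL` when only nutrition accounting is needed.
#' @param column_map optional named list of lists, e.g.
#'   `list(loads = c(load_kg_yr = "NSURQ"), et = c(et_a_mm = "ET"))`,
#'   mapping canonical column names to file headers per table.
#' @param units optional named character vector declaring input units,
#'   e.g. `c(load = "ton/yr")`. Defaults: load `kg/yr`, et `mm`,
#'   area `ha`, yield `ton/ha`.
#' @param aggregate_hrus sum duplicate load keys (HRU rows) instead of
#'   rejecting them. Default `TRUE`.
#' @return a [scenario_dataset()]
#' @export
read_scenario_tables <- function(land_use, loads = NULL, et = NULL,
                                 column_map = NULL, units = NULL,
                                 aggregate_hrus = TRUE) {
  units <- utils::modifyList(
    list(load = "kg/yr", et = "mm", area = "ha", yield = "ton/ha"),
    as.list(units %||% list()))
  read1 <- function(path, what) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path))
      stop_config("%s table: file not found: %s", what, path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    apply_column_map(df, column_map[[what]], what)
  }
  lu <- read1(land_use, "land_use")
  if (is.null(lu)) stop_config("a land-use table is required")
  if ("area_ha" %in% names(lu))
    lu$area_ha <- convert_unit(lu$area_ha, units$area, "area", "land_use")
  if ("yield_ton_ha" %in% names(lu))
    lu$yield_ton_ha <- convert_unit(lu$yield_ton_ha, units$yield, "yield",
                                    "land_use")
  ld <- read1(loads, "loads")
  if (!is.null(ld) && nrow(ld)) {
    if (!"load_kg_yr" %in% names(ld))
      stop_config("loads table is missing required column(s): load_kg_yr")
    ld$load_kg_yr <- convert_unit(ld$load_kg_yr, units$load, "load", "loads")
    if (aggregate_hrus)
      ld <- stats::aggregate(load_kg_yr ~ scenario + lu_name + year + pollutant,
                             data = ld, FUN = sum)
  }
  ev <- read1(et, "et")
  if (!is.null(ev) && nrow(ev)) {
    for (col in c("et_a_mm", "et_b_mm"))
      if (col %in% names(ev))
        ev[[col]] <- convert_unit(ev[[col]], units$et, "et", "et")
  }
  scenario_dataset(lu, ld, ev)
}

#' Write a scenario dataset to delimited files
#'
#' Writes the three member tables as CSV in the same dialect
#' [read_scenario_tables()] reads, so that a write/read round trip
#' reproduces the dataset.
#'
#' @param ds a [scenario_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written (named `land_use`, `loads`, `et`)
#' @export
write_scenario_tables <- function(ds, dir) {
  stopifnot(inherits(ds, "scenario_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(land_use = file.path(dir, "land_use.csv"),
             loads = file.path(dir, "loads.csv"),
             et = file.path(dir, "et.csv"))
  utils::write.csv(ds$land_use, paths["land_use"], row.names = FALSE)
  utils::write.csv(ds$loads, paths["loads"], row.names = FALSE)
  utils::write.csv(ds$et, paths["et"], row.names = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
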