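# The food environmental footprint: FEF = C / S, cumulative environmental
# impact per unit of normalized nutrition production. S normalizes the
# basin's daily caloric output by a malnutrition baseline (2,000
# cal/day/person) times the global population, so FEF near 0 indicates
# clean production and FEF > 1 production whose damages outweigh its
# normalized nutrition value.

#' Total nutrition production of a set of land uses
#'
#' Sums per-land-use nutrition output (MCal/yr). Records lacking a direct
#' `nutrition_mcal_yr` value must carry `yield_ton_ha`, `area_ha` and
#' `caloric_cal_kg`, from which nutrition is computed.
#'
#' @param records land-use data frame (one scenario)
#' @param year_days days per year used for the MCal/yr to cal/day
#'   conversion (default 365)
#' @return list with `mcal_yr` (MCal/yr) and `cal_day` (cal/day)
#' @export
nutrition_total <- function(records, year_days = 365) {
  if (!nrow(records)) return(list(mcal_yr = 0, cal_day = 0))
  n <- records$nutrition_mcal_yr
  if (is.null(n)) n <- rep(NA_real_, nrow(records))
  miss <- is.na(n)
  if (any(miss)) {
    need <- c("yield_ton_ha", "area_ha", "caloric_cal_kg")
    if (!all(need %in% names(records)) ||
        anyNA(records[miss, need]))
      stop_validation(
        "record %d has neither nutrition_mcal_yr nor yield/area/caloric inputs",
        which(miss)[1])
    n[miss] <- with(records[miss, , drop = FALSE],
                    yield_ton_ha * area_ha * 1000 * caloric_cal_kg / 1e6)
  }
  mcal <- sum(n)
  list(mcal_yr = mcal, cal_day = mcal * 1e6 / year_days)
}

#' Nutrition index S
#'
#' `S = T_cal / (B x P)`: daily caloric production normalized by the
#' malnutrition baseline `B` (cal/day/person) times the global
#' population `P`.
#'
#' @param t_cal_day total nutrition production, cal/day
#' @param baseline malnutrition baseline, cal/day/person (default 2,000)
#' @param population persons (default 7.75e9)
#' @return dimensionless per-person nutrition index
#' @export
s_index <- function(t_cal_day, baseline = 2000, population = 7.75e9) {
  check_num(t_cal_day, "t_cal_day")
  if (baseline <= 0 || population <= 0)
    stop_domain("baseline and population must be > 0")
  if (any(t_cal_day < 0)) stop_domain("t_cal_day must be >= 0")
  t_cal_day / (baseline * population)
}

#' Food environmental footprint
#'
#' `FEF = C / S`: cumulative impact per unit of normalized nutrition
#' production.
#'
#' @param c_value cumulative impact C (dimensionless per person per year)
#' @param s nutrition index S (> 0)
#' @return FEF (dimensionless)
#' @export
fef <- function(c_value, s) {
  check_num(c_value, "c_value"); check_num(s, "s")
  if (any(s <= 0))
    stop_domain("nutrition index S must be > 0 for a defined footprint")
  if (any(c_value < 0)) stop_domain("cumulative impact must be >= 0")
  c_value / s
}

#' Percent reduction relative to a base value
#'
#' `100 * (base - value) / base`; negative when the scenario value
#' exceeds the base (an increase).
#'
#' @param base_value base-scenario value (> 0)
#' @param scenario_value scenario value
#' @return percent reduction
#' @export
percent_reduction <- function(base_value, scenario_value) {
  check_num(base_value, "base_value"); check_num(scenario_value, "scenario_value")
  if (any(base_value <= 0))
    stop_domain("base value must be > 0 for a percent reduction")
  100 * (base_value - scenario_value) / base_value
}

#' Areal export coefficient
#'
#' Annual pollutant mass exported per hectare of farmland.
#'
#' @param load_kg_yr pollutant load, kg/yr
#' @param area_ha farmed area, ha (> 0)
#' @return export coefficient, kg/ha/yr
#' @export
export_coefficient <- function(load_kg_yr, area_ha) {
  check_num(load_kg_yr, "load_kg_yr"); check_num(area_ha, "area_ha")
  if (any(area_ha <= 0)) stop_domain("area must be > 0")
  load_kg_yr / area_ha
}

#' Compare scenarios against a base
#'
#' Tabulates cumulative impact `C`, nutrition index `S` and `FEF` per
#' scenario and weighting method, with percent reductions relative to the
#' base scenario. Any additional numeric columns in `results` (loads,
#' water footprints) gain reduction columns as well.
#'
#' @param results data frame with columns `scenario`, `method`, `c_value`,
#'   `s`, `fef` (one row per scenario x weighting method) plus optional
#'   extra numeric columns.
#' @param base_id scenario label of the base (default `"base"`)
#' @return a `comparison_report`: `results` augmented with
#'   `*_reduction_pct` columns
#' @export
compare_scenarios <- function(results, base_id = "base") {
  need <- c("scenario", "method", "c_value", "s", "fef")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop_validation("results are missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (anyNA(results[need]))
    stop_validation("results contain missing values in required columns")
  if (!base_id %in% results$scenario)
    stop_config("base scenario '%s' not present in results", base_id)
  numcols <- setdiff(names(results)[vapply(results, is.numeric, logical(1))],
                     character())
  out <- results
  for (col in numcols) {
    red <- rep(NA_real_, nrow(out))
    for (m in unique(out$method)) {
      sel <- out$method == m
      base_val <- out[[col]][sel & out$scenario == base_id]
      if (length(base_val) == 1 && base_val > 0)
        red[sel] <- percent_reduction(base_val, out[[col]][sel])
    }
    out[[paste0(col, "_reduction_pct")]] <- red
  }
  structure(out, class = c("comparison_report", "data.frame"),
            base_id = base_id)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Scenario comparison (base: ", attr(x, "base_id"), ")\n", sep = "")
  df <- as.data.frame(x)
  # report granularity: FEF to 2 decimals, percentages to 1
  for (col in names(df)) {
    if (col == "fef") df[[col]] <- round(df[[col]], 2)
    if (grepl("_reduction_pct$", col)) df[[col]] <- round(df[[col]], 1)
  }
  print(df, row.names = FALSE)
  invisible(x)
}
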