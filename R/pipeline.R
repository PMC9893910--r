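# End-to-end accounting: dataset -> water footprints -> midpoints ->
# endpoint damages -> normalized groups -> weighted cumulative impact ->
# nutrition index -> FEF -> scenario comparison.

#' Run the full basin-to-FEF accounting pipeline
#'
#' From a validated [scenario_dataset()], computes per-land-use water
#' footprints, characterizes loads and total water footprint into
#' midpoints, converts to normalized endpoint damages per year, derives
#' entropy weights from the per-year group series (pooled across
#' scenarios by default), averages the normalized groups over years per
#' scenario, aggregates into the cumulative impact `C` under the
#' requested weighting method(s), computes the nutrition index `S` and
#' `FEF = C/S`, and tabulates a comparison against the base scenario.
#'
#' @param ds a [scenario_dataset()] with loads and ET tables
#' @param weighting `"entropy"`, `"epi"` or `"both"` (default)
#' @param base_id label of the base scenario (default `"base"`)
#' @param entropy_pooling `"pooled"` (default): one weight pair from the
#'   year series of all scenarios stacked; `"per_scenario"`: weights from
#'   the base scenario's series only.
#' @param standards,midpoint_factors,endpoint_factors coefficient tables
#' @param baseline,population,year_days nutrition-index constants
#' @return a `fef_run` list: `wf` (per-land-use footprints), `midpoints`,
#'   `endpoints`, `groups` (per scenario-year normalized scores),
#'   `weights` (per method), `results` (per scenario x method `c_value`,
#'   `s`, `fef`, loads and WF), `comparison`
#' @export
run_fef_pipeline <- function(ds, weighting = c("both", "entropy", "epi"),
                             base_id = "base",
                             entropy_pooling = c("pooled", "per_scenario"),
                             standards = default_water_quality_standards(),
                             midpoint_factors = default_midpoint_factors(),
                             endpoint_factors = default_endpoint_factors(),
                             baseline = 2000, population = 7.75e9,
                             year_days = 365) {
  weighting <- match.arg(weighting)
  entropy_pooling <- match.arg(entropy_pooling)
  stopifnot(inherits(ds, "scenario_dataset"))
  if (!nrow(ds$loads)) stop_validation("dataset has no pollutant loads")

  wf <- water_footprint_table(ds, standards = standards)
  wf_year <- stats::aggregate(total_m3 ~ scenario + year, data = wf, FUN = sum)
  names(wf_year)[names(wf_year) == "total_m3"] <- "wf_m3"

  loads_year <- stats::aggregate(load_kg_yr ~ scenario + year + pollutant,
                                 data = ds$loads, FUN = sum)
  mid <- characterize(loads_year, wf_year, factors = midpoint_factors)
  ep <- to_endpoints(mid, factors = endpoint_factors)
  norm <- normalize_endpoints(ep)
  groups <- norm$groups

  methods <- switch(weighting, both = c("entropy", "epi"), weighting)
  weights <- list()
  for (m in methods) {
    weights[[m]] <- if (m == "epi") epi_weights() else {
      src <- if (entropy_pooling == "pooled") groups
             else groups[groups$scenario == base_id, , drop = FALSE]
      if (nrow(src) < 2)
        stop_domain("entropy weighting needs at least 2 years of data")
      entropy_weights(cbind(health = src$r_health,
                            ecosystem = src$r_ecosystem))
    }
  }

  # multi-year scenario means of the normalized groups (after per-year
  # normalization), then weighting
  gmean <- stats::aggregate(cbind(r_health, r_ecosystem) ~ scenario,
                            data = groups, FUN = mean)
  scen_loads <- scenario_load_summary(ds)
  rows <- list()
  for (m in methods) {
    for (i in seq_len(nrow(gmean))) {
      scen <- gmean$scenario[i]
      cval <- aggregate_impact(gmean$r_health[i], gmean$r_ecosystem[i],
                               weights[[m]])
      nut <- nutrition_total(
        ds$land_use[ds$land_use$scenario == scen, , drop = FALSE],
        year_days = year_days)
      s <- s_index(nut$cal_day, baseline, population)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scen, method = m, c_value = cval, s = s,
        fef = fef(cval, s),
        r_health = gmean$r_health[i], r_ecosystem = gmean$r_ecosystem[i],
        nutrition_mcal_yr = nut$mcal_yr,
        tn_load_kg_yr = scen_loads$tn[scen_loads$scenario == scen],
        tp_load_kg_yr = scen_loads$tp[scen_loads$scenario == scen],
        wf_m3 = mean(wf_year$wf_m3[wf_year$scenario == scen]),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(wf = wf, midpoints = mid, endpoints = ep, groups = groups,
                 weights = weights, results = results,
                 comparison = compare_scenarios(results, base_id = base_id)),
            class = "fef_run")
}

# mean annual TN / TP load per scenario (species summed into aggregates)
scenario_load_summary <- function(ds) {
  scen <- unique(ds$land_use$scenario)
  tn <- tp <- numeric(length(scen))
  for (i in seq_along(scen)) {
    l <- ds$loads[ds$loads$scenario == scen[i], , drop = FALSE]
    if (!nrow(l)) next
    per_year <- vapply(split(l, l$year),
                       function(d) aggregate_tn_tp(d), numeric(2))
    tn[i] <- mean(per_year["TN", ])
    tp[i] <- mean(per_year["TP", ])
  }
  data.frame(scenario = scen, tn = tn, tp = tp, stringsAsFactors = FALSE)
}

#' @export
print.fef_run <- function(x, ...) {
  cat("<fef_run>\n")
  for (m in names(x$weights)) {
    w <- x$weights[[m]]
    cat(sprintf("  %s weights: health %.3g, ecosystem %.3g\n",
                m, w[["health"]], w[["ecosystem"]]))
  }
  print(x$comparison)
  invisible(x)
}

#' Desk-scale FEF accounting from the bundled study tables
#'
#' Recomputes the study's headline numbers from the bundled fixtures
#' alone: cumulative impact `C` per scenario from the reported multi-year
#' average normalized endpoint values, under both the reported entropy
#' weights (ecosystem 0.44, health 0.56) and the fixed EPI weights
#' (0.6 / 0.4); nutrition index `S` from the per-scenario land-use
#' nutrition totals; `FEF = C/S`; and percent reductions against the
#' base scenario.
#'
#' @param baseline,population,year_days nutrition-index constants
#'   (defaults: 2,000 cal/day/person, 7.75e9 persons, 365 days)
#' @return a `comparison_report` with one row per scenario x method
#' @export
fef_from_fixtures <- function(baseline = 2000, population = 7.75e9,
                              year_days = 365) {
  fx <- fef_fixtures()
  avg <- fx$endpoint_averages
  cn <- fx$constants
  wts <- list(
    entropy = impact_weights(cn$entropy_w_health, cn$entropy_w_ecosystem,
                             method = "entropy"),
    epi = epi_weights())
  scen <- unique(avg$scenario)
  rows <- list()
  for (m in names(wts)) {
    for (s in scen) {
      r_h <- avg$value[avg$scenario == s & avg$endpoint_group == "human_health"]
      r_e <- avg$value[avg$scenario == s & avg$endpoint_group == "ecosystem"]
      if (length(r_h) != 1 || length(r_e) != 1)
        stop_validation("scenario '%s' lacks a health or ecosystem average", s)
      cval <- aggregate_impact(r_h, r_e, wts[[m]])
      nut <- nutrition_total(fx$land_use_outputs[fx$land_use_outputs$scenario == s, , drop = FALSE],
                             year_days = year_days)
      sval <- s_index(nut$cal_day, baseline, population)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = s, method = m, c_value = cval, s = sval,
        fef = fef(cval, sval), r_health = r_h, r_ecosystem = r_e,
        nutrition_mcal_yr = nut$mcal_yr, stringsAsFactors = FALSE)
    }
  }
  compare_scenarios(do.call(rbind, rows), base_id = "base")
}
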