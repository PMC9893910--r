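# Small in-code fixtures shared across test files.

tiny_land_use <- function(scenario = "base") {
  data.frame(
    scenario = scenario,
    lu_name = c("wheat", "rf_pea"),
    irrigated = c(TRUE, FALSE),
    area_ha = c(100, 50),
    yield_ton_ha = c(2.8, 0.5),
    caloric_cal_kg = c(3640, 420),
    stringsAsFactors = FALSE)
}

tiny_loads <- function(scenario = "base", years = 2007:2008) {
  expand.grid(scenario = scenario, lu_name = c("wheat", "rf_pea"),
              year = years, pollutant = c("NO3", "PO4"),
              stringsAsFactors = FALSE) |>
    transform(load_kg_yr = 100)
}

tiny_et <- function(scenario = "base", years = 2007:2008) {
  g <- expand.grid(scenario = scenario, lu_name = c("wheat", "rf_pea"),
                   year = years, stringsAsFactors = FALSE)
  g$et_a_mm <- ifelse(g$lu_name == "wheat", 440, 380)
  g$et_b_mm <- ifelse(g$lu_name == "wheat", 720, 380)
  g
}

tiny_dataset <- function(scenario = "base", years = 2007:2008) {
  scenario_dataset(
    do.call(rbind, lapply(scenario, tiny_land_use)),
    do.call(rbind, lapply(scenario, tiny_loads, years = years)),
    do.call(rbind, lapply(scenario, tiny_et, years = years)))
}

# random inventory for property sweeps
random_loads <- function(n, seed) {
  set.seed(seed)
  data.frame(scenario = "s", year = 2007L,
             pollutant = sample(c("NO3", "NO2", "PO4", "P"), n, replace = TRUE),
             load_kg_yr = stats::runif(n, 0, 500),
             stringsAsFactors = FALSE)
}
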