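test_that("scenario tables read, validate and round-trip through CSV", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(c("base", "BMP1"))
  paths <- write_scenario_tables(ds, dir)
  back <- read_scenario_tables(paths["land_use"], paths["loads"], paths["et"])
  expect_s3_class(back, "scenario_dataset")
  for (tab in c("land_use", "loads", "et")) {
    a <- ds[[tab]][do.call(order, ds[[tab]]), ]
    b <- back[[tab]][do.call(order, back[[tab]]), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, ignore_attr = TRUE)
  }
})

test_that("an empty load table with a valid header yields a zero series", {
  dir <- withr::local_tempdir()
  lu_path <- file.path(dir, "lu.csv")
  write.csv(tiny_land_use(), lu_path, row.names = FALSE)
  loads_path <- file.path(dir, "loads.csv")
  writeLines("scenario,lu_name,year,pollutant,load_kg_yr", loads_path)
  ds <- read_scenario_tables(lu_path, loads_path)
  expect_identical(nrow(ds$loads), 0L)
})

test_that("validation rejects bad rows with informative errors", {
  loads <- tiny_loads()
  loads$load_kg_yr[3] <- -1
  expect_error(scenario_dataset(tiny_land_use(), loads),
               "row 3", class = "basinfef_validation_error")
  dup <- rbind(tiny_loads(), tiny_loads()[1, ])
  expect_error(scenario_dataset(tiny_land_use(), dup),
               "duplicate", class = "basinfef_validation_error")
  et <- tiny_et()
  et$et_b_mm[2] <- et$et_a_mm[2] - 10
  expect_error(scenario_dataset(tiny_land_use(), et = et),
               "et_b_mm below et_a_mm", class = "basinfef_validation_error")
  expect_error(scenario_dataset(tiny_land_use()[, -3]),
               "irrigated", class = "basinfef_config_error")
})

test_that("column maps rename and unit declarations convert on ingest", {
  dir <- withr::local_tempdir()
  lu_path <- file.path(dir, "lu.csv")
  write.csv(tiny_land_use(), lu_path, row.names = FALSE)
  raw <- tiny_loads()
  names(raw)[names(raw) == "load_kg_yr"] <- "NSURQ"
  raw$NSURQ <- raw$NSURQ / 1000  # ton/yr
  loads_path <- file.path(dir, "loads.csv")
  write.csv(raw, loads_path, row.names = FALSE)
  ds <- read_scenario_tables(lu_path, loads_path,
                             column_map = list(loads = c(load_kg_yr = "NSURQ")),
                             units = c(load = "ton/yr"))
  expect_equal(sort(unique(ds$loads$load_kg_yr)), 100)
  expect_error(
    read_scenario_tables(lu_path, loads_path,
                         column_map = list(loads = c(load_kg_yr = "nope"))),
    "nope", class = "basinfef_config_error")
  expect_error(
    read_scenario_tables(lu_path, loads_path,
                         column_map = list(loads = c(load_kg_yr = "NSURQ")),
                         units = c(load = "stone/fortnight")),
    "unsupported unit", class = "basinfef_config_error")
})

test_that("HRU-level duplicate load rows are summed to land-use level", {
  dir <- withr::local_tempdir()
  lu_path <- file.path(dir, "lu.csv")
  write.csv(tiny_land_use(), lu_path, row.names = FALSE)
  hru <- rbind(tiny_loads(years = 2007), tiny_loads(years = 2007))
  loads_path <- file.path(dir, "loads.csv")
  write.csv(hru, loads_path, row.names = FALSE)
  ds <- read_scenario_tables(lu_path, loads_path)
  expect_equal(unique(ds$loads$load_kg_yr), 200)
})

test_that("missing nutrition is computed from yield, area and caloric value", {
  lu <- tiny_land_use()
  ds <- scenario_dataset(lu)
  # wheat: 2.8 ton/ha x 100 ha x 1000 kg/ton x 3640 cal/kg / 1e6 = 1019.2 MCal
  expect_equal(ds$land_use$nutrition_mcal_yr,
               c(2.8 * 100 * 1000 * 3640 / 1e6, 0.5 * 50 * 1000 * 420 / 1e6))
  lu$yield_ton_ha[1] <- NA
  expect_error(scenario_dataset(lu), class = "basinfef_validation_error")
})

test_that("bundled fixtures match the transcribed study tables", {
  fx <- fef_fixtures()
  luo <- fx$land_use_outputs
  expect_identical(nrow(luo), 30L)
  expect_equal(luo$yield_ton_ha[luo$scenario == "base" & luo$lu_name == "alfalfa"],
               4.5)
  expect_equal(luo$wf_m3_ton[luo$scenario == "base" & luo$lu_name == "alfalfa"],
               2699.7)
  expect_equal(luo$yield_ton_ha[luo$scenario == "BMP2" & luo$lu_name == "tomato"],
               3.7)
  # per-scenario nutrition sums of the printed column
  sums <- tapply(luo$nutrition_mcal_yr, luo$scenario, sum)
  expect_equal(as.numeric(sums[c("base", "BMP1", "BMP2")]),
               c(7117, 6998, 6850))

  mf <- fx$midpoint_factors
  expect_equal(mf$factor[mf$pollutant == "NO3" &
                           mf$emission_compartment == "freshwater" &
                           mf$category == "marine_eutrophication"], 0.07)
  expect_equal(mf$factor[mf$pollutant == "PO4" &
                           mf$category == "freshwater_eutrophication"], 33)
  # marine-emission phosphorus pathway is absent, not zero
  expect_false(any(mf$emission_compartment == "marine" &
                     mf$pollutant %in% c("P", "PO4")))

  ef <- fx$endpoint_factors
  hw <- ef[ef$endpoint_row == "health_water", ]
  expect_equal(hw$factor, 2.22e-06)
  expect_equal(hw$normalization, 1.96e-04)
  expect_equal(ef$factor[ef$endpoint_row == "freshwater_eutro"], 6.71e-07)
  expect_equal(ef$normalization[ef$endpoint_row == "marine_eutro"], 6.12e-09)

  expect_equal(fx$standards$c_max_mg_l, c(1.5, 0.035))
  expect_equal(fx$standards$c_nat_mg_l, c(0.4, 0.01))
  avg <- fx$endpoint_averages
  expect_equal(avg$value[avg$scenario == "base" &
                           avg$endpoint_group == "ecosystem"], 1.41e-06)
  expect_equal(avg$value[avg$scenario == "BMP2" &
                           avg$endpoint_group == "human_health"], 2.22e-07)
})
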