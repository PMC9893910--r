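test_that("characterization multiplies loads by their midpoint factors", {
  mid <- characterize(data.frame(scenario = "s", year = 2007L,
                                 pollutant = "NO3", load_kg_yr = 100))
  expect_equal(mid$value[mid$category == "marine_eutrophication"], 7)
  expect_equal(mid$value[mid$category == "freshwater_eutrophication"], 0)

  mid <- characterize(data.frame(scenario = "s", year = 2007L,
                                 pollutant = "PO4", load_kg_yr = 10))
  expect_equal(mid$value[mid$category == "freshwater_eutrophication"], 330)

  zero <- characterize(data.frame(scenario = "s", year = 2007L,
                                  pollutant = c("NO3", "PO4"),
                                  load_kg_yr = c(0, 0)),
                       wf = data.frame(scenario = "s", year = 2007L,
                                       wf_m3 = 0))
  expect_true(all(zero$value == 0))
  expect_setequal(zero$category,
                  c("freshwater_eutrophication", "marine_eutrophication",
                    "water_consumption"))
})

test_that("strict mode rejects unmapped pollutants, lax mode drops them", {
  nh3 <- data.frame(scenario = "s", year = 2007L, pollutant = "NH3",
                    load_kg_yr = 5)
  expect_error(characterize(nh3), "NH3", class = "basinfef_config_error")
  expect_message(lax <- characterize(nh3, strict = FALSE), "NH3")
  expect_identical(nrow(lax), 0L)
})

test_that("water consumption passes through as a midpoint unchanged", {
  mid <- characterize(wf = data.frame(scenario = "s", year = 2007L,
                                      wf_m3 = 12345.6))
  expect_equal(mid$value[mid$category == "water_consumption"], 12345.6)
})

test_that("endpoint conversion applies the damage factors row-wise", {
  mid <- characterize(wf = data.frame(scenario = "s", year = 2007L,
                                      wf_m3 = 1e6))
  ep <- to_endpoints(mid)
  expect_equal(ep$damage[ep$endpoint_row == "health_water"], 2.22)
  expect_equal(ep$damage[ep$endpoint_row == "terrestrial_water"], 0.0135)
  expect_equal(ep$damage[ep$endpoint_row == "freshwater_water"], 6.04e-7)

  one_p <- data.frame(scenario = "s", year = 2007L,
                      category = "freshwater_eutrophication", value = 1)
  expect_equal(to_endpoints(one_p)$damage, 6.71e-07)

  bogus <- data.frame(scenario = "s", year = 2007L,
                      category = "noise_pollution", value = 1)
  expect_error(to_endpoints(bogus), class = "basinfef_config_error")
})

test_that("normalization divides by the reference and sums per group", {
  d <- data.frame(scenario = "s", year = 2007L,
                  endpoint_row = c("health_water", "terrestrial_water"),
                  endpoint_group = c("human_health", "ecosystem"),
                  damage = c(1.96e-04, 3.48e-06),
                  normalization = c(1.96e-04, 3.48e-06))
  norm <- normalize_endpoints(d)
  expect_equal(norm$rows$normalized, c(1, 1))
  expect_equal(norm$groups$r_health, 1)
  expect_equal(norm$groups$r_ecosystem, 1)

  d$damage <- 0
  z <- normalize_endpoints(d)
  expect_equal(z$groups$r_health + z$groups$r_ecosystem, 0)

  d$normalization[1] <- 0
  expect_error(normalize_endpoints(d), class = "basinfef_config_error")
})

test_that("the ecosystem score decomposes exactly into its endpoint rows", {
  loads <- random_loads(12, seed = 5)
  wf <- data.frame(scenario = "s", year = 2007L, wf_m3 = 5e5)
  norm <- normalize_endpoints(to_endpoints(characterize(loads, wf)))
  eco_rows <- norm$rows[norm$rows$endpoint_group == "ecosystem", ]
  expect_setequal(eco_rows$endpoint_row,
                  c("terrestrial_water", "freshwater_eutro",
                    "freshwater_water", "marine_eutro"))
  expect_identical(sum(norm$rows$endpoint_group == "human_health"), 1L)
  expect_equal(norm$groups$r_ecosystem, sum(eco_rows$normalized))
})

test_that("characterization and endpoint conversion are linear", {
  a <- random_loads(8, seed = 1)
  b <- random_loads(8, seed = 2)
  wf_a <- data.frame(scenario = "s", year = 2007L, wf_m3 = 3e5)
  wf_b <- data.frame(scenario = "s", year = 2007L, wf_m3 = 1e5)
  r <- function(loads, wf) {
    g <- normalize_endpoints(to_endpoints(characterize(loads, wf)))$groups
    c(g$r_health, g$r_ecosystem)
  }
  ab <- rbind(a, b)
  wf_ab <- data.frame(scenario = "s", year = 2007L,
                      wf_m3 = wf_a$wf_m3 + wf_b$wf_m3)
  expect_equal(r(ab, wf_ab), r(a, wf_a) + r(b, wf_b), tolerance = 1e-12)
  k <- 3.7
  ka <- a; ka$load_kg_yr <- k * ka$load_kg_yr
  wf_ka <- wf_a; wf_ka$wf_m3 <- k * wf_ka$wf_m3
  expect_equal(r(ka, wf_ka), k * r(a, wf_a), tolerance = 1e-12)
})

test_that("the vectorized pipeline matches a brute-force cell-by-cell oracle", {
  mf <- default_midpoint_factors()
  ef <- default_endpoint_factors()
  for (seed in 1:5) {
    loads <- random_loads(10, seed = seed)
    wf_val <- 1e5 + seed * 1e4
    # oracle: explicit loops over every factor-table cell
    q <- c(freshwater_eutrophication = 0, marine_eutrophication = 0,
           water_consumption = wf_val)
    for (i in seq_len(nrow(loads))) {
      for (j in seq_len(nrow(mf))) {
        if (mf$emission_compartment[j] == "freshwater" &&
            mf$pollutant[j] == loads$pollutant[i]) {
          q[mf$category[j]] <- q[mf$category[j]] +
            loads$load_kg_yr[i] * mf$factor[j]
        }
      }
    }
    r_h <- r_e <- 0
    for (j in seq_len(nrow(ef))) {
      d <- q[[ef$midpoint_category[j]]] * ef$factor[j]
      if (ef$endpoint_group[j] == "human_health")
        r_h <- r_h + d / ef$normalization[j]
      else r_e <- r_e + d / ef$normalization[j]
    }
    g <- normalize_endpoints(to_endpoints(characterize(
      loads, data.frame(scenario = "s", year = 2007L, wf_m3 = wf_val))))$groups
    expect_equal(g$r_health, r_h, tolerance = 1e-12)
    expect_equal(g$r_ecosystem, r_e, tolerance = 1e-12)
  }
})
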