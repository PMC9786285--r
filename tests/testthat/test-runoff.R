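test_that("C-CAP codes aggregate to the six LULC groups", {
  expect_identical(aggregate_ccap(14), "palustrine_wetland")
  expect_identical(aggregate_ccap(6), "cropland")
  expect_identical(aggregate_ccap(8), NA_character_)
  # full mapping, vectorised
  expect_identical(
    aggregate_ccap(c(2:6, 9:11, 13:18, 20)),
    c(rep("developed", 4), "cropland", rep("forest", 3),
      rep("palustrine_wetland", 3), rep("estuarine_wetland", 3), "barren"))
  # everything else drops out
  expect_true(all(is.na(aggregate_ccap(c(0, 1, 7, 12, 19, 21, 25, -3)))))
  expect_error(aggregate_ccap(2.5), "integer")
})

test_that("potential retention follows S = 1000/CN - 10", {
  expect_equal(potential_retention(100), 0)
  expect_equal(potential_retention(50), 10)
  expect_equal(potential_retention(75), 1000 / 75 - 10)
  expect_error(potential_retention(0), "curve_number")
  expect_error(potential_retention(101), "curve_number")
  expect_error(potential_retention(-5), "curve_number")
})

test_that("event runoff matches the TR-55 closed form", {
  expect_equal(event_runoff(2.0, 100), 2.0)
  expect_equal(event_runoff(0.3, 50), 0)       # P <= Ia = 2.0
  expect_equal(event_runoff(2.0, 75), (2 - 2 / 3)^2 / (2 - 2 / 3 + 10 / 3),
               tolerance = 1e-12)
  expect_error(event_runoff(-1, 75), "non-negative")
})

test_that("event runoff is monotone in P and CN, and bounded by P", {
  p_grid <- seq(0, 6, by = 0.25)
  cn_grid <- seq(35, 100, by = 5)
  for (cn in cn_grid) {
    q <- event_runoff(p_grid, cn)
    expect_true(all(diff(q) >= 0))
    expect_true(all(q >= 0 & q <= p_grid + 1e-12))
  }
  for (p in p_grid) {
    q <- vapply(cn_grid, function(cn) event_runoff(p, cn), 1)
    expect_true(all(diff(q) >= -1e-12))
  }
})

test_that("curve-number table validation enforces the contract", {
  cn <- default_cn_table()
  expect_s3_class(cn, "cn_table")
  expect_equal(nrow(cn), 24)
  wet <- cn$lulc_group %in% c("palustrine_wetland", "estuarine_wetland")
  expect_true(all(cn$cn[wet] == 100))
  expect_true(all(cn$cn >= 30 & cn$cn <= 100))

  expect_error(validate_cn_table(cn[-1, ]), "missing")
  bad <- cn; bad$cn[bad$lulc_group == "estuarine_wetland"][1] <- 80
  expect_error(validate_cn_table(bad), "wetland")
  bad <- cn; bad$cn[1] <- 20
  expect_error(validate_cn_table(bad), "30")
})

# independent per-day, per-stratum oracle used by several tests below
brute_force_runoff <- function(areas_m2, cns, precip_mm, n_years,
                               watershed_km2) {
  total_m3 <- 0
  for (r in seq_along(areas_m2)) {
    for (p in precip_mm) {
      p_in <- p / 25.4
      s <- 1000 / cns[r] - 10
      ia <- 0.2 * s
      q_in <- if (p_in <= ia) 0 else (p_in - ia)^2 / (p_in - ia + s)
      total_m3 <- total_m3 + q_in * 0.0254 * areas_m2[r]
    }
  }
  total_m3 / n_years / watershed_km2
}

year_dates <- function(year = 1981) {
  seq(as.Date(paste0(year, "-01-01")), as.Date(paste0(year, "-12-31")), 1)
}

test_that("annual runoff equals the brute-force day/stratum sum", {
  dates <- year_dates()
  mm <- numeric(length(dates))
  mm[c(10, 100, 200)] <- c(20, 60, 5)          # a 3-event toy year
  comp <- watershed_composition("T", ccap_code = 6, soil_group = "C",
                                area_m2 = 5000, watershed_area_km2 = 0.01)
  pr <- precip_series("T", dates, mm)
  out <- annual_runoff_by_class(comp, pr)
  cn_c <- cn_lookup(default_cn_table(), "cropland", "C")
  expect_equal(out[["cropland"]],
               brute_force_runoff(5000, cn_c, mm, 1, 0.01),
               tolerance = 1e-9)
  expect_true(all(out[setdiff(lulc_groups(), "cropland")] == 0))

  # several strata, two soils and two groups, multi-year
  dates2 <- c(year_dates(1981), year_dates(1982))
  set.seed(4)
  mm2 <- rbinom(length(dates2), 1, 0.3) * rgamma(length(dates2), 0.7, 0.1)
  comp2 <- watershed_composition(
    "T2", ccap_code = c(6, 6, 2), soil_group = c("C", "D", "A"),
    area_m2 = c(5000, 2000, 1500), watershed_area_km2 = 0.01)
  out2 <- annual_runoff_by_class(comp2, precip_series("T2", dates2, mm2))
  cn <- default_cn_table()
  expect_equal(out2[["cropland"]],
               brute_force_runoff(c(5000, 2000),
                                  cn_lookup(cn, "cropland", c("C", "D")),
                                  mm2, 2, 0.01),
               tolerance = 1e-9)
  expect_equal(out2[["developed"]],
               brute_force_runoff(1500, cn_lookup(cn, "developed", "A"),
                                  mm2, 2, 0.01),
               tolerance = 1e-9)
})

test_that("wetland override makes runoff equal precipitation volume", {
  dates <- year_dates()
  mm <- rep(3, length(dates))
  comp <- watershed_composition("W", ccap_code = c(17, 17), area_m2 = c(1e6, 5e5),
                                soil_group = c("A", "D"),
                                watershed_area_km2 = 2)
  out <- annual_runoff_by_class(comp, precip_series("W", dates, mm))
  # CN = 100 => Q = P: volume = depth * area
  expect_equal(out[["estuarine_wetland"]],
               sum(mm / 1000) * 1.5e6 / 2, tolerance = 1e-9)
})

test_that("runoff is additive over strata and scale-invariant", {
  dates <- year_dates()
  set.seed(9)
  mm <- rbinom(length(dates), 1, 0.3) * rgamma(length(dates), 0.7, 0.1)
  pr <- precip_series("X", dates, mm)
  one <- watershed_composition("X", 9, "B", 8000, 0.05)
  split2 <- watershed_composition("X", c(9, 9), c("B", "B"), c(4000, 4000),
                                  0.05)
  expect_equal(as.numeric(annual_runoff_by_class(one, pr)),
               as.numeric(annual_runoff_by_class(split2, pr)))
  scaled <- watershed_composition("X", 9, "B", 8000 * 7, 0.05 * 7)
  expect_equal(as.numeric(annual_runoff_by_class(one, pr)),
               as.numeric(annual_runoff_by_class(scaled, pr)),
               tolerance = 1e-12)
})

test_that("input readers round-trip the CSV dialects", {
  d <- withr::local_tempdir()
  comp_csv <- file.path(d, "comp.csv")
  ws_csv <- file.path(d, "ws.csv")
  pr_csv <- file.path(d, "pr.csv")
  write.csv(data.frame(estuary_id = c("A", "A", "B"),
                       ccap_code = c(6, 9, 14), soil_group = c("C", "B", "D"),
                       area_m2 = c(100, 200, 300)),
            comp_csv, row.names = FALSE)
  write.csv(data.frame(estuary_id = c("A", "B"),
                       watershed_area_km2 = c(1, 2)),
            ws_csv, row.names = FALSE)
  dates <- year_dates()
  write.csv(data.frame(estuary_id = "A", date = as.character(dates),
                       precip_mm = 1), pr_csv, row.names = FALSE)
  comps <- read_composition(comp_csv, ws_csv)
  expect_length(comps, 2)
  expect_equal(comps[["A"]]$watershed_area_km2, 1)
  expect_equal(nrow(comps[["A"]]$rows), 2)
  prs <- read_precip(pr_csv)
  expect_length(prs, 1)
  expect_equal(length(prs[["A"]]$precip_mm), 365)
  # missing precip for estuary B is an error at covariate time
  expect_error(runoff_covariates(comps, prs), "precipitation")
})

test_that("incomplete years are rejected or excluded from the mean", {
  short <- precip_series("S", year_dates()[1:200], rep(1, 200))
  comp <- watershed_composition("S", 6, "C", 1000, 0.01)
  expect_error(annual_runoff_by_class(comp, short), "complete year")
  # one complete year + a partial year: partial days are excluded
  dates <- c(year_dates(1981), year_dates(1982)[1:50])
  full <- annual_runoff_by_class(
    comp, precip_series("S", year_dates(1981), rep(10, 365)))
  padded <- annual_runoff_by_class(
    comp, precip_series("S", dates, rep(10, length(dates))))
  expect_equal(as.numeric(full), as.numeric(padded))
})
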