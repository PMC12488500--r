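test_that("direct overshoot reproduces published worked values", {
  # CO2 2021-22: boundary 350 ppm, Holocene baseline 280 ppm
  expect_equal(overshoot_direct(416, 350, 280), 0.9428571, tolerance = 1e-6)
  expect_equal(round_half_away(100 * overshoot_direct(416, 350, 280)), 94)
  # nitrogen 2000-01
  expect_equal(round_half_away(100 * overshoot_direct(134, 62, 0)), 116)
  # aerosol interhemispheric AOD, within boundary
  expect_equal(round_half_away(100 * overshoot_direct(0.08, 0.1, 0.03)), -29)
})

test_that("boundary and baseline identities hold for both framings", {
  expect_equal(overshoot_direct(350, 350, 280), 0)
  expect_equal(overshoot_direct(280, 350, 280), -1)
  expect_equal(overshoot_inverted(48, 48, 64), 0)
  expect_equal(overshoot_inverted(64, 48, 64), -1)
  expect_error(overshoot_direct(1, 2, 2), class = "doughnut_degenerate_error")
  expect_error(overshoot_inverted(1, 2, 0), class = "doughnut_degenerate_error")
})

test_that("inverted framing equals the transformed direct formula", {
  set.seed(11)
  for (i in 1:200) {
    x_base <- runif(1, 0.5, 400)
    x_star <- runif(1, 0.01, 0.99) * x_base # below baseline, positive
    x <- runif(1, 0.01, 1.5) * x_base
    expect_equal(
      overshoot_inverted(x, x_star, x_base),
      overshoot_direct(x_base - x, x_base - x_star, 0),
      tolerance = 1e-12
    )
  }
  # forest worked value from printed (rounded) table inputs
  expect_equal(overshoot_inverted(38, 48, 64), 0.625, tolerance = 1e-12)
})

test_that("normalized overshoot is monotone in degradation", {
  x <- seq(280, 500, by = 5)
  o <- overshoot_direct(x, 350, 280)
  expect_true(all(diff(o) > 0))
  xi <- seq(64, 30, by = -1)
  oi <- overshoot_inverted(xi, 48, 64)
  expect_true(all(diff(oi) > 0)) # declining forest => rising overshoot
})

test_that("period averaging honours windows, sparsity and the ozone rule", {
  expect_equal(period_average(c(2021, 2022), c(10, 12), 2021:2022)$value, 11)
  pa <- period_average(2022, 7, 2021:2022)
  expect_equal(pa$value, 7)
  expect_equal(pa$n_years, 1L)
  expect_equal(pa$window_years, 2L)
  expect_true(is.na(period_average(2000, 1, 2021:2022)$value))

  # 5-year ozone window picks up all five observations
  reg <- default_registry()
  oz <- tibble::tibble(indicator_id = "ozone", year = 2000:2022,
                       value = 283 + sin(2000:2022))
  norm <- normalize_table(oz, reg)
  lv <- period_levels(norm, reg)
  expect_equal(lv$n_years[lv$period == "end"], 5L)
  expect_equal(
    lv$value[lv$period == "end"],
    mean(norm$value[norm$year >= 2018])
  )
})

test_that("normalization is a social pass-through and is idempotent there", {
  reg <- default_registry()
  s <- tibble::tibble(indicator_id = "poverty", year = 2000:2004,
                      value = c(35, 34, 33, 31, 30))
  n1 <- normalize_table(s, reg)
  expect_equal(n1$value, s$value)
  n2 <- normalize_table(
    tibble::tibble(indicator_id = n1$indicator_id, year = n1$year, value = n1$value),
    reg
  )
  expect_equal(n2$value, n1$value)
  expect_error(
    normalize_table(tibble::tibble(indicator_id = "poverty", year = 2000, value = 120), reg),
    class = "doughnut_validation_error"
  )
  expect_error(
    normalize_table(tibble::tibble(indicator_id = "nope", year = 2000, value = 1), reg),
    class = "doughnut_validation_error"
  )
})

test_that("published table of levels recomputes to the printed overshoot cells", {
  status <- published_status()
  eco <- status[status$domain == "ecological", ]
  printed <- tibble::tribble(
    ~indicator_id, ~period, ~printed,
    "co2", "start", 28, "co2", "end", 94,
    "radiative_forcing", "start", 78, "radiative_forcing", "end", 183,
    "ocean_acidification", "start", -34, "ocean_acidification", "end", -6,
    "chemical_pollution", "start", 1455, "chemical_pollution", "end", 3174,
    "phosphorus", "start", 123, "phosphorus", "end", 273,
    "nitrogen", "start", 116, "nitrogen", "end", 212,
    "aerosols", "start", -29, "aerosols", "end", -29,
    "blue_water", "start", 78, "blue_water", "end", 78,
    "green_water", "start", 43, "green_water", "end", 74,
    "forest", "start", 55, "forest", "end", 61,
    "extinctions", "start", 900, "extinctions", "end", 900,
    "hanpp", "start", 162, "hanpp", "end", 204,
    "ozone", "start", -50, "ozone", "end", -53
  )
  cmp <- dplyr::inner_join(eco, printed, by = c("indicator_id", "period"))
  expect_equal(nrow(cmp), 26)
  cmp$recomputed <- round_half_away(cmp$value)
  # cells whose printed native inputs are rounded too coarsely to recompute
  # within +/-2 integer points (unrounded-source artifacts)
  coarse <- c("radiative_forcing.end", "phosphorus.start", "hanpp.start")
  key <- paste(cmp$indicator_id, cmp$period, sep = ".")
  expect_true(all(abs(cmp$recomputed - cmp$printed)[!key %in% coarse] <= 2))
  expect_true(all(abs(cmp$recomputed - cmp$printed)[key %in% coarse] <= 6))
})
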