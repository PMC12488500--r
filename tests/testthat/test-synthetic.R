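test_that("generation is fully reproducible under a fixed seed", {
  cfg <- world_config(n_countries = 20, seed = 5)
  w1 <- gen_world(cfg)
  w2 <- gen_world(cfg)
  expect_equal(w1$panel, w2$panel)
  expect_equal(w1$global_series, w2$global_series)
  expect_equal(w1$footprints, w2$footprints)
  w3 <- gen_world(world_config(n_countries = 20, seed = 6))
  expect_false(isTRUE(all.equal(w1$panel$value, w3$panel$value)))
})

test_that("noise-free configurations are deterministic lines", {
  cfg <- world_config(
    n_countries = 5, seed = 1,
    social = list(intercept = 60, slope = -0.5, rho = 0, sigma = 0, gni_gradient = 0),
    eco = list(start_overshoot = 0.5, drift = 0.02, rho = 0, sigma = 0)
  )
  panel <- gen_country_panel(cfg)
  pov <- panel[panel$indicator_id == "poverty" & panel$country_code == "C001", ]
  expect_equal(pov$value, 60 - 0.5 * (pov$year - 2000))

  gs <- gen_global_series(cfg)
  co2 <- gs[gs$indicator_id == "co2", ]
  o <- overshoot_direct(co2$value, 350, 280)
  expect_equal(o, 0.5 + 0.02 * (co2$year - 2000), tolerance = 1e-12)
  # inverted indicator declines in native units while overshoot rises
  forest <- gs[gs$indicator_id == "forest", ]
  expect_true(all(diff(forest$value) < 0))
  expect_equal(overshoot_inverted(forest$value, 48, 64),
               0.5 + 0.02 * (forest$year - 2000), tolerance = 1e-12)
})

test_that("generated tables satisfy the interchange invariants", {
  w <- small_world(seed = 23)
  reg <- default_registry()
  expect_silent(as_country_panel(w$panel))
  expect_silent(as_global_series(w$global_series))
  expect_silent(as_footprint_table(w$footprints))
  # shares bounded, populations constant per country
  ws_ids <- reg$id[reg$aggregation_mode %in% "weighted_share"]
  shares <- w$panel$value[w$panel$indicator_id %in% ws_ids]
  expect_true(all(shares >= 0 & shares <= 100))
  pops <- tapply(w$panel$population, w$panel$country_code,
                 function(x) length(unique(x)))
  expect_true(all(pops == 1))
  # late-start and single-year indicators respect their registry coverage
  expect_equal(min(w$panel$year[w$panel$indicator_id == "food_insecurity"]), 2015)
  expect_equal(unique(w$panel$year[w$panel$indicator_id == "public_transport"]), 2022)
  expect_true(all(w$global_series$value[w$global_series$indicator_id == "forest"] > 0))
})

test_that("footprints track affluence as configured", {
  cfg0 <- world_config(n_countries = 12, seed = 3,
                       footprint = list(elasticity = 0, sigma = 0, level = 0.8))
  gni <- gen_gni(cfg0)
  fp0 <- gen_footprint_table(cfg0, gni)
  expect_equal(length(unique(fp0$ef_per_capita[fp0$footprint_id == "co2"])), 1)

  cfg1 <- world_config(n_countries = 12, seed = 3,
                       footprint = list(elasticity = 1, sigma = 0, level = 0.8))
  fp1 <- gen_footprint_table(cfg1, gni)
  co2 <- fp1[fp1$footprint_id == "co2", ]
  expect_equal(order(co2$ef_per_capita), order(gni$gni_per_capita))
})

test_that("the richest cluster out-emits the poorest across seeds", {
  hits <- vapply(1:60, function(s) {
    cfg <- world_config(n_countries = 60, seed = 1000 + s)
    gni <- gen_gni(cfg)
    fp <- gen_footprint_table(cfg, gni)
    asg <- assign_clusters(gni)
    cf <- cluster_footprint(fp[fp$footprint_id == "co2", ], asg)
    cf$ef_per_capita[cf$cluster == "richest20"] >
      cf$ef_per_capita[cf$cluster == "poorest40"]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("the configured panel trend is recovered from the aggregate", {
  cfg <- world_config(n_countries = 150, seed = 37)
  reg <- default_registry()
  panel <- gen_country_panel(cfg, reg)
  glob <- aggregate_panel_global(panel[panel$indicator_id == "poverty", ], reg)
  est <- fit_linear_trend(glob[c("year", "value")], seed = 2)
  expect_true(est$ci_lower <= -0.5 && -0.5 <= est$ci_upper)
  expect_lt(abs(est$beta1 - (-0.5)), 0.3)
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_countries = 2), class = "doughnut_validation_error")
  expect_error(world_config(social = list(intercept = 50, slope = 0, rho = 1.2,
                                          sigma = 1, gni_gradient = 0)),
               class = "doughnut_validation_error")
  expect_error(world_config(eco = list(start_overshoot = 0, drift = 0, rho = 0,
                                       sigma = -1)),
               class = "doughnut_validation_error")
})
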