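test_that("income clusters reproduce published counts and exact fractions", {
  gni193 <- tibble::tibble(country_code = sprintf("C%03d", 1:193),
                           gni_per_capita = exp(seq(6, 11, length.out = 193)))
  a <- assign_clusters(gni193)
  expect_equal(unname(a$counts), c(78, 77, 38))
  expect_true(all(diff(unname(a$cut_points)) > 0))

  a5 <- assign_clusters(tibble::tibble(country_code = sprintf("C%d", 1:5),
                                       gni_per_capita = 1:5))
  expect_equal(unname(a5$counts), c(2, 2, 1))

  expect_error(assign_clusters(gni193[1:2, ]), class = "doughnut_validation_error")
  expect_error(assign_clusters(dplyr::mutate(gni193, gni_per_capita = -1)),
               class = "doughnut_validation_error")
})

test_that("assignment is invariant to input order and GNI rescaling", {
  set.seed(51)
  gni <- tibble::tibble(country_code = sprintf("C%03d", 1:40),
                        gni_per_capita = rlnorm(40, 9, 1))
  a <- assign_clusters(gni)
  b <- assign_clusters(gni[sample(40), ])
  expect_equal(a$assignment, b$assignment)
  c_ <- assign_clusters(dplyr::mutate(gni, gni_per_capita = gni_per_capita * 17.3))
  expect_equal(a$assignment$cluster, c_$assignment$cluster)
  expect_equal(a$assignment$country_code, c_$assignment$country_code)
  # no poorer country sits in a richer cluster
  ord <- order(a$assignment$gni_per_capita)
  ranks <- match(a$assignment$cluster[ord], c("poorest40", "middle40", "richest20"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("cluster social shares aggregate by population and threshold", {
  asg <- toy_assignment(c("AAA", "BBB", "CCC"), c(1000, 2000, 50000))
  # weighted share: two equal-population countries in one cluster
  panel <- as_country_panel(tibble::tibble(
    country_code = c("AAA", "BBB"), year = 2017, indicator_id = "poverty",
    value = c(10, 30), population = c(5e6, 5e6)
  ))
  reg <- default_registry()
  s <- cluster_social_share(panel, reg[reg$id == "poverty", ], asg, 2017)
  expect_equal(s$share_deprived[s$cluster == "poorest40"], 20)

  # threshold indicator: one of two equal-population countries breaches
  panel2 <- as_country_panel(tibble::tibble(
    country_code = c("AAA", "BBB"), year = 2017, indicator_id = "child_mortality",
    value = c(40, 10), population = c(5e6, 5e6)
  ))
  s2 <- cluster_social_share(panel2, reg[reg$id == "child_mortality", ], asg, 2017)
  expect_equal(s2$share_deprived[s2$cluster == "poorest40"], 50)

  # no data in a cluster => cluster omitted
  expect_false("richest20" %in% s$cluster)
})

test_that("deprived population is conserved between global and cluster scales", {
  w <- small_world(seed = 13)
  reg <- default_registry()
  asg <- assign_clusters(w$gni)
  yr <- 2017
  for (id in c("poverty", "child_mortality")) {
    spec <- reg[reg$id == id, ]
    s <- share_of_global_shortfall(cluster_social_share(w$panel, spec, asg, yr))
    glob <- aggregate_panel_global(w$panel[w$panel$indicator_id == id, ], reg)
    gshare <- glob$value[glob$year == yr]
    gpop <- sum(w$gni$population)
    expect_equal(sum(s$deprived_population), gshare / 100 * gpop, tolerance = 1e-9)
    expect_equal(sum(s$share_of_global_shortfall), 1, tolerance = 1e-9)
  }
})

test_that("shortfall shares follow the attribution formula", {
  shares <- tibble::tibble(
    cluster = c("poorest40", "middle40", "richest20"),
    share_deprived = c(50, 20, 10),
    population = c(1e6, 2e6, 7e6),
    n_countries = 1:3
  )
  s <- share_of_global_shortfall(shares)
  expect_equal(s$share_of_global_shortfall, c(0.5, 0.4, 0.7) / 1.6)
  expect_equal(s$share_of_global_shortfall[1], 0.3125)

  one <- share_of_global_shortfall(dplyr::mutate(shares, share_deprived = c(40, 0, 0)))
  expect_equal(one$share_of_global_shortfall, c(1, 0, 0))

  none <- share_of_global_shortfall(dplyr::mutate(shares, share_deprived = 0))
  expect_equal(none$share_of_global_shortfall, rep(0, 3))
  expect_true(attr(none, "no_shortfall"))
})

test_that("footprint aggregation conserves the global per-capita mean", {
  w <- small_world(seed = 17)
  asg <- assign_clusters(w$gni)
  cf <- cluster_footprint(w$footprints, asg)
  for (id in unique(cf$footprint_id)) {
    d <- cf[cf$footprint_id == id, ]
    pooled <- sum(d$ef_per_capita * d$population) / sum(d$population)
    raw <- w$footprints[w$footprints$footprint_id == id, ]
    expect_equal(pooled, sum(raw$ef_per_capita * raw$population) / sum(raw$population),
                 tolerance = 1e-9)
  }
  # single-country cluster equals that country (richest is 1 of 5)
  asg5 <- toy_assignment(c("AAA", "BBB", "CCC", "DDD", "EEE"), c(1, 2, 3, 4, 5))
  fp <- as_footprint_table(tibble::tibble(
    country_code = c("AAA", "BBB", "CCC", "DDD", "EEE"), footprint_id = "co2",
    ef_per_capita = c(0.5, 1.0, 1.5, 2.0, 4.0), population = 1e6,
    per_capita_boundary = 1.6
  ))
  cf5 <- cluster_footprint(fp, asg5)
  expect_equal(cf5$ef_per_capita[cf5$cluster == "richest20"], 4.0)
})

test_that("fair-share overshoot follows the zero-baseline normalization", {
  expect_equal(cluster_overshoot(1.6, 1.6), 0)
  expect_equal(cluster_overshoot(3.2, 1.6), 100)
  expect_equal(cluster_overshoot(0, 1.6), -100)
})

test_that("excess shares obey the clamp and signed policies", {
  b <- 2
  cfp <- tibble::tibble(
    footprint_id = "co2",
    cluster = c("poorest40", "middle40", "richest20"),
    ef_per_capita = c(0.5 * b, 1.5 * b, 2 * b),
    per_capita_boundary = b,
    population = c(1e6, 1e6, 1e6)
  )
  cl <- share_of_global_excess(cfp, "clamp")
  expect_equal(cl$share_of_global_excess[match(c("richest20", "middle40", "poorest40"), cl$cluster)],
               c(2 / 3, 1 / 3, 0))
  expect_equal(sum(cl$share_of_global_excess), 1, tolerance = 1e-12)

  sg <- share_of_global_excess(cfp, "signed")
  expect_equal(sum(sg$share_of_global_excess), 1, tolerance = 1e-12)
  expect_true(sg$share_of_global_excess[sg$cluster == "poorest40"] < 0)

  # all clusters exactly at boundary: within-boundary flag, no shares
  at <- share_of_global_excess(dplyr::mutate(cfp, ef_per_capita = b), "clamp")
  expect_true(all(at$within_boundary))
  expect_true(all(is.na(at$share_of_global_excess)))

  single <- share_of_global_excess(cfp[3, ], "clamp")
  expect_equal(single$share_of_global_excess, 1)
})

test_that("the affluence gradient emerges in the cluster table", {
  reg <- default_registry()
  w <- gen_world(world_config(n_countries = 120, seed = 29))
  asg <- assign_clusters(w$gni)
  ct <- cluster_table(w$panel, w$footprints, reg, asg, year = 2017)

  soc <- ct[ct$domain == "social", ]
  med <- tapply(soc$share_deprived, soc$cluster, stats::median)
  expect_gt(med["poorest40"], med["middle40"])
  expect_gt(med["middle40"], med["richest20"])

  eco <- ct[ct$domain == "ecological", ]
  medo <- tapply(eco$cluster_overshoot, eco$cluster, stats::median)
  expect_gt(medo["richest20"], medo["middle40"])
  expect_gt(medo["middle40"], medo["poorest40"])

  # poorest cluster holds the largest shortfall for nearly all indicators
  wide <- tidyr::pivot_wider(soc[c("indicator_id", "cluster", "share_deprived")],
                             names_from = "cluster", values_from = "share_deprived")
  frac <- mean(wide$poorest40 > wide$richest20, na.rm = TRUE)
  expect_gte(frac, 19 / 21)
})
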