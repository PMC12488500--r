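# shared in-code fixtures

tiny_registry <- function() {
  default_registry()[default_registry()$id %in%
                       c("poverty", "child_mortality", "co2", "forest"), ]
}

# small world reused across tests needing a realistic synthetic input
small_world <- function(seed = 7, n = 30) {
  gen_world(world_config(n_countries = n, seed = seed))
}

toy_panel <- function() {
  as_country_panel(tibble::tibble(
    country_code = rep(c("AAA", "BBB"), each = 2),
    year = rep(c(2016, 2017), 2),
    indicator_id = "poverty",
    value = c(10, 10, 30, 30),
    population = c(5e6, 5e6, 5e6, 5e6)
  ))
}

# three-cluster assignment over named countries with chosen GNI
toy_assignment <- function(codes, gni) {
  assign_clusters(tibble::tibble(country_code = codes, gni_per_capita = gni))
}
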