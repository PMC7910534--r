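# Shared fixtures and independent oracles, all built in code.

# three collinear regions: b (pop 20) lies between a and c
toy_locs3 <- function() {
  location_set(c("a", "b", "c"), cbind(c(0, 5, 10), 0), c(10, 20, 30))
}

rand_locs <- function(n, seed, side = 100, pop_min = 50, pop_max = 5000) {
  set.seed(seed)
  location_set(sprintf("g%03d", seq_len(n)),
               cbind(stats::runif(n, 0, side), stats::runif(n, 0, side)),
               exp(stats::runif(n, log(pop_min), log(pop_max))))
}

# brute-force intervening population: direct scan of all regions inside the
# open disc centred at the origin, independent of the sort-based production
# code
oracle_intervening <- function(locs, d) {
  n <- length(locs$ids)
  pop <- locs$populations
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      inside <- setdiff(which(d[i, ] < d[i, j]), c(i, j))
      s[i, j] <- sum(pop[inside])
    }
  }
  s
}

# cell-by-cell prediction through the scalar flux functions
oracle_predict <- function(model_id, params, locs, geom) {
  n <- geom$n
  pop <- locs$populations
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      m <- pop[i]
      nn <- pop[j]
      r <- geom$distances[i, j]
      s <- geom$intervening[i, j]
      out[i, j] <- switch(
        model_id,
        gravity = gravity_flux(params, m, nn, r),
        gravity_distance = gravity_distance_flux(params, m, nn, r),
        radiation = radiation_flux(params, m, nn, s),
        radiation_selection =
          radiation_selection_flux(params, m, nn, m + nn + s),
        intervening_opportunities =
          intervening_opportunities_flux(params, m, nn, s)
      )
    }
  }
  out
}

example_params <- function(model_id) {
  switch(model_id,
         gravity = gravity_params(0.002, 0.8, 0.6, 1.5),
         gravity_distance = gravity_distance_params(
           40, gravity_params(0.004, 0.7, 0.7, 1.2),
           gravity_params(0.001, 0.9, 0.5, 1.8)),
         radiation = radiation_params(0.4),
         radiation_selection = radiation_selection_params(30, 0.5),
         intervening_opportunities =
           intervening_opportunities_params(60, log(2) / 4000, 0.95))
}

# the half-gravity half-intervening-opportunities study scenario
mixture_scenario <- function(n_regions, seed, weight = 0.5) {
  synthetic_scenario(
    n_regions, model = "gravity",
    mixture = list(
      model = "intervening_opportunities",
      params = intervening_opportunities_params(1, log(2) / 15000, 1),
      weight = weight),
    mean_flow = 25, noise = "poisson", seed = seed)
}

scenario_data <- function(scn) {
  locs <- generate_locations(scn)
  geom <- pairwise_geometry(locs)
  flows <- generate_flows(scn, locs, geom)
  list(locs = locs, geom = geom, flows = flows)
}
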