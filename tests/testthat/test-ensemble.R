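# Five distinguishable prediction matrices on a small-population location set
# (small populations keep the radiation-with-selection surface non-constant).
ens_fixture <- function(n = 15, seed = 4) {
  locs <- rand_locs(n, seed = seed, pop_min = 2, pop_max = 80)
  geom <- pairwise_geometry(locs)
  params <- list(
    gravity = gravity_params(0.05, 0.8, 0.6, 1.2),
    gravity_distance = gravity_distance_params(
      40, gravity_params(0.1, 0.6, 0.8, 0.9),
      gravity_params(0.02, 1.0, 0.4, 1.6)),
    radiation = radiation_params(20),
    radiation_selection = radiation_selection_params(5, 0.6),
    intervening_opportunities =
      intervening_opportunities_params(8, log(2) / 60, 0.9)
  )
  preds <- lapply(flowstack_models(), function(id) {
    predict_matrix(id, params[[id]], locs, geom)
  })
  names(preds) <- flowstack_models()
  list(locs = locs, geom = geom, preds = preds)
}

test_that("the design matrix vectorises off-diagonal cells with the log clamp", {
  fx <- ens_fixture(3)
  d <- build_design(fx$preds)
  expect_equal(nrow(d$X), 6)   # z^2 - z
  expect_equal(colnames(d$X), flowstack_models())
  expect_true(all(d$index[, 1] != d$index[, 2]))

  zeroed <- fx$preds
  zeroed$gravity[1, 2] <- 0
  dz <- build_design(zeroed)
  expect_equal(unname(dz$X[dz$cells == 4, "gravity"]), log(1e-10))

  # identical predictions give identical columns; collinearity is preserved
  dup <- fx$preds
  dup$gravity_distance <- dup$gravity
  dd <- build_design(dup)
  expect_identical(dd$X[, "gravity"], dd$X[, "gravity_distance"])

  bad <- fx$preds
  bad$radiation <- bad$radiation[1:2, 1:2]
  expect_error(build_design(bad), "identical shape")
})

test_that("a base model that generated the data gets weight one", {
  fx <- ens_fixture()
  obs <- fx$preds$gravity   # observed flows exactly equal one base model
  ens <- fit_ensemble(obs, fx$preds)
  expect_true(ens$converged)
  expect_lt(ens$training_deviance, 1e-6)
  expect_equal(unname(ens$coefficients[["gravity"]]), 1, tolerance = 1e-4)
  expect_equal(unname(ens$coefficients[["intercept"]]), 0, tolerance = 1e-3)
  expect_true(all(abs(ens$coefficients[c("gravity_distance", "radiation",
                                         "intervening_opportunities")])
                  < 1e-3))
})

test_that("a constant design collapses to the intercept-only solution", {
  n <- 12
  cells <- which(!diag(TRUE, n))
  cpred <- matrix(0, n, n)
  cpred[cells] <- 7
  preds <- rep(list(cpred), 5)
  names(preds) <- flowstack_models()
  obs <- matrix(0, n, n)
  set.seed(8)
  obs[cells] <- rpois(length(cells), 7)
  ens <- fit_ensemble(obs, preds)
  # all columns equal log 7: the fitted linear predictor must equal
  # log(mean(y)) however the pseudo-inverse spreads it across coefficients
  eta <- ens$coefficients[["intercept"]] +
    sum(ens$coefficients[flowstack_models()]) * log(7)
  expect_equal(eta, log(mean(obs[cells])), tolerance = 1e-8)
})

test_that("generating stacking weights are recovered from Poisson counts", {
  fx <- ens_fixture(30, seed = 12)
  d <- build_design(fx$preds)
  eta <- 0.3 + 0.6 * d$X[, "gravity"] +
    0.4 * d$X[, "intervening_opportunities"]
  eta <- eta - mean(eta) + log(150)   # large counts, mean 150
  n <- fx$geom$n
  obs <- matrix(0, n, n)
  set.seed(99)
  obs[d$cells] <- rpois(length(eta), exp(eta))
  ens <- fit_ensemble(obs, fx$preds)
  expect_true(ens$converged)
  expect_equal(unname(ens$coefficients[["gravity"]]), 0.6, tolerance = 0.05)
  expect_equal(unname(ens$coefficients[["intervening_opportunities"]]), 0.4,
               tolerance = 0.05)
  expect_true(all(abs(ens$coefficients[c("gravity_distance", "radiation",
                                         "radiation_selection")]) < 0.05))
})

test_that("our IRLS agrees with stats::glm on a well-conditioned design", {
  fx <- ens_fixture(20, seed = 21)
  d <- build_design(fx$preds)
  set.seed(31)
  n <- fx$geom$n
  obs <- matrix(0, n, n)
  obs[d$cells] <- rpois(nrow(d$X), exp(1 + 0.5 * d$X[, "gravity"] +
                                         0.3 * d$X[, "radiation"]))
  ens <- fit_ensemble(obs, fx$preds)
  ref <- stats::glm.fit(cbind(1, d$X), obs[d$cells],
                        family = stats::poisson())
  expect_equal(unname(ens$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_equal(ens$training_deviance, ref$deviance, tolerance = 1e-8)
})

test_that("ensemble training deviance is bounded by every pure weighting", {
  for (seed in c(3, 17)) {
    d <- scenario_data(mixture_scenario(20, seed = seed))
    fits <- lapply(flowstack_models(), function(id) {
      fit_model(id, d$flows, d$locs, d$geom)
    })
    preds <- lapply(fits, function(f) {
      predict_matrix(f$model_id, f$params, d$locs, d$geom)
    })
    names(preds) <- flowstack_models()
    ens <- fit_ensemble(d$flows, preds)
    cells <- which(!diag(TRUE, d$geom$n))
    y <- d$flows[cells]
    base_dev <- vapply(preds, function(p) poisson_deviance(y, p[cells]),
                       numeric(1))
    mean_dev <- poisson_deviance(y, Reduce(`+`, preds)[cells] / 5)
    expect_lte(ens$training_deviance, min(base_dev) * (1 + 1e-8) + 1e-8)
    expect_lte(ens$training_deviance, mean_dev * (1 + 1e-8) + 1e-8)
  }
})

test_that("predict_ensemble is the log-linear combination of base predictions", {
  fx <- ens_fixture()
  ident <- structure(
    list(coefficients = c(intercept = 0, gravity = 1, gravity_distance = 0,
                          radiation = 0, radiation_selection = 0,
                          intervening_opportunities = 0),
         converged = TRUE, training_deviance = 0, n_iterations = 0L),
    class = "stacked_ensemble")
  mu <- predict_ensemble(ident, fx$preds)
  expect_equal(unname(mu), unname(fx$preds$gravity), tolerance = 1e-12)

  flat <- ident
  flat$coefficients[] <- 0
  mu0 <- predict_ensemble(flat, fx$preds)
  cells <- which(!diag(TRUE, fx$geom$n))
  expect_true(all(mu0[cells] == 1))
  expect_true(all(diag(mu0) == 0))

  half <- ident
  half$coefficients[["gravity"]] <- 0.5
  doubled <- fx$preds
  doubled$gravity <- 2 * doubled$gravity
  expect_equal(predict_ensemble(half, doubled)[cells],
               sqrt(2) * predict_ensemble(half, fx$preds)[cells],
               tolerance = 1e-12)
})

test_that("fitting then predicting reproduces the training mean vector", {
  fx <- ens_fixture(10, seed = 2)
  set.seed(5)
  n <- fx$geom$n
  cells <- which(!diag(TRUE, n))
  obs <- matrix(0, n, n)
  obs[cells] <- rpois(length(cells), pmax(fx$preds$gravity[cells], 0.5))
  ens <- fit_ensemble(obs, fx$preds)
  mu <- predict_ensemble(ens, fx$preds)
  expect_equal(poisson_deviance(obs[cells], mu[cells]),
               ens$training_deviance, tolerance = 1e-10)
})

test_that("extreme linear predictors are capped with a warning", {
  fx <- ens_fixture(6, seed = 13)
  big <- structure(
    list(coefficients = c(intercept = 1000, gravity = 5, gravity_distance = 0,
                          radiation = 0, radiation_selection = 0,
                          intervening_opportunities = 0),
         converged = TRUE, training_deviance = 0, n_iterations = 0L),
    class = "stacked_ensemble")
  expect_warning(mu <- predict_ensemble(big, fx$preds), "capped")
  expect_true(all(is.finite(mu)) && max(mu) <= 1e12)
})

test_that("ensembles round-trip through their JSON layout", {
  fx <- ens_fixture(8, seed = 3)
  set.seed(2)
  n <- fx$geom$n
  cells <- which(!diag(TRUE, n))
  obs <- matrix(0, n, n)
  obs[cells] <- rpois(length(cells), 5)
  ens <- fit_ensemble(obs, fx$preds)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$coefficients, ens$coefficients)
  expect_equal(back$training_deviance, ens$training_deviance)
})
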