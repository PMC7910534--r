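test_that("poisson_nll matches hand-computed values", {
  y <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(poisson_nll(y, y), 2)  # two off-diag cells, each 1 - log 1

  y0 <- matrix(c(0, 0, 0, 0), 2)
  mu3 <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(poisson_nll(y0, mu3), 6)  # zero-count cells contribute mu

  # scaling mu by e at y = 1 raises the per-cell NLL by e - 2
  one <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(poisson_nll(one, exp(1) * one) - poisson_nll(one, one),
               2 * (exp(1) - 2))
})

test_that("poisson_nll validates inputs and respects the mask", {
  y <- matrix(c(0, -1, 1, 0), 2)
  expect_error(poisson_nll(y, abs(y)), "non-negative")
  expect_error(poisson_nll(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")

  obs <- matrix(c(0, 2, 4, 0), 2)
  mu <- matrix(c(0, 1, 1, 0), 2)
  mask <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2)
  expect_equal(poisson_nll(obs, mu, mask), 1 - 2 * log(1))
})

test_that("gravity parameters are recovered exactly from noise-free flows", {
  scn <- synthetic_scenario(50, params = gravity_params(1, 0.8, 0.6, 1.5),
                            noise = "expectation", seed = 7)
  d <- scenario_data(scn)
  fit <- fit_model("gravity", d$flows, d$locs, d$geom)
  expect_true(fit$converged)
  expect_equal(fit$params$alpha, 0.8, tolerance = 1e-3)
  expect_equal(fit$params$beta, 0.6, tolerance = 1e-3)
  expect_equal(fit$params$gamma, 1.5, tolerance = 1e-3)
  expect_equal(fit$params$theta, 1, tolerance = 5e-3)

  # the truth is the exact optimum on noise-free flows; the achieved NLL
  # must sit at it up to convergence error
  truth_pred <- predict_matrix("gravity", scn$params, d$locs, d$geom)
  truth_nll <- poisson_nll(d$flows, truth_pred)
  expect_lte(fit$neg_log_likelihood, truth_nll + 1e-6 * abs(truth_nll))

  # optimiser soundness proper: on noisy flows the fit beats the truth
  scn_n <- synthetic_scenario(50, params = gravity_params(1, 0.8, 0.6, 1.5),
                              noise = "poisson", seed = 7)
  dn <- scenario_data(scn_n)
  fit_n <- fit_model("gravity", dn$flows, dn$locs, dn$geom)
  truth_n <- poisson_nll(dn$flows,
                         predict_matrix("gravity", scn_n$params, dn$locs,
                                        dn$geom))
  expect_lte(fit_n$neg_log_likelihood, truth_n)
})

test_that("refitting with the same configuration is bit-identical", {
  scn <- synthetic_scenario(20, noise = "poisson", seed = 11)
  d <- scenario_data(scn)
  f1 <- fit_model("gravity", d$flows, d$locs, d$geom, fit_config(seed = 4))
  f2 <- fit_model("gravity", d$flows, d$locs, d$geom, fit_config(seed = 4))
  expect_identical(f1, f2)
})

test_that("the fitted optimum beats a coarse grid on a 1-parameter slice", {
  scn <- synthetic_scenario(20, model = "radiation",
                            params = radiation_params(0.3),
                            noise = "poisson", seed = 5, mean_flow = 40)
  d <- scenario_data(scn)
  fit <- fit_model("radiation", d$flows, d$locs, d$geom)
  grid <- seq(0.5, 2, length.out = 61) * fit$params$theta
  grid_nll <- vapply(grid, function(th) {
    poisson_nll(d$flows,
                predict_matrix("radiation", radiation_params(th), d$locs,
                               d$geom))
  }, numeric(1))
  expect_lte(fit$neg_log_likelihood, min(grid_nll) + 1e-8)
  # and the grid argmin sits at the fitted theta within grid resolution
  expect_equal(grid[which.min(grid_nll)], fit$params$theta,
               tolerance = diff(grid[1:2]) / fit$params$theta * 1.5)
})

test_that("all five models converge on Poisson mixture data", {
  d <- scenario_data(mixture_scenario(25, seed = 2))
  for (id in flowstack_models()) {
    fit <- fit_model(id, d$flows, d$locs, d$geom)
    expect_true(fit$converged, info = id)
    expect_true(is.finite(fit$neg_log_likelihood), info = id)
  }
})

test_that("masked cells are excluded from the likelihood", {
  scn <- synthetic_scenario(12, noise = "poisson", seed = 9)
  d <- scenario_data(scn)
  corrupted <- d$flows
  mask <- !diag(TRUE, 12)
  mask[1, 2:6] <- FALSE
  corrupted[1, 2:6] <- 1e6   # absurd values in the masked cells
  f_ref <- fit_model("gravity", d$flows, d$locs, d$geom, mask = mask)
  f_cor <- fit_model("gravity", corrupted, d$locs, d$geom, mask = mask)
  expect_identical(f_ref$params, f_cor$params)
})

test_that("an all-zero flow matrix yields a collapsed-scale fit with warning", {
  locs <- rand_locs(6, seed = 1)
  geom <- pairwise_geometry(locs)
  zeros <- matrix(0, 6, 6)
  expect_warning(fit <- fit_model("gravity", zeros, locs, geom),
                 "all scored observed flows are zero")
  expect_lt(fit$params$theta, 1e-6)
})

test_that("fixing the distance cut-off is honoured", {
  d <- scenario_data(synthetic_scenario(15, noise = "poisson", seed = 3))
  cfg <- fit_config(fix_delta = 33)
  fit <- fit_model("gravity_distance", d$flows, d$locs, d$geom, cfg)
  expect_equal(fit$params$delta, 33)
})

test_that("fit results round-trip through JSON", {
  d <- scenario_data(mixture_scenario(12, seed = 6))
  for (id in c("gravity_distance", "intervening_opportunities",
               "radiation_selection")) {
    fit <- fit_model(id, d$flows, d$locs, d$geom)
    path <- tempfile(fileext = ".json")
    on.exit(unlink(path), add = TRUE)
    write_fit_result(fit, path)
    back <- read_fit_result(path)
    expect_equal(back$params, fit$params)
    expect_equal(back$neg_log_likelihood, fit$neg_log_likelihood)
  }
})
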