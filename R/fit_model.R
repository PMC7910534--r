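#' Poisson negative log-likelihood of a predicted OD matrix
#'
#' Returns `sum(mu - y * log(mu))` over the scored cells, i.e. the Poisson
#' negative log-likelihood up to the parameter-free `sum(log(y!))` constant.
#' Observed values may be non-integer (continuous-Poisson contract, so
#' normalised GPS-like intensities can be scored with the same code path).
#' Predictions are clamped below at `1e-10` before the log.
#'
#' @param observed,predicted Aligned square matrices.
#' @param mask Optional logical matrix marking the cells entering the sum;
#'   defaults to all off-diagonal cells.  Diagonal cells are never scored.
#' @return Scalar negative log-likelihood.
#' @export
#' @examples
#' y <- matrix(c(0, 1, 1, 0), 2)
#' poisson_nll(y, y)  # 2 * (1 - log 1) = 2
poisson_nll <- function(observed, predicted, mask = NULL) {
  observed <- as.matrix(observed)
  predicted <- as.matrix(predicted)
  if (!all(dim(observed) == dim(predicted))) {
    stop("observed and predicted matrices must have the same shape",
         call. = FALSE)
  }
  if (any(observed < 0, na.rm = TRUE)) {
    stop("observed flows must be non-negative", call. = FALSE)
  }
  n <- nrow(observed)
  if (is.null(mask)) {
    mask <- !diag(TRUE, n)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(observed))) {
      stop("mask shape does not match the matrices", call. = FALSE)
    }
    mask <- mask & !diag(TRUE, n)
  }
  y <- observed[mask]
  mu <- pmax(predicted[mask], .FLUX_EPS)
  sum(mu - y * log(mu))
}

#' Fitting configuration
#'
#' @param seed Integer seed controlling restart jitter (the base optimisation
#'   itself is deterministic).
#' @param max_iterations Maximum BFGS iterations per start.
#' @param tolerance Relative convergence tolerance handed to the optimiser.
#' @param max_restarts Jittered restarts attempted after a non-converged run.
#' @param fix_delta Optional fixed distance cut-off (km) for the
#'   gravity-with-distance model; when `NULL` (default) delta is estimated
#'   jointly with the other parameters through a log transform.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(seed = 1L, max_iterations = 500L, tolerance = 1e-10,
                       max_restarts = 3L, fix_delta = NULL) {
  stopifnot(max_iterations >= 1, tolerance > 0, max_restarts >= 0)
  structure(list(seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 max_restarts = as.integer(max_restarts),
                 fix_delta = fix_delta),
            class = "fit_config")
}

# ---- parameter transforms ---------------------------------------------------
# Each model optimises over an unconstrained vector: log for positive scales
# (theta, kappa, lam_IO, theta_exp, delta), logit for the selection lam in
# (0,1), identity for the power-law exponents.

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

.unpack_params <- function(model_id, vec, cfg) {
  switch(
    model_id,
    gravity = gravity_params(exp(vec[1L]), vec[2L], vec[3L], vec[4L]),
    gravity_distance = {
      delta <- if (is.null(cfg$fix_delta)) exp(vec[9L]) else cfg$fix_delta
      gravity_distance_params(
        delta,
        short = gravity_params(exp(vec[1L]), vec[2L], vec[3L], vec[4L]),
        long = gravity_params(exp(vec[5L]), vec[6L], vec[7L], vec[8L])
      )
    },
    radiation = radiation_params(exp(vec[1L])),
    radiation_selection = radiation_selection_params(exp(vec[1L]),
                                                     .inv_logit(vec[2L])),
    intervening_opportunities = intervening_opportunities_params(
      exp(vec[1L]), exp(vec[2L]), exp(vec[3L])
    )
  )
}

.pack_params <- function(params, cfg) {
  switch(
    .params_model_id(params),
    gravity = c(log(params$theta), params$alpha, params$beta, params$gamma),
    gravity_distance = {
      v <- c(log(params$short$theta), params$short$alpha, params$short$beta,
             params$short$gamma,
             log(params$long$theta), params$long$alpha, params$long$beta,
             params$long$gamma)
      if (is.null(cfg$fix_delta)) v <- c(v, log(params$delta))
      v
    },
    radiation = log(params$theta),
    radiation_selection = c(log(params$theta), .logit(params$lam)),
    intervening_opportunities = c(log(params$kappa), log(params$lam),
                                  log(params$theta_exp))
  )
}

# Starting values: power-law exponents at 1, scale constants matched to the
# mean observed flow, lam_sel at 0.5, lam_IO such that the median cumulative
# opportunity count has survival probability one half, delta at the median
# off-diagonal distance.
.start_params <- function(model_id, observed, locs, geom, mask, cfg) {
  ybar <- mean(observed[mask])
  scale_to_data <- function(params) {
    pred <- .flux_matrix(model_id, params, locs, geom)
    pbar <- mean(pred[mask])
    if (!is.finite(pbar) || pbar <= 0 || ybar <= 0) 1 else ybar / pbar
  }
  switch(
    model_id,
    gravity = {
      p0 <- gravity_params(1, 1, 1, 1)
      gravity_params(max(scale_to_data(p0), 1e-12), 1, 1, 1)
    },
    gravity_distance = {
      delta0 <- if (is.null(cfg$fix_delta)) {
        stats::median(geom$distances[mask])
      } else {
        cfg$fix_delta
      }
      g0 <- gravity_params(1, 1, 1, 1)
      th <- max(scale_to_data(gravity_distance_params(delta0, g0, g0)), 1e-12)
      gravity_distance_params(delta0,
                              gravity_params(th, 1, 1, 1),
                              gravity_params(th, 1, 1, 1))
    },
    radiation = {
      p0 <- radiation_params(1)
      radiation_params(max(scale_to_data(p0), 1e-12))
    },
    radiation_selection = {
      p0 <- radiation_selection_params(1, 0.5)
      radiation_selection_params(max(scale_to_data(p0), 1e-12), 0.5)
    },
    intervening_opportunities = {
      n <- geom$n
      M <- matrix(locs$populations, n, n)
      lam0 <- log(2) / stats::median((geom$intervening + M)[mask])
      p0 <- intervening_opportunities_params(1, lam0, 1)
      intervening_opportunities_params(max(scale_to_data(p0), 1e-12), lam0, 1)
    }
  )
}

#' Fit a base movement model by Poisson maximum likelihood
#'
#' Minimises [poisson_nll()] over the model's parameter space with BFGS on
#' unconstrained transformed parameters (log for positive scales, logit for
#' the selection parameter, identity for exponents).  Gradients are numerical
#' central differences.  After the first run the optimum is polished by a
#' second BFGS pass; if the optimiser reports non-convergence, up to
#' `config$max_restarts` seeded jittered restarts are attempted and the best
#' result kept.
#'
#' @param model_id One of [flowstack_models()].
#' @param observed Observed OD matrix (non-negative, diagonal ignored).
#' @param locs A `location_set`.
#' @param geom A `pairwise_geometry`.
#' @param config A [fit_config()].
#' @param mask Optional logical matrix of cells entering the likelihood
#'   (e.g. the training cells of a cross-validation fold); defaults to all
#'   off-diagonal cells.
#' @return A `fit_result`: list with `model_id`, `params`,
#'   `neg_log_likelihood`, `converged`, `n_iterations`, `seed`.
#' @export
fit_model <- function(model_id, observed, locs, geom, config = fit_config(),
                      mask = NULL) {
  model_id <- match.arg(model_id, flowstack_models())
  stopifnot(inherits(locs, "location_set"),
            inherits(geom, "pairwise_geometry"),
            inherits(config, "fit_config"))
  observed <- as.matrix(observed)
  n <- geom$n
  if (!all(dim(observed) == c(n, n))) {
    stop("observed matrix shape does not match the geometry", call. = FALSE)
  }
  if (any(observed < 0)) {
    stop("observed flows must be non-negative", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- !diag(TRUE, n)
  } else {
    mask <- as.matrix(mask) & !diag(TRUE, n)
  }
  if (all(observed[mask] == 0)) {
    warning("all scored observed flows are zero; the fitted scale will collapse towards the prediction floor",
            call. = FALSE)
  }

  objective <- function(vec) {
    params <- tryCatch(.unpack_params(model_id, vec, config),
                       error = function(e) NULL)
    if (is.null(params)) return(1e12)
    pred <- .flux_matrix(model_id, params, locs, geom)
    if (any(!is.finite(pred[mask]))) return(1e12)
    val <- poisson_nll(observed, pred, mask)
    if (!is.finite(val)) 1e12 else val
  }

  run_bfgs <- function(start) {
    res <- stats::optim(start, objective, method = "BFGS",
                        control = list(maxit = config$max_iterations,
                                       reltol = config$tolerance,
                                       ndeps = rep(1e-6, length(start))))
    # polish from the optimum; keep whichever is better
    res2 <- stats::optim(res$par, objective, method = "BFGS",
                         control = list(maxit = config$max_iterations,
                                        reltol = config$tolerance,
                                        ndeps = rep(1e-6, length(start))))
    if (res2$value <= res$value) {
      res2$counts <- res$counts + res2$counts
      res2
    } else {
      res
    }
  }

  start <- .pack_params(.start_params(model_id, observed, locs, geom, mask,
                                      config), config)
  best <- run_bfgs(start)
  attempts <- 0L
  while (best$convergence != 0 && attempts < config$max_restarts) {
    attempts <- attempts + 1L
    set.seed(config$seed + 7919L * attempts)
    jitter <- stats::rnorm(length(start), sd = 0.3)
    cand <- run_bfgs(best$par + jitter)
    if (cand$value < best$value || cand$convergence == 0) best <- cand
  }
  converged <- best$convergence == 0 && is.finite(best$value) &&
    best$value < 1e12
  if (!converged) {
    warning(sprintf("fit of '%s' did not converge after %d restart(s); returning best point found",
                    model_id, attempts), call. = FALSE)
  }
  structure(
    list(model_id = model_id,
         params = .unpack_params(model_id, best$par, config),
         neg_log_likelihood = best$value,
         converged = converged,
         n_iterations = as.integer(best$counts[["function"]]),
         seed = config$seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s, NLL = %.4f, %s after %d evaluations>\n",
              x$model_id, x$neg_log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  p <- unclass(x$params)
  if (x$model_id == "gravity_distance") {
    p <- c(list(delta = p$delta),
           stats::setNames(unclass(p$short), paste0(names(unclass(p$short)), "_short")),
           stats::setNames(unclass(p$long), paste0(names(unclass(p$long)), "_long")))
  }
  cat("  ", paste(sprintf("%s = %.5g", names(p), unlist(p)), collapse = ", "),
      "\n")
  invisible(x)
}
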