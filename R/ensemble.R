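#' Ensemble (stacker) configuration
#'
#' @param ridge Non-negative ridge penalty added to the non-intercept
#'   diagonal of the IRLS normal equations; 0 (default) reproduces the plain
#'   unregularised Poisson GLM, where strongly collinear base predictions
#'   may legitimately receive huge offsetting weights.
#' @param max_iter Maximum IRLS iterations.
#' @param tolerance Relative deviance-change convergence tolerance.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(ridge = 0, max_iter = 100L, tolerance = 1e-10) {
  stopifnot(ridge >= 0, max_iter >= 1, tolerance > 0)
  structure(list(ridge = ridge, max_iter = as.integer(max_iter),
                 tolerance = tolerance),
            class = "ensemble_config")
}

#' Stacker design matrix from five base-model predictions
#'
#' Vectorises the off-diagonal cells of the five predicted OD matrices (in
#' the fixed [flowstack_models()] order) into a k x 5 matrix of
#' log-predictions, `k = z^2 - z` for z regions.  Diagonal cells are
#' excluded: base predictions there are exactly zero and their log is
#' undefined.  Each entry is `log(max(prediction, 1e-10))`.  Collinear or
#' identical columns are kept as-is; resolving them is the fitter's job.
#'
#' @param predictions List of five aligned square prediction matrices.  If
#'   named, names must be the canonical model ids (any order, reordered
#'   internally); if unnamed, canonical order is assumed.
#' @return List with `X` (k x 5 log-prediction matrix, columns named by model
#'   id), `cells` (column-major linear indices of the off-diagonal cells) and
#'   `index` (k x 2 matrix of (origin row, destination column) pairs).
#' @export
build_design <- function(predictions) {
  ids <- flowstack_models()
  if (!is.list(predictions) || length(predictions) != 5L) {
    stop("predictions must be a list of five matrices", call. = FALSE)
  }
  if (!is.null(names(predictions)) && !all(names(predictions) == "")) {
    if (!setequal(names(predictions), ids)) {
      stop("prediction names must be the five canonical model ids",
           call. = FALSE)
    }
    predictions <- predictions[ids]
  } else {
    names(predictions) <- ids
  }
  dims <- vapply(predictions, function(p) dim(as.matrix(p)), integer(2))
  n <- dims[1L, 1L]
  if (any(dims != n)) {
    stop("all prediction matrices must be square and of identical shape",
         call. = FALSE)
  }
  cells <- .offdiag_cells(n)
  X <- vapply(predictions,
              function(p) log(pmax(as.matrix(p)[cells], .FLUX_EPS)),
              numeric(length(cells)))
  list(X = X, cells = cells, index = arrayInd(cells, c(n, n)), n = n)
}

#' Fit the stacked Poisson ensemble
#'
#' Regresses the observed off-diagonal flows on the logs of the five base
#' models' predictions with a Poisson GLM (log link):
#' `log(mu) = b0 + b1 log(l1) + ... + b5 log(l5)`.  Fitting is by iteratively
#' reweighted least squares; each weighted least-squares step is solved with
#' a pseudo-inverse, so exactly or nearly collinear prediction columns are
#' retained rather than dropped (offsetting weights on near-duplicate models
#' are a faithful behaviour of the unregularised stacker).
#'
#' @param observed Observed OD matrix aligned with the predictions.
#' @param predictions List of five base-model prediction matrices (see
#'   [build_design()]).
#' @param config An [ensemble_config()].
#' @param train_rows Optional logical or integer subset of design rows
#'   (off-diagonal cells, column-major order) to train on; defaults to all.
#' @return A `stacked_ensemble`: list with `coefficients` (intercept plus one
#'   weight per model id), `converged`, `training_deviance`, `n_iterations`.
#' @export
fit_ensemble <- function(observed, predictions, config = ensemble_config(),
                         train_rows = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  d <- build_design(predictions)
  observed <- as.matrix(observed)
  if (!all(dim(observed) == c(d$n, d$n))) {
    stop("observed matrix shape does not match the predictions",
         call. = FALSE)
  }
  if (any(observed < 0)) {
    stop("observed flows must be non-negative", call. = FALSE)
  }
  y_all <- observed[d$cells]
  X_all <- cbind(intercept = 1, d$X)
  if (is.null(train_rows)) train_rows <- seq_along(y_all)
  y <- y_all[train_rows]
  X <- X_all[train_rows, , drop = FALSE]

  # weighted least-squares step solved by SVD on sqrt(w) * X: numerically
  # equivalent to the QR solve of a standard GLM fitter but rank-deficient
  # designs get the minimum-norm (pseudo-inverse) solution instead of
  # dropped columns, so near-duplicate base models keep their (possibly
  # offsetting) weights
  pinv_lstsq <- function(Xw, zw) {
    sv <- svd(Xw)
    keep <- sv$d > max(sv$d) * .Machine$double.eps * max(dim(Xw))
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], zw) / sv$d[keep]))
  }
  ridge_rows <- sqrt(config$ridge) * diag(6L)[-1L, , drop = FALSE]
  mu <- (y + mean(y)) / 2 + .FLUX_EPS
  eta <- log(mu)
  dev <- poisson_deviance(y, mu)
  beta <- rep(0, 6L)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    w <- mu
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    if (config$ridge > 0) {
      beta_new <- pinv_lstsq(rbind(sw * X, ridge_rows), c(sw * z, rep(0, 5L)))
    } else {
      beta_new <- pinv_lstsq(sw * X, sw * z)
    }
    eta <- pmin(drop(X %*% beta_new), log(.MU_CAP))
    mu <- pmax(exp(eta), .FLUX_EPS)
    dev_new <- poisson_deviance(y, mu)
    if (!is.finite(dev_new)) {
      warning("IRLS diverged (non-finite deviance); returning last finite state",
              call. = FALSE)
      break
    }
    beta <- beta_new
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < config$tolerance) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  if (!converged && iter >= config$max_iter) {
    warning(sprintf("ensemble IRLS did not converge in %d iterations (deviance %.6g)",
                    iter, dev), call. = FALSE)
  }
  names(beta) <- c("intercept", flowstack_models())
  structure(
    list(coefficients = beta, converged = converged,
         training_deviance = dev, n_iterations = iter),
    class = "stacked_ensemble"
  )
}

#' Predict flows from a fitted stacked ensemble
#'
#' `mu = exp(b0 + sum_a b_a log(lambda_a))` on every off-diagonal cell, with
#' the diagonal forced to zero.  Entries that would overflow are capped at
#' `1e12` with a warning.
#'
#' @param model A `stacked_ensemble` from [fit_ensemble()].
#' @param predictions List of five base-model prediction matrices.
#' @return Square non-negative matrix of ensemble-predicted flows.
#' @export
predict_ensemble <- function(model, predictions) {
  stopifnot(inherits(model, "stacked_ensemble"))
  d <- build_design(predictions)
  eta <- drop(cbind(1, d$X) %*% model$coefficients)
  if (any(eta > log(.MU_CAP))) {
    warning(sprintf("ensemble predictions capped at %g", .MU_CAP),
            call. = FALSE)
    eta <- pmin(eta, log(.MU_CAP))
  }
  out <- matrix(0, d$n, d$n)
  out[d$cells] <- exp(eta)
  dimnames(out) <- dimnames(as.matrix(predictions[[1L]]))
  out
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf("<stacked_ensemble: training deviance %.4f, %s in %d IRLS iterations>\n",
              x$training_deviance,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Serialise a stacked ensemble to JSON
#'
#' Layout: `{"intercept": b0, "weights": {<model id>: b_a, ...},
#' "converged": ..., "training_deviance": ...}`.
#'
#' @param model A `stacked_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(model, path) {
  stopifnot(inherits(model, "stacked_ensemble"))
  obj <- list(
    intercept = model$coefficients[["intercept"]],
    weights = as.list(model$coefficients[flowstack_models()]),
    converged = model$converged,
    training_deviance = model$training_deviance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a stacked ensemble from JSON
#'
#' @param path File written by [write_ensemble()].
#' @return A `stacked_ensemble`.
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- c(intercept = obj$intercept,
            unlist(obj$weights)[flowstack_models()])
  names(beta) <- c("intercept", flowstack_models())
  structure(
    list(coefficients = beta,
         converged = isTRUE(obj$converged),
         training_deviance = obj$training_deviance,
         n_iterations = NA_integer_),
    class = "stacked_ensemble"
  )
}
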