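#' Poisson deviance between observed and predicted flows
#'
#' `D = 2 * sum(y * log(y / mu) - (y - mu))`, with the `y = 0` term taken as
#' its limit `2 * mu`.  Predictions are clamped below at `1e-10`.  Observed
#' values may be non-integer (normalised intensities score through the same
#' formula).  The deviance is a relative measure: values are comparable
#' across models scored on the same data only.
#'
#' @param observed,predicted Numeric vectors (or matrices, used elementwise)
#'   of equal length; `observed >= 0`.
#' @return Scalar non-negative deviance.
#' @export
#' @examples
#' poisson_deviance(c(2), c(1))  # 2 * (2 log 2 - 1)
#' poisson_deviance(c(0), c(3))  # 6
poisson_deviance <- function(observed, predicted) {
  y <- as.numeric(observed)
  mu <- as.numeric(predicted)
  if (length(y) != length(mu)) {
    stop("observed and predicted must have the same length", call. = FALSE)
  }
  if (any(y < 0)) {
    stop("observed flows must be non-negative", call. = FALSE)
  }
  mu <- pmax(mu, .FLUX_EPS)
  term <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
  2 * sum(term)
}

#' Random partition of off-diagonal OD cells into k folds
#'
#' Cells (not regions) are partitioned, so every fold holds out a random set
#' of origin-destination flows between regions that remain in training.
#' Fold sizes differ by at most one; the same seed reproduces the same
#' assignment exactly.
#'
#' @param n_regions Number of regions (the OD matrix is n x n).
#' @param k Number of folds, `>= 2` and at most the number of off-diagonal
#'   cells.
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `k`, `n`, `cells` (column-major
#'   linear indices of off-diagonal cells), `fold` (fold index per cell) and
#'   `seed`.
#' @export
make_folds <- function(n_regions, k, seed) {
  n_regions <- as.integer(n_regions)
  k <- as.integer(k)
  ncells <- n_regions^2 - n_regions
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > ncells) {
    stop("k exceeds the number of off-diagonal cells", call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = ncells))
  structure(
    list(k = k, n = n_regions, cells = .offdiag_cells(n_regions),
         fold = fold, seed = as.integer(seed)),
    class = "fold_assignment"
  )
}

#' k-fold cross-validation of base models, stacked ensemble and mean baseline
#'
#' For each fold: the five base models are refitted by Poisson maximum
#' likelihood on the training cells only (held-out cells are masked from the
#' likelihood, not zero-filled); the stacked ensemble is then trained on the
#' same training cells using those fold-specific base predictions (no
#' leakage); finally every model — each base model, the ensemble, and the
#' unweighted mean of the five base predictions — is scored by Poisson
#' deviance on the held-out cells.
#'
#' @param observed Observed OD matrix.
#' @param locs A `location_set`.
#' @param geom A `pairwise_geometry`.
#' @param model_ids Base models to include (default all five).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param fit_cfg A [fit_config()] for the per-fold base-model fits.
#' @param ens_cfg An [ensemble_config()] for the per-fold stacker fits.
#' @return A `cv_report`: list with `deviance` (model x fold matrix), `mean`,
#'   `min`, `max` per model, `k`, `seed` and a per-fold `degraded` flag
#'   marking folds where some base fit failed to converge.
#' @export
cross_validate <- function(observed, locs, geom,
                           model_ids = flowstack_models(), k = 5, seed = 1,
                           fit_cfg = fit_config(), ens_cfg = ensemble_config()) {
  model_ids <- match.arg(model_ids, flowstack_models(), several.ok = TRUE)
  observed <- as.matrix(observed)
  n <- geom$n
  fa <- make_folds(n, k, seed)
  full_ensemble <- setequal(model_ids, flowstack_models())
  rows <- c(model_ids, if (full_ensemble) c("ensemble", "mean") else "mean")
  dev <- matrix(NA_real_, length(rows), fa$k,
                dimnames = list(rows, paste0("fold", seq_len(fa$k))))
  degraded <- logical(fa$k)

  for (f in seq_len(fa$k)) {
    train <- fa$fold != f
    test_cells <- fa$cells[!train]
    mask <- matrix(FALSE, n, n)
    mask[fa$cells[train]] <- TRUE
    y_test <- observed[test_cells]

    fits <- lapply(model_ids, function(id) {
      fit_model(id, observed, locs, geom, fit_cfg, mask = mask)
    })
    names(fits) <- model_ids
    if (any(!vapply(fits, `[[`, logical(1), "converged"))) {
      degraded[f] <- TRUE
      warning(sprintf("fold %d: at least one base model did not converge; fold marked degraded",
                      f), call. = FALSE)
    }
    preds <- lapply(fits, function(fr) {
      .flux_matrix(fr$model_id, fr$params, locs, geom)
    })
    for (id in model_ids) {
      dev[id, f] <- poisson_deviance(y_test, preds[[id]][test_cells])
    }
    mean_pred <- Reduce(`+`, preds) / length(preds)
    dev["mean", f] <- poisson_deviance(y_test, mean_pred[test_cells])
    if (full_ensemble) {
      ens <- fit_ensemble(observed, preds, ens_cfg, train_rows = train)
      mu <- predict_ensemble(ens, preds)
      dev["ensemble", f] <- poisson_deviance(y_test, mu[test_cells])
    }
  }

  structure(
    list(deviance = dev,
         mean = rowMeans(dev),
         min = apply(dev, 1L, min),
         max = apply(dev, 1L, max),
         k = fa$k, seed = fa$seed, degraded = degraded),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d-fold, seed %d>\n", x$k, x$seed))
  tab <- cbind(mean = x$mean, min = x$min, max = x$max)
  print(signif(tab, 6))
  if (any(x$degraded)) {
    cat("  degraded folds:", paste(which(x$degraded), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Long-format view of a CV report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A data frame with columns `model`, `fold`, `deviance`.
#' @export
as.data.frame.cv_report <- function(x, ...) {
  data.frame(
    model = rep(rownames(x$deviance), ncol(x$deviance)),
    fold = rep(seq_len(ncol(x$deviance)), each = nrow(x$deviance)),
    deviance = as.vector(x$deviance),
    stringsAsFactors = FALSE
  )
}

#' Write a CV report as CSV (model,fold,deviance) plus a JSON summary
#'
#' @param report A `cv_report`.
#' @param csv_path Path for the long-format CSV.
#' @param json_path Optional path for a JSON summary (per-model mean/min/max,
#'   k, seed, degraded folds); skipped when `NULL`.
#' @return `csv_path`, invisibly.
#' @export
write_cv_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  df <- as.data.frame(report)
  df$deviance <- sprintf("%.17g", df$deviance)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    obj <- list(
      k = report$k, seed = report$seed,
      models = lapply(rownames(report$deviance), function(id) {
        list(model = id, mean_deviance = report$mean[[id]],
             min_deviance = report$min[[id]], max_deviance = report$max[[id]])
      }),
      degraded_folds = which(report$degraded)
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(csv_path)
}
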