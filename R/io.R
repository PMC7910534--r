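# Numbers are written with 17 significant digits so every writer/reader pair
# round-trips doubles bit-identically.
.fmt_num <- function(x) sprintf("%.17g", x)

#' Read a location table from CSV
#'
#' Accepts the two declared dialects: header `id,x,y,population` (projected
#' kilometres) or `id,lon,lat,population` (degrees).  No missing values are
#' allowed.
#'
#' @param path CSV file path.
#' @return A `location_set`.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (identical(names(df), c("id", "x", "y", "population"))) {
    mode <- "projected_km"
    coords <- cbind(df$x, df$y)
  } else if (identical(names(df), c("id", "lon", "lat", "population"))) {
    mode <- "lonlat_degrees"
    coords <- cbind(df$lon, df$lat)
  } else {
    stop(sprintf("unrecognised location header in '%s': expected id,x,y,population or id,lon,lat,population",
                 path), call. = FALSE)
  }
  if (anyNA(df)) {
    stop(sprintf("missing values in location table '%s' (first bad row %d)",
                 path, which(rowSums(is.na(df)) > 0)[1L]), call. = FALSE)
  }
  location_set(df$id, coords, df$population, coord_mode = mode)
}

#' Write a location table to CSV
#'
#' @param locs A `location_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locations <- function(locs, path) {
  stopifnot(inherits(locs, "location_set"))
  nm <- if (locs$coord_mode == "projected_km") c("x", "y") else c("lon", "lat")
  df <- data.frame(id = locs$ids,
                   a = .fmt_num(locs$coords[, 1L]),
                   b = .fmt_num(locs$coords[, 2L]),
                   population = .fmt_num(locs$populations))
  names(df)[2:3] <- nm
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OD flow matrix from CSV
#'
#' Two dialects are accepted.  Long format has header
#' `origin,destination,count`; absent pairs are zero.  Wide format is a
#' square matrix with an `id` first column and one column per region.  All
#' ids must belong to `ids`; in wide format the row/column ids must match
#' `ids` exactly and in order.  Self-loop entries with a positive count are
#' ignored with a warning (the models force a zero diagonal); negative
#' counts and unknown ids are errors naming the offending row.
#'
#' @param path CSV file path.
#' @param ids Region ids of the matching location set.
#' @return Square flow matrix with zero diagonal, dimnames `ids`.
#' @export
read_od <- function(path, ids) {
  ids <- as.character(ids)
  n <- length(ids)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  if (identical(names(df), c("origin", "destination", "count"))) {
    oi <- match(df$origin, ids)
    di <- match(df$destination, ids)
    bad <- which(is.na(oi) | is.na(di))
    if (length(bad)) {
      stop(sprintf("unknown region id in '%s' at data row %d", path, bad[1L]),
           call. = FALSE)
    }
    if (any(df$count < 0)) {
      stop(sprintf("negative count in '%s' at data row %d", path,
                   which(df$count < 0)[1L]), call. = FALSE)
    }
    loops <- oi == di
    if (any(df$count[loops] > 0)) {
      warning(sprintf("'%s': %d self-loop flow(s) ignored (zero-diagonal rule)",
                      path, sum(df$count[loops] > 0)), call. = FALSE)
    }
    keep <- !loops
    out[cbind(oi[keep], di[keep])] <- df$count[keep]
  } else if (names(df)[1L] == "id") {
    if (ncol(df) - 1L != nrow(df)) {
      stop(sprintf("wide OD matrix in '%s' is not square (%d rows, %d value columns)",
                   path, nrow(df), ncol(df) - 1L), call. = FALSE)
    }
    if (!identical(as.character(df$id), ids) ||
        !identical(names(df)[-1L], ids)) {
      stop(sprintf("wide OD matrix ids in '%s' must match the location table exactly",
                   path), call. = FALSE)
    }
    vals <- as.matrix(df[, -1L])
    if (any(vals < 0)) {
      stop(sprintf("negative count in '%s' at data row %d", path,
                   which(rowSums(vals < 0) > 0)[1L]), call. = FALSE)
    }
    if (any(diag(vals) > 0)) {
      warning(sprintf("'%s': positive diagonal entries ignored (zero-diagonal rule)",
                      path), call. = FALSE)
    }
    out[, ] <- vals
    diag(out) <- 0
  } else {
    stop(sprintf("unrecognised OD header in '%s'", path), call. = FALSE)
  }
  out
}

#' Write an OD flow matrix to CSV
#'
#' Long format (the canonical on-disk form; zero cells are omitted, so large
#' sparse matrices stay small) or wide square format for small matrices.
#'
#' @param mat Square flow matrix.
#' @param ids Region ids (defaults to the matrix dimnames).
#' @param path Output path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_od <- function(mat, path, ids = rownames(mat),
                     format = c("long", "wide")) {
  format <- match.arg(format)
  mat <- as.matrix(mat)
  if (is.null(ids)) stop("region ids are required", call. = FALSE)
  n <- length(ids)
  stopifnot(all(dim(mat) == n))
  if (format == "long") {
    idx <- which(mat != 0 & !diag(TRUE, n), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    df <- data.frame(origin = ids[idx[, 1L]],
                     destination = ids[idx[, 2L]],
                     count = .fmt_num(mat[idx]))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(id = ids)
    for (j in seq_len(n)) df[[ids[j]]] <- .fmt_num(mat[, j])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Scale a predicted OD matrix to the unit interval
#'
#' Divides by the maximum entry so all predictions lie in [0, 1] (the
#' scaling used before mapping predictions to visual intensity).  Rank order
#' is preserved and the diagonal stays zero.
#'
#' @param predicted Square non-negative matrix with at least one positive
#'   entry.
#' @return The matrix divided by its maximum.
#' @export
scale_unit <- function(predicted) {
  predicted <- as.matrix(predicted)
  mx <- max(predicted)
  if (!is.finite(mx) || mx <= 0) {
    stop("cannot unit-scale a matrix with no positive entries", call. = FALSE)
  }
  predicted / mx
}

#' Serialise a fit result to JSON
#'
#' Layout: `{"model": <id>, "params": {<name>: <value>}, ...}` with the
#' gravity-with-distance branches flattened as `theta_short`, ...,
#' `gamma_long`, `delta`.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  p <- unclass(fit$params)
  if (fit$model_id == "gravity_distance") {
    p <- c(list(delta = p$delta),
           stats::setNames(unclass(p$short),
                           paste0(names(unclass(p$short)), "_short")),
           stats::setNames(unclass(p$long),
                           paste0(names(unclass(p$long)), "_long")))
  }
  obj <- list(model = fit$model_id, params = p,
              neg_log_likelihood = fit$neg_log_likelihood,
              converged = fit$converged, n_iterations = fit$n_iterations,
              seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a fit result from JSON
#'
#' @param path File written by [write_fit_result()].
#' @return A `fit_result`.
#' @export
read_fit_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  params <- switch(
    obj$model,
    gravity = gravity_params(p$theta, p$alpha, p$beta, p$gamma),
    gravity_distance = gravity_distance_params(
      p$delta,
      gravity_params(p$theta_short, p$alpha_short, p$beta_short, p$gamma_short),
      gravity_params(p$theta_long, p$alpha_long, p$beta_long, p$gamma_long)
    ),
    radiation = radiation_params(p$theta),
    radiation_selection = radiation_selection_params(p$theta, p$lam),
    intervening_opportunities = intervening_opportunities_params(
      p$kappa, p$lam, p$theta_exp),
    stop(sprintf("unknown model id '%s' in '%s'", obj$model, path),
         call. = FALSE)
  )
  structure(
    list(model_id = obj$model, params = params,
         neg_log_likelihood = obj$neg_log_likelihood,
         converged = isTRUE(obj$converged),
         n_iterations = obj$n_iterations, seed = obj$seed),
    class = "fit_result"
  )
}
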