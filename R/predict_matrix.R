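# Vectorised flux evaluation over all region pairs.  No validation and no
# error on non-finite values: the likelihood objective calls this inside the
# optimiser and handles bad parameter regions itself.
.flux_matrix <- function(model_id, params, locs, geom) {
  n <- geom$n
  pop <- locs$populations
  M <- matrix(pop, n, n)        # origin population, constant along rows
  N <- t(M)                     # destination population
  R <- geom$distances
  S <- geom$intervening
  Rsafe <- R
  diag(Rsafe) <- 1              # diagonal overwritten with 0 below
  out <- switch(
    model_id,
    gravity = {
      params$theta * M^params$alpha * N^params$beta / Rsafe^params$gamma
    },
    gravity_distance = {
      short <- params$short
      long <- params$long
      ifelse(R <= params$delta,
             short$theta * M^short$alpha * N^short$beta / Rsafe^short$gamma,
             long$theta * M^long$alpha * N^long$beta / Rsafe^long$gamma)
    },
    radiation = {
      params$theta * M * N / ((M + S) * (M + N + S))
    },
    radiation_selection = {
      loglam <- log(params$lam)
      f <- function(x) 1 - exp(x * loglam) / x
      # the printed equation can dip below zero for sub-unit populations;
      # predicted flows are defined as non-negative
      pmax(params$theta * f(M) * f(N) / f(M + N + S), 0)
    },
    intervening_opportunities = {
      params$kappa * (exp(-params$lam * (S + M)^params$theta_exp) -
                        exp(-params$lam * (S + M + N)^params$theta_exp))
    },
    stop(sprintf("unknown model id '%s'", model_id), call. = FALSE)
  )
  diag(out) <- 0
  out
}

#' Predicted origin-destination matrix for a base model
#'
#' Evaluates the model's flux for every ordered region pair and sets all
#' self-loops (diagonal cells) to exactly zero, since none of the movement
#' models allow within-region trips.
#'
#' @param model_id One of [flowstack_models()].
#' @param params The matching `*_params` object.
#' @param locs A `location_set`.
#' @param geom A `pairwise_geometry` for the same regions.
#' @return Square non-negative matrix of predicted flows with zero diagonal
#'   and region ids as dimnames.
#' @export
#' @examples
#' locs <- location_set(letters[1:3], cbind(c(0, 5, 10), 0), c(10, 20, 30))
#' geom <- pairwise_geometry(locs)
#' predict_matrix("gravity", gravity_params(1, 1, 1, 1), locs, geom)
predict_matrix <- function(model_id, params, locs, geom) {
  stopifnot(inherits(locs, "location_set"),
            inherits(geom, "pairwise_geometry"))
  model_id <- match.arg(model_id, flowstack_models())
  if (.params_model_id(params) != model_id) {
    stop(sprintf("params of class '%s' do not match model '%s'",
                 class(params)[1L], model_id), call. = FALSE)
  }
  if (geom$n != length(locs$ids)) {
    stop("geometry does not match the location set", call. = FALSE)
  }
  out <- .flux_matrix(model_id, params, locs, geom)
  if (any(!is.finite(out))) {
    stop("predicted flows are not all finite; parameters are out of range for these inputs",
         call. = FALSE)
  }
  if (any(out < 0)) {
    stop("predicted flows must be non-negative", call. = FALSE)
  }
  dimnames(out) <- list(locs$ids, locs$ids)
  out
}
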