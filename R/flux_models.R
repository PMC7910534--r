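#' Gravity model parameters
#'
#' Flux between an origin of population m and destination of population n at
#' distance r is `theta * m^alpha * n^beta / r^gamma`.  `alpha` and `beta`
#' tune the dependence on origin and destination population, `gamma` the
#' distance decay, `theta` sets the overall scale.
#'
#' @param theta Positive scale constant.
#' @param alpha,beta Real exponents on origin and destination population.
#' @param gamma Real exponent on distance.
#' @return Object of class `gravity_params`.
#' @export
gravity_params <- function(theta, alpha, beta, gamma) {
  .check_finite(theta = theta, alpha = alpha, beta = beta, gamma = gamma)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  structure(list(theta = theta, alpha = alpha, beta = beta, gamma = gamma),
            class = c("gravity_params", "model_params"))
}

#' Gravity with distance cut-off parameters
#'
#' Short trips (r <= delta) and long trips (r > delta) get independent
#' gravity parameter sets, so the two trip regimes are fitted separately.
#' The boundary r = delta belongs to the short-range branch.
#'
#' @param delta Positive cut-off distance in kilometres.
#' @param short,long `gravity_params` for the short- and long-range branches.
#' @return Object of class `gravity_distance_params`.
#' @export
gravity_distance_params <- function(delta, short, long) {
  .check_finite(delta = delta)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  stopifnot(inherits(short, "gravity_params"), inherits(long, "gravity_params"))
  structure(list(delta = delta, short = short, long = long),
            class = c("gravity_distance_params", "model_params"))
}

#' Radiation model parameters
#'
#' @param theta Positive scale.  Interpreted as the proportion of the origin
#'   population that commutes when flows are raw counts; left unconstrained
#'   above (only `theta > 0` enforced) so the model can also be fitted to
#'   normalised intensities, where the proportion reading does not apply.
#' @return Object of class `radiation_params`.
#' @export
radiation_params <- function(theta) {
  .check_finite(theta = theta)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  structure(list(theta = theta), class = c("radiation_params", "model_params"))
}

#' Radiation with selection parameters
#'
#' @param theta Positive scale.
#' @param lam Selection parameter in (0, 1): the probability that any single
#'   opportunity is not attractive enough to end the trip.
#' @return Object of class `radiation_selection_params`.
#' @export
radiation_selection_params <- function(theta, lam) {
  .check_finite(theta = theta, lam = lam)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (lam <= 0 || lam >= 1) stop("lam must lie in (0, 1)", call. = FALSE)
  structure(list(theta = theta, lam = lam),
            class = c("radiation_selection_params", "model_params"))
}

#' Intervening opportunities (Schneider) parameters
#'
#' @param kappa Positive proportionality constant giving the model an
#'   absolute intensity scale (required for Poisson fitting).
#' @param lam Positive rate; `exp(-lam)` is the probability that a single
#'   opportunity is not sufficiently attractive as a destination.
#' @param theta_exp Positive exponent on the cumulative opportunity count.
#' @return Object of class `intervening_opportunities_params`.
#' @export
intervening_opportunities_params <- function(kappa, lam, theta_exp) {
  .check_finite(kappa = kappa, lam = lam, theta_exp = theta_exp)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (lam <= 0) stop("lam must be > 0", call. = FALSE)
  if (theta_exp <= 0) stop("theta_exp must be > 0", call. = FALSE)
  structure(list(kappa = kappa, lam = lam, theta_exp = theta_exp),
            class = c("intervening_opportunities_params", "model_params"))
}

.check_finite <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("%s must be a single finite number", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# model id for a params object
.params_model_id <- function(params) {
  switch(class(params)[1L],
         gravity_params = "gravity",
         gravity_distance_params = "gravity_distance",
         radiation_params = "radiation",
         radiation_selection_params = "radiation_selection",
         intervening_opportunities_params = "intervening_opportunities",
         stop("not a model_params object", call. = FALSE))
}

#' Gravity flux
#'
#' `theta * m^alpha * n^beta / r^gamma` for one (or elementwise many)
#' origin-destination pairs.  Defined off-diagonal only: with a positive
#' distance exponent the flux is undefined at r = 0 and the caller must route
#' diagonal cells through the self-loop rule (zero).
#'
#' @param params A `gravity_params` object.
#' @param m,n Origin and destination populations (> 0).
#' @param r Distance in km (> 0 when `gamma > 0`).
#' @return Non-negative flux, vectorised over `m`, `n`, `r`.
#' @export
#' @examples
#' gravity_flux(gravity_params(1, 1, 1, 1), 100, 200, 10)  # 2000
gravity_flux <- function(params, m, n, r) {
  stopifnot(inherits(params, "gravity_params"))
  if (params$gamma > 0 && any(r == 0)) {
    stop("gravity flux is undefined at r = 0; self-loops must be zeroed by the caller",
         call. = FALSE)
  }
  params$theta * m^params$alpha * n^params$beta / r^params$gamma
}

#' Gravity flux with a distance cut-off
#'
#' Applies the short-range parameter set where `r <= delta` and the
#' long-range set where `r > delta`.
#'
#' @param params A `gravity_distance_params` object.
#' @inheritParams gravity_flux
#' @return Non-negative flux, vectorised.
#' @export
gravity_distance_flux <- function(params, m, n, r) {
  stopifnot(inherits(params, "gravity_distance_params"))
  short <- gravity_flux(params$short, m, n, r)
  long <- gravity_flux(params$long, m, n, r)
  ifelse(r <= params$delta, short, long)
}

#' Radiation flux
#'
#' `theta * m * n / ((m + s) * (m + n + s))` where `s` is the intervening
#' population between origin and destination.
#'
#' @param params A `radiation_params` object.
#' @param m,n Origin and destination populations (> 0).
#' @param s Intervening population (>= 0).
#' @return Non-negative flux, vectorised.
#' @export
#' @examples
#' radiation_flux(radiation_params(1), 100, 100, 0)  # 0.5
radiation_flux <- function(params, m, n, s) {
  stopifnot(inherits(params, "radiation_params"))
  params$theta * m * n / ((m + s) * (m + n + s))
}

#' Radiation-with-selection flux
#'
#' `theta * (1 - lam^P / P) * (1 - lam^Q / Q) / (1 - lam^R / R)` with P the
#' origin population, Q the destination population and R the total population
#' P + Q + s including the intervening population.  `lam^x` is computed as
#' `exp(x * log(lam))`, which underflows cleanly to 0 for the large
#' populations typical of census regions (where each factor tends to 1).
#'
#' @param params A `radiation_selection_params` object.
#' @param P,Q Origin and destination populations (> 0).
#' @param R Total population P + Q + s (> 0).
#' @return Flux, vectorised.
#' @export
radiation_selection_flux <- function(params, P, Q, R) {
  stopifnot(inherits(params, "radiation_selection_params"))
  loglam <- log(params$lam)
  f <- function(x) 1 - exp(x * loglam) / x
  params$theta * f(P) * f(Q) / f(R)
}

#' Intervening-opportunities (Schneider) flux
#'
#' `kappa * (exp(-lam * (s + m)^theta_exp) - exp(-lam * (s + m + n)^theta_exp))`:
#' the probability that an acceptable destination lies in region j and none
#' was found among the s + m opportunities closer to the origin, scaled to an
#' absolute intensity by `kappa`.
#'
#' @param params An `intervening_opportunities_params` object.
#' @param m Origin population (> 0).
#' @param n Destination population (>= 0).
#' @param s Intervening population (>= 0).
#' @return Non-negative flux, vectorised.
#' @export
#' @examples
#' intervening_opportunities_flux(
#'   intervening_opportunities_params(1, log(2), 1), m = 1, n = 1, s = 0
#' )  # 2^-1 - 2^-2 = 0.25
intervening_opportunities_flux <- function(params, m, n, s) {
  stopifnot(inherits(params, "intervening_opportunities_params"))
  params$kappa * (exp(-params$lam * (s + m)^params$theta_exp) -
                    exp(-params$lam * (s + m + n)^params$theta_exp))
}
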