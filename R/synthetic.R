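#' Describe a synthetic origin-destination scenario
#'
#' A scenario fixes everything needed to generate a reproducible location set
#' and OD flow matrix with the statistical structure the analysis assumes:
#' heterogeneous region populations (log-uniform between `pop_min` and
#' `pop_max`, echoing the 3,000-25,000 band of Australian SA2 census
#' regions), distance-decaying flows from a generating movement model
#' (optionally a convex mixture of two models), independent Poisson noise,
#' zero self-loops, and two sampling regimes: dense census-like integer
#' counts or sparse GPS-like intensities normalised to sum to one.
#'
#' @param n_regions Number of regions (>= 2).
#' @param pop_min,pop_max Population bounds (persons); sampling is
#'   log-uniform so large-population "urban" regions are rare.
#' @param spatial `"uniform"` scatters region centres uniformly over a
#'   square of side `side_km`; `"clustered"` places them Gaussian (sd
#'   `hub_sd_km`) around `n_hubs` hub centres, an urban-heterogeneity
#'   analogue.
#' @param side_km Side of the study square, km.
#' @param n_hubs,hub_sd_km Cluster count and spread for `"clustered"` mode.
#' @param model Generating model id (see [flowstack_models()]).
#' @param params Generating parameters; defaults to
#'   `gravity_params(1, 0.8, 0.6, 1.5)` for the gravity model, required for
#'   all others.
#' @param mixture Optional `list(model =, params =, weight =)` describing a
#'   second component; the expectation becomes
#'   `(1 - weight) * E_primary + weight * E_secondary`, with each component
#'   rescaled to `mean_flow` first so the weight is a genuine proportion.
#' @param mean_flow Optional target mean off-diagonal flow; rescales the
#'   generating expectation (and each mixture component).  Required when
#'   `mixture` is given.
#' @param noise `"poisson"` samples each off-diagonal cell independently;
#'   `"expectation"` returns the noise-free expectation (exact pass-through,
#'   used for closure testing).
#' @param regime `"census_like"` keeps integer-count scale;
#'   `"gps_like"` divides the matrix by its total so it sums to one.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_regions, pop_min = 3000, pop_max = 25000,
                               spatial = c("uniform", "clustered"),
                               side_km = 500, n_hubs = 3, hub_sd_km = 20,
                               model = "gravity", params = NULL,
                               mixture = NULL, mean_flow = NULL,
                               noise = c("poisson", "expectation"),
                               regime = c("census_like", "gps_like"),
                               seed = 1L) {
  spatial <- match.arg(spatial)
  noise <- match.arg(noise)
  regime <- match.arg(regime)
  model <- match.arg(model, flowstack_models())
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("n_regions must be at least 2", call. = FALSE)
  if (pop_min <= 0 || pop_max < pop_min) {
    stop("require 0 < pop_min <= pop_max", call. = FALSE)
  }
  if (is.null(params)) {
    if (model == "gravity") {
      params <- gravity_params(1, 0.8, 0.6, 1.5)
    } else {
      stop("params must be supplied for generating models other than gravity",
           call. = FALSE)
    }
  }
  if (.params_model_id(params) != model) {
    stop("params do not match the generating model", call. = FALSE)
  }
  if (!is.null(mixture)) {
    stopifnot(is.list(mixture),
              all(c("model", "params", "weight") %in% names(mixture)))
    mixture$model <- match.arg(mixture$model, flowstack_models())
    if (.params_model_id(mixture$params) != mixture$model) {
      stop("mixture params do not match the mixture model", call. = FALSE)
    }
    if (mixture$weight < 0 || mixture$weight > 1) {
      stop("mixture weight must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(mean_flow)) {
      stop("mean_flow is required for mixture scenarios so the weight is a true proportion",
           call. = FALSE)
    }
  }
  structure(
    list(n_regions = n_regions, pop_min = pop_min, pop_max = pop_max,
         spatial = spatial, side_km = side_km, n_hubs = as.integer(n_hubs),
         hub_sd_km = hub_sd_km, model = model, params = params,
         mixture = mixture, mean_flow = mean_flow, noise = noise,
         regime = regime, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Generate a seeded synthetic location set
#'
#' Populations are drawn log-uniformly within the scenario's bounds;
#' coordinates are uniform over the study square or Gaussian around hub
#' centres in clustered mode (every hub receives at least one region).
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `location_set` in projected-km coordinates.
#' @export
generate_locations <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_regions
  ids <- sprintf("r%04d", seq_len(n))
  if (scenario$spatial == "uniform") {
    coords <- cbind(stats::runif(n, 0, scenario$side_km),
                    stats::runif(n, 0, scenario$side_km))
  } else {
    hubs <- cbind(stats::runif(scenario$n_hubs, 0, scenario$side_km),
                  stats::runif(scenario$n_hubs, 0, scenario$side_km))
    assign <- c(seq_len(scenario$n_hubs),
                sample(scenario$n_hubs, max(n - scenario$n_hubs, 0L),
                       replace = TRUE))[seq_len(n)]
    coords <- hubs[assign, , drop = FALSE] +
      matrix(stats::rnorm(2L * n, sd = scenario$hub_sd_km), n, 2L)
  }
  pops <- exp(stats::runif(n, log(scenario$pop_min), log(scenario$pop_max)))
  location_set(ids, coords, pops, coord_mode = "projected_km")
}

# Noise-free expectation matrix of a scenario (mixture-aware, rescaled to
# mean_flow when requested).
.expectation_matrix <- function(scenario, locs, geom) {
  cells <- .offdiag_cells(geom$n)
  scale_component <- function(E) {
    if (is.null(scenario$mean_flow)) return(E)
    m <- mean(E[cells])
    if (m <= 0) stop("generating expectation is identically zero", call. = FALSE)
    E * (scenario$mean_flow / m)
  }
  E <- scale_component(predict_matrix(scenario$model, scenario$params, locs,
                                      geom))
  if (!is.null(scenario$mixture)) {
    E2 <- scale_component(predict_matrix(scenario$mixture$model,
                                         scenario$mixture$params, locs, geom))
    w <- scenario$mixture$weight
    E <- (1 - w) * E + w * E2
  }
  E
}

#' Generate a synthetic OD flow matrix for a scenario
#'
#' Builds the generating model's expectation matrix (a convex mixture when
#' the scenario has one), then applies the scenario's noise and sampling
#' regime.  `noise = "expectation"` returns the expectation exactly;
#' `noise = "poisson"` samples each off-diagonal cell independently, giving
#' integer counts (the census-like regime).  `regime = "gps_like"` finally
#' divides the matrix by its total, emulating normalised contact
#' intensities.  The diagonal is always zero, and the expectation used is
#' attached as attribute `"expectation"`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param locs Location set from [generate_locations()] (or compatible).
#' @param geom Matching [pairwise_geometry()].
#' @return Square flow matrix with zero diagonal.
#' @export
generate_flows <- function(scenario, locs, geom) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(locs, "location_set"),
            inherits(geom, "pairwise_geometry"))
  E <- .expectation_matrix(scenario, locs, geom)
  cells <- .offdiag_cells(geom$n)
  if (scenario$noise == "poisson" && any(E[cells] > 1e9)) {
    stop("expected flows exceed 1e9; reduce the generating scale (theta/kappa) or mean_flow",
         call. = FALSE)
  }
  out <- matrix(0, geom$n, geom$n)
  if (scenario$noise == "expectation") {
    out[cells] <- E[cells]
  } else {
    set.seed(scenario$seed + 1L)
    out[cells] <- stats::rpois(length(cells), E[cells])
  }
  if (scenario$regime == "gps_like") {
    tot <- sum(out)
    if (tot <= 0) stop("generated matrix is all zero; cannot normalise",
                       call. = FALSE)
    out <- out / tot
  }
  dimnames(out) <- list(locs$ids, locs$ids)
  attr(out, "expectation") <- E
  out
}
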