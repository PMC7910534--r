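#' Construct a set of regions with coordinates and populations
#'
#' A `location_set` holds the point population centres the movement models
#' operate on: unique region ids, one coordinate pair per region, and a
#' strictly positive population (persons).  Coordinates are either projected
#' x/y in kilometres (`"projected_km"`) or lon/lat in decimal degrees
#' (`"lonlat_degrees"`).
#'
#' @param ids Vector of unique region identifiers (coerced to character).
#' @param coords Two-column matrix (or coercible) of coordinates, one row per
#'   region: x/y km in projected mode, lon/lat degrees in lonlat mode.
#' @param populations Numeric vector of strictly positive population sizes.
#' @param coord_mode `"projected_km"` or `"lonlat_degrees"`.
#' @return An object of class `location_set`.
#' @export
#' @examples
#' location_set(c("a", "b"), rbind(c(0, 0), c(3, 4)), c(100, 200))
location_set <- function(ids, coords, populations,
                         coord_mode = c("projected_km", "lonlat_degrees")) {
  coord_mode <- match.arg(coord_mode)
  ids <- as.character(ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  populations <- as.numeric(populations)
  if (length(ids) < 1L) {
    stop("at least one region is required", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("region ids must be unique", call. = FALSE)
  }
  if (nrow(coords) != length(ids) || ncol(coords) != 2L) {
    stop("coords must have one row per region and exactly two columns",
         call. = FALSE)
  }
  if (length(populations) != length(ids)) {
    stop("populations must have one entry per region", call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(!is.finite(populations)) || any(populations <= 0)) {
    stop("populations must be finite and strictly positive", call. = FALSE)
  }
  if (coord_mode == "lonlat_degrees") {
    if (any(coords[, 1L] < -180 | coords[, 1L] > 180) ||
        any(coords[, 2L] < -90 | coords[, 2L] > 90)) {
      stop("lonlat coordinates must lie in [-180, 180] x [-90, 90]",
           call. = FALSE)
    }
  }
  rownames(coords) <- ids
  structure(
    list(ids = ids, coords = coords, populations = populations,
         coord_mode = coord_mode),
    class = "location_set"
  )
}

#' Number of regions in a location set
#' @param locs A `location_set`.
#' @return Integer count of regions.
#' @export
n_regions <- function(locs) {
  stopifnot(inherits(locs, "location_set"))
  length(locs$ids)
}

#' @export
print.location_set <- function(x, ...) {
  cat(sprintf("<location_set: %d regions, %s coordinates>\n",
              length(x$ids), x$coord_mode))
  cat(sprintf("  populations: %.0f - %.0f (total %.0f)\n",
              min(x$populations), max(x$populations), sum(x$populations)))
  invisible(x)
}

#' Pairwise distance matrix between region centres
#'
#' Euclidean distance on projected kilometre coordinates; great-circle
#' (haversine) distance with Earth radius 6371 km on lon/lat coordinates.
#'
#' @param locs A `location_set`.
#' @return Symmetric, zero-diagonal matrix of distances in kilometres with
#'   region ids as dimnames.
#' @export
#' @examples
#' locs <- location_set(c("a", "b"), rbind(c(0, 0), c(3, 4)), c(1, 1))
#' pairwise_distances(locs)  # 5 km apart
pairwise_distances <- function(locs) {
  stopifnot(inherits(locs, "location_set"))
  if (locs$coord_mode == "projected_km") {
    d <- as.matrix(stats::dist(locs$coords))
  } else {
    d <- geosphere::distm(
      locs$coords,
      fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371)
    )
  }
  d <- (d + t(d)) / 2      # enforce exact symmetry
  diag(d) <- 0
  dimnames(d) <- list(locs$ids, locs$ids)
  d
}

#' Intervening population matrix s_ij
#'
#' For each ordered pair (i, j), the total population of all regions k lying
#' strictly closer to the origin i than the destination j is, i.e. within the
#' open disc centred at i of radius r_ij, excluding both i and j themselves.
#' Regions at exactly distance r_ij from the origin do not count.  This is
#' the opportunity count consumed by the radiation and intervening
#' opportunities models.
#'
#' @param locs A `location_set`.
#' @param distances Distance matrix from [pairwise_distances()] on the same
#'   location set.
#' @return Square matrix of intervening populations (persons), zero diagonal.
#' @export
intervening_population <- function(locs, distances) {
  stopifnot(inherits(locs, "location_set"))
  n <- length(locs$ids)
  distances <- as.matrix(distances)
  if (!all(dim(distances) == c(n, n))) {
    stop("distance matrix shape does not match the location set",
         call. = FALSE)
  }
  pop <- locs$populations
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dr <- distances[i, ]
    ord <- order(dr)
    srt <- dr[ord]
    csum <- c(0, cumsum(pop[ord]))
    # count of regions strictly closer to i than each destination
    cnt <- findInterval(dr, srt, left.open = TRUE)
    row <- csum[cnt + 1L] - pop[i]  # i itself (distance 0) is always counted
    row[i] <- 0
    s[i, ] <- row
  }
  dimnames(s) <- dimnames(distances)
  s
}

#' Bundle distances and intervening populations for a location set
#'
#' @param locs A `location_set`.
#' @param distances Optional precomputed distance matrix; computed with
#'   [pairwise_distances()] when `NULL`.
#' @param intervening Optional precomputed intervening-population matrix;
#'   computed with [intervening_population()] when `NULL`.
#' @return An object of class `pairwise_geometry` with elements `distances`,
#'   `intervening` and `n`.
#' @export
#' @examples
#' locs <- location_set(letters[1:3], cbind(c(0, 5, 10), 0), c(10, 20, 30))
#' geom <- pairwise_geometry(locs)
#' geom$intervening["a", "c"]  # population of b intervenes
pairwise_geometry <- function(locs, distances = NULL, intervening = NULL) {
  stopifnot(inherits(locs, "location_set"))
  if (is.null(distances)) distances <- pairwise_distances(locs)
  if (is.null(intervening)) {
    intervening <- intervening_population(locs, distances)
  }
  n <- length(locs$ids)
  if (!all(dim(intervening) == c(n, n))) {
    stop("intervening matrix shape does not match the location set",
         call. = FALSE)
  }
  structure(
    list(distances = distances, intervening = intervening, n = n),
    class = "pairwise_geometry"
  )
}

#' @export
print.pairwise_geometry <- function(x, ...) {
  cat(sprintf("<pairwise_geometry: %d regions, distances %.1f - %.1f km>\n",
              x$n, min(x$distances[upper.tri(x$distances)]),
              max(x$distances)))
  invisible(x)
}
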