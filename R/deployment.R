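#' Construct a set of receiver stations
#'
#' @param positions A matrix or data frame with two columns (x, y); may have
#'   zero rows for an empty deployment.
#' @param radius Reception radius r (> 0), shared by all stations.
#' @param mobile Logical; whether the stations perform a random walk.
#' @param station_speed Step length of mobile stations (ignored when static).
#' @return An object of class `station_set`.
#' @export
station_set <- function(positions, radius, mobile = FALSE, station_speed = 0) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L) positions <- matrix(numeric(0), ncol = 2L)
  if (ncol(positions) != 2L)
    stop("`positions` must have two columns (x, y)", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number", call. = FALSE)
  if (mobile && (!is.numeric(station_speed) || station_speed < 0))
    stop("`station_speed` must be non-negative", call. = FALSE)
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions, radius = radius,
                 mobile = isTRUE(mobile), station_speed = station_speed),
            class = "station_set")
}

#' @export
print.station_set <- function(x, ...) {
  cat(sprintf("%d receiver station(s), r = %g%s\n", nrow(x$positions),
              x$radius,
              if (x$mobile) sprintf(", mobile (speed %g)", x$station_speed)
              else ", static"))
  invisible(x)
}

#' Place stations uniformly at random in the unit square
#'
#' @param x Number of stations (>= 0).
#' @param radius Reception radius r.
#' @param seed Optional seed (see [init_population()]).
#' @inheritParams station_set
#' @return A `station_set`.
#' @export
place_random <- function(x, radius, seed = NULL, mobile = FALSE,
                         station_speed = 0) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x != round(x))
    stop("station count `x` must be a non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x)
  station_set(cbind(runif(x), runif(x)), radius = radius, mobile = mobile,
              station_speed = station_speed)
}

#' Place stations at animal homes
#'
#' Places `min(x, n_homes)` stations exactly at a uniformly-sampled subset of
#' distinct homes (no more than one station per home); any excess stations
#' beyond the number of homes are placed uniformly at random in the unit
#' square.
#'
#' @param homes Matrix of home coordinates (one row per animal), e.g.
#'   `state$homes` from [init_population()].
#' @inheritParams place_random
#' @return A `station_set`.
#' @export
place_at_homes <- function(homes, x, radius, seed = NULL) {
  homes <- as.matrix(homes)
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x != round(x))
    stop("station count `x` must be a non-negative integer", call. = FALSE)
  if (nrow(homes) == 0L && x > 0)
    stop("cannot place stations at homes: no homes given", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x)
  k <- min(x, nrow(homes))
  pos <- homes[sample(nrow(homes), k), , drop = FALSE]
  if (x > k) pos <- rbind(pos, cbind(runif(x - k), runif(x - k)))
  station_set(pos, radius = radius)
}

#' Advance mobile stations by one step
#'
#' Each station is displaced by `station_speed` along an independent uniform
#' random direction (the a = 0 limit of the movement law applied to
#' stations). Stations are not reflected at the square's boundary.
#'
#' @param stations A mobile `station_set`.
#' @return The displaced `station_set`.
#' @export
step_mobile <- function(stations) {
  stopifnot(inherits(stations, "station_set"))
  if (!stations$mobile)
    stop("`step_mobile()` called on a static station set", call. = FALSE)
  n <- nrow(stations$positions)
  theta <- 2 * pi * runif(n)
  stations$positions <- stations$positions +
    stations$station_speed * cbind(cos(theta), sin(theta))
  stations
}

#' Expected covered fraction of the arena
#'
#' For x independently, uniformly placed discs of radius r in an arena of
#' area A, the expected fraction of the arena covered by at least one disc is
#' \deqn{f = 1 - (1 - p)^x, \qquad p = \pi r^2 / A.}
#' This is also the analytic transfer function in the static limit
#' (a = 1, v << r).
#'
#' @param r Reception radius (> 0).
#' @param A Arena area (> 0); 1 for the model's unit square.
#' @param x Station count (>= 0).
#' @return An object of class `coverage_summary`: list with `p` (single-disc
#'   probability), `f` (expected covered fraction), `total_area` (x * pi r^2,
#'   overlaps not subtracted) and `A`.
#' @export
covered_fraction <- function(r, A = 1, x) {
  if (!is.numeric(r) || r <= 0 || !is.numeric(A) || A <= 0)
    stop("`r` and `A` must be positive", call. = FALSE)
  if (!is.numeric(x) || any(x < 0))
    stop("station count `x` must be non-negative", call. = FALSE)
  p <- pi * r^2 / A
  if (p > 1)
    stop("reception radius too large for the arena (pi r^2 > A)", call. = FALSE)
  structure(list(p = p, f = 1 - (1 - p)^x, total_area = x * pi * r^2, A = A),
            class = "coverage_summary")
}

#' Total reception area of a deployment
#'
#' Sum of the disc areas, `x * pi * r^2`, with overlaps *not* subtracted.
#' This is the covered-area convention used as the x-axis of the
#' transfer-versus-area curves (e.g. 10 stations of radius 50 km give
#' 78,539.8 km^2).
#'
#' @param x Station count (>= 0).
#' @param r Reception radius (> 0), in the same length units as desired for
#'   the squared-area result.
#' @return Numeric area.
#' @export
total_reception_area <- function(x, r) {
  if (!is.numeric(x) || any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  if (!is.numeric(r) || any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  x * pi * r^2
}
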