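#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' recycled to a common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distances in km.
#' @examples
#' haversine_km(0, 0, 0, 180)  # half circumference, ~20015 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)", call. = FALSE)
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = 6371))
}

EARTH_KM_PER_DEG <- 111.195  # 6371 km * pi / 180

#' Read and validate geographic tracks
#'
#' Expects a CSV with header `animal_id,timestamp,lat,lon` (ISO-8601
#' timestamps). Latitude must lie in \[-90, 90\], longitude in \[-180, 180\],
#' and timestamps must be non-decreasing within each animal.
#'
#' @param file Path to the CSV file.
#' @return A data frame of class `geotracks`.
#' @export
read_geotracks <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  as_geotracks(df)
}

#' Coerce a data frame to validated geographic tracks
#'
#' @param df Data frame with columns `animal_id`, `timestamp`, `lat`, `lon`.
#' @return A data frame of class `geotracks`.
#' @export
as_geotracks <- function(df) {
  need <- c("animal_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("tracks need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("coordinates out of range", call. = FALSE)
  ord <- order(df$animal_id, df$timestamp)
  if (is.unsorted(ord, strictly = FALSE)) df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("geotracks", "data.frame")
  df
}

#' Write geographic tracks to CSV
#'
#' @param tracks A `geotracks` data frame.
#' @param file Output path.
#' @export
write_geotracks <- function(tracks, file) {
  write.csv(as.data.frame(tracks)[, c("animal_id", "timestamp", "lat", "lon")],
            file, row.names = FALSE)
}

#' Construct a geographic station set
#'
#' @param positions Data frame or matrix with columns `lat`, `lon`.
#' @param radius_km Reception radius in km (> 0).
#' @return An object of class `geo_station_set`.
#' @export
geo_station_set <- function(positions, radius_km) {
  positions <- as.data.frame(positions)
  if (nrow(positions) > 0 && !all(c("lat", "lon") %in% names(positions))) {
    names(positions) <- c("lat", "lon")
  }
  if (nrow(positions) == 0L)
    positions <- data.frame(lat = numeric(0), lon = numeric(0))
  if (!is.numeric(radius_km) || radius_km <= 0)
    stop("`radius_km` must be positive", call. = FALSE)
  structure(list(positions = positions[, c("lat", "lon")],
                 radius_km = radius_km),
            class = "geo_station_set")
}

track_bbox <- function(tracks) {
  bb <- c(lat_min = min(tracks$lat), lat_max = max(tracks$lat),
          lon_min = min(tracks$lon), lon_max = max(tracks$lon))
  if (bb["lat_min"] == bb["lat_max"] || bb["lon_min"] == bb["lon_max"])
    stop("degenerate track bounding box: cannot place stations", call. = FALSE)
  bb
}

#' Place geographic stations uniformly in the track bounding box
#'
#' @param tracks A `geotracks` data frame.
#' @param x Number of stations (>= 0).
#' @param radius_km Reception radius in km.
#' @param seed Optional seed.
#' @return A `geo_station_set`.
#' @export
place_geo_random <- function(tracks, x, radius_km, seed = NULL) {
  if (!is.numeric(x) || x < 0 || x != round(x))
    stop("station count `x` must be a non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x)
  if (x == 0L) return(geo_station_set(NULL, radius_km))
  bb <- track_bbox(tracks)
  geo_station_set(data.frame(
    lat = runif(x, bb["lat_min"], bb["lat_max"]),
    lon = runif(x, bb["lon_min"], bb["lon_max"])), radius_km)
}

#' Place geographic stations at animal homes
#'
#' The home of a real track is taken as the animal's first recorded fix
#' (central-place foragers start from their colony / haul-out). Stations
#' are placed at the first fixes of a uniformly sampled subset of at most
#' `x` animals; any excess stations are placed uniformly in the bounding
#' box.
#'
#' @inheritParams place_geo_random
#' @return A `geo_station_set`.
#' @export
place_geo_at_homes <- function(tracks, x, radius_km, seed = NULL) {
  if (!is.numeric(x) || x < 0 || x != round(x))
    stop("station count `x` must be a non-negative integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x)
  if (x == 0L) return(geo_station_set(NULL, radius_km))
  firsts <- do.call(rbind, lapply(split(tracks, tracks$animal_id),
                                  function(d) d[1L, c("lat", "lon")]))
  k <- min(x, nrow(firsts))
  pos <- firsts[sample(nrow(firsts), k), , drop = FALSE]
  if (x > k) {
    bb <- track_bbox(tracks)
    pos <- rbind(pos, data.frame(
      lat = runif(x - k, bb["lat_min"], bb["lat_max"]),
      lon = runif(x - k, bb["lon_min"], bb["lon_max"])))
  }
  geo_station_set(pos, radius_km)
}

#' Run the transmission model on geographic tracks
#'
#' Each recorded fix generates one package; a fix whose Haversine distance
#' to any station is strictly below the reception radius flushes the
#' animal's whole buffer as a single event. The transfer function is total
#' transmitted packages over total recorded fixes.
#'
#' @param tracks A `geotracks` data frame.
#' @param stations A `geo_station_set`.
#' @return An object of class `geo_run_result`: list with `T_mean`,
#'   per-animal `transmitted`, `stored`, `generated`, and `events`
#'   (`animal_id`, `time` = fix index within the track, `size`).
#' @export
run_geo <- function(tracks, stations) {
  stopifnot(inherits(stations, "geo_station_set"))
  tracks <- as_geotracks(as.data.frame(tracks))
  per <- split(tracks, tracks$animal_id)
  ids <- names(per)
  r <- stations$radius_km
  st <- stations$positions
  ev_list <- list()
  transmitted <- stored <- generated <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    d <- per[[id]]
    n <- nrow(d)
    if (n == 0L) {
      warning("skipping empty track for animal ", id, call. = FALSE)
      next
    }
    inrange <- rep(FALSE, n)
    if (nrow(st) > 0L) {
      for (j in seq_len(nrow(st))) {
        inrange <- inrange |
          haversine_km(d$lat, d$lon, st$lat[j], st$lon[j]) < r
        if (all(inrange)) break
      }
    }
    idx <- which(inrange)
    generated[id] <- n
    if (length(idx) > 0L) {
      sizes <- diff(c(0L, idx))
      transmitted[id] <- idx[length(idx)]
      stored[id] <- n - idx[length(idx)]
      ev_list[[id]] <- data.frame(animal_id = id, time = idx, size = sizes)
    } else {
      stored[id] <- n
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(animal_id = character(0), time = integer(0), size = integer(0))
  rownames(events) <- NULL
  structure(list(
    T_mean = sum(transmitted) / sum(generated),
    transmitted = transmitted, stored = stored, generated = generated,
    events = events, stations = stations),
    class = "geo_run_result")
}

#' Transfer versus covered area for geographic tracks
#'
#' Sweeps station counts over a set of geographic tracks, placing stations
#' afresh per realization, and fits the saturating-exponential transfer law
#' against the covered area in km^2 (x pi r^2, overlaps not subtracted).
#'
#' @param tracks A `geotracks` data frame.
#' @param counts Station counts to sweep.
#' @param radius_km Reception radius in km.
#' @param n_realizations Station placements averaged per count.
#' @param base_seed Integer seed.
#' @param strategy `"random"` or `"at_home"`.
#' @return A list with `sweep` (class `sweep_result`; `covered_area` in
#'   km^2) and `fit` (a `fit_result`, or `NULL` if the fit failed, with the
#'   error under `fit_error`).
#' @export
transfer_vs_area_geo <- function(tracks, counts, radius_km,
                                 n_realizations = 10, base_seed = 1,
                                 strategy = c("random", "at_home")) {
  strategy <- match.arg(strategy)
  if (length(counts) == 0L) stop("`counts` must be non-empty", call. = FALSE)
  Tmat <- matrix(NA_real_, nrow = length(counts), ncol = n_realizations)
  for (i in seq_along(counts)) {
    for (k in seq_len(n_realizations)) {
      seed <- base_seed + (i - 1L) * n_realizations + (k - 1L)
      st <- switch(strategy,
        random = place_geo_random(tracks, counts[i], radius_km, seed = seed),
        at_home = place_geo_at_homes(tracks, counts[i], radius_km,
                                     seed = seed))
      Tmat[i, k] <- run_geo(tracks, st)$T_mean
    }
  }
  sweep <- data.frame(
    n_stations = counts,
    covered_area = total_reception_area(counts, radius_km),
    r = radius_km, strategy = strategy, n_realizations = n_realizations,
    T_mean = rowMeans(Tmat), T_sd = apply(Tmat, 1L, sd),
    T_se = apply(Tmat, 1L, sd) / sqrt(n_realizations))
  attr(sweep, "realizations") <- Tmat
  class(sweep) <- c("sweep_result", "data.frame")
  fit <- tryCatch(fit_transfer_vs_area(sweep), error = function(e) e)
  if (inherits(fit, "error"))
    list(sweep = sweep, fit = NULL, fit_error = fit)
  else
    list(sweep = sweep, fit = fit)
}

#' Generate synthetic central-place geographic tracks
#'
#' Applies the central-place movement law in a local tangent plane (km)
#' around each animal's home and converts the displacements to
#' latitude/longitude (1 degree latitude = 111.195 km; longitude scaled by
#' cos(home latitude)). The two named regimes emulate a weakly
#' home-attracted wide-ranging species (long excursions, as for southern
#' elephant seals) and a strongly home-attracted coastal one (fixes within
#' roughly `step_km / a` of the colony, as for Australian sea lions).
#'
#' @param regime `"weak"` (a = 0.005) or `"strong"` (a = 0.1); ignored when
#'   `a` is given.
#' @param a Optional explicit home attraction.
#' @param n_animals Number of animals.
#' @param n_steps Fixes per animal after the first.
#' @param step_km Step scale v in km per fix.
#' @param home_lat,home_lon Colony coordinates; animals' homes are
#'   scattered within `home_spread_deg` degrees of this point.
#' @param home_spread_deg Half-width of the home scatter, degrees.
#' @param seed Optional seed.
#' @param start_time Timestamp of the first fix (fixes are hourly).
#' @return A `geotracks` data frame (synthetic), with the per-animal home
#'   coordinates attached as attribute `"homes"`.
#' @export
generate_synthetic_geotracks <- function(regime = c("weak", "strong"),
                                         a = NULL, n_animals = 10,
                                         n_steps = 500, step_km = 5,
                                         home_lat = -35, home_lon = 135,
                                         home_spread_deg = 0.5, seed = NULL,
                                         start_time = "2010-01-01T00:00:00Z") {
  regime <- match.arg(regime)
  if (is.null(a)) a <- switch(regime, weak = 0.005, strong = 0.1)
  if (a < 0 || a > 1) stop("`a` must be in [0, 1]", call. = FALSE)
  if (step_km <= 0) stop("`step_km` must be positive", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (abs(home_lat) + home_spread_deg >= 89)
    stop("homes too close to the pole for the tangent-plane mapping",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t0 <- as.POSIXct(start_time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  stamps <- format(t0 + 3600 * (0:n_steps), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  homes <- data.frame(
    animal_id = sprintf("synth%02d", seq_len(n_animals)),
    lat = home_lat + runif(n_animals, -home_spread_deg, home_spread_deg),
    lon = home_lon + runif(n_animals, -home_spread_deg, home_spread_deg))
  out <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    # tangent-plane walk in km around (0, 0) = home
    xy <- matrix(0, nrow = n_steps + 1L, ncol = 2L)
    for (t in seq_len(n_steps)) {
      th <- 2 * pi * runif(1)
      xy[t + 1L, ] <- xy[t, ] + step_km * c(cos(th), sin(th)) - a * xy[t, ]
    }
    lat <- homes$lat[i] + xy[, 2L] / EARTH_KM_PER_DEG
    lon <- homes$lon[i] +
      xy[, 1L] / (EARTH_KM_PER_DEG * cos(homes$lat[i] * pi / 180))
    out[[i]] <- data.frame(animal_id = homes$animal_id[i],
                           timestamp = stamps, lat = lat, lon = lon)
  }
  tracks <- as_geotracks(do.call(rbind, out))
  attr(tracks, "homes") <- homes
  tracks
}

#' @importFrom stats setNames
NULL
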