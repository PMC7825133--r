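# Independent reference implementations used as oracles. These deliberately
# stay naive (brute force, plain loops) and must not call the code paths
# they check.

# Pure-R reference of the coupled engine: same event order (move ->
# [mobile stations] -> generate -> detect/flush), brute-force distance scan,
# one uniform angle per animal then per mobile station, drawn from the
# current RNG stream.
reference_engine <- function(movement, stations, n_steps, seed) {
  set.seed(seed)
  n <- movement$n_animals
  homes <- cbind(runif(n), runif(n))
  pos <- homes
  st <- stations$positions
  stored <- integer(n)
  transmitted <- numeric(n)
  ev <- list()
  for (t in seq_len(n_steps)) {
    th <- 2 * pi * runif(n)
    pos <- pos + movement$v * cbind(cos(th), sin(th)) -
      movement$a * (pos - homes)
    if (stations$mobile && nrow(st) > 0) {
      ths <- 2 * pi * runif(nrow(st))
      st <- st + stations$station_speed * cbind(cos(ths), sin(ths))
    }
    for (i in seq_len(n)) {
      stored[i] <- stored[i] + 1L
      inr <- FALSE
      if (nrow(st) > 0) {
        d2 <- (pos[i, 1] - st[, 1])^2 + (pos[i, 2] - st[, 2])^2
        inr <- any(d2 <= stations$radius^2)
      }
      if (inr) {
        transmitted[i] <- transmitted[i] + stored[i]
        ev[[length(ev) + 1L]] <- c(i, t, stored[i])
        stored[i] <- 0L
      }
    }
  }
  events <- if (length(ev)) {
    m <- do.call(rbind, ev)
    data.frame(animal_id = m[, 1], time = m[, 2], size = m[, 3])
  } else data.frame(animal_id = integer(0), time = integer(0),
                    size = integer(0))
  list(T_mean = sum(transmitted) / (n * n_steps),
       transmitted = transmitted, stored = stored, events = events)
}

# Rasterized-grid estimate of the fraction of the unit square covered by
# the union of reception discs.
grid_coverage <- function(stations, r, n_grid = 100) {
  g <- (seq_len(n_grid) - 0.5) / n_grid
  pts <- expand.grid(x = g, y = g)
  covered <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(stations))) {
    covered <- covered |
      ((pts$x - stations[j, 1])^2 + (pts$y - stations[j, 2])^2 <= r^2)
  }
  mean(covered)
}

# Textbook haversine on a 6371-km sphere, written out explicitly.
haversine_formula <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  h <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h)))
}
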