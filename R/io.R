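#' Write simulated trajectories to CSV
#'
#' One row per animal per time point, header `animal_id,t,x,y`.
#'
#' @param trajectory Data frame from [simulate_trajectory()].
#' @param file Output path.
#' @export
write_trajectory <- function(trajectory, file) {
  write.csv(as.data.frame(trajectory)[, c("animal_id", "t", "x", "y")],
            file, row.names = FALSE)
}

#' Read trajectories written by [write_trajectory()]
#' @param file CSV path.
#' @return Data frame with columns `animal_id`, `t`, `x`, `y`.
#' @export
read_trajectory <- function(file) {
  df <- read.csv(file)
  stopifnot(all(c("animal_id", "t", "x", "y") %in% names(df)))
  df
}

#' Write a station set to CSV (`station_id,x,y`)
#' @param stations A `station_set`.
#' @param file Output path.
#' @export
write_stations <- function(stations, file) {
  stopifnot(inherits(stations, "station_set"))
  df <- data.frame(station_id = seq_len(nrow(stations$positions)),
                   x = stations$positions[, 1L],
                   y = stations$positions[, 2L])
  write.csv(df, file, row.names = FALSE)
}

#' Read a station set from CSV (`station_id,x,y`)
#' @param file CSV path.
#' @inheritParams station_set
#' @return A `station_set`.
#' @export
read_stations <- function(file, radius, mobile = FALSE, station_speed = 0) {
  df <- read.csv(file)
  stopifnot(all(c("x", "y") %in% names(df)))
  station_set(cbind(df$x, df$y), radius = radius, mobile = mobile,
              station_speed = station_speed)
}

#' Write transmission events to CSV (`animal_id,event_time,event_size`)
#' @param run A `run_result` or `geo_run_result`.
#' @param file Output path.
#' @export
write_events <- function(run, file) {
  ev <- run$events
  write.csv(data.frame(animal_id = ev$animal_id, event_time = ev$time,
                       event_size = ev$size),
            file, row.names = FALSE)
}
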