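#' Run the coupled movement/transmission simulation
#'
#' Per time step: (1) every animal takes one step of the central-place
#' update; (2) mobile stations, if any, move; (3) every sensor generates one
#' data package; (4) every animal within Euclidean distance <= r of any
#' station flushes its entire buffer (including the package generated this
#' step) as a single transmission event. An animal in range of several
#' stations flushes once. The transfer function is
#' \eqn{\langle T\rangle = \mathrm{total\ transmitted} / (N \cdot
#' \mathrm{n\_steps})}.
#'
#' @param movement A [movement_params()] object.
#' @param stations A [station_set()].
#' @param n_steps Number of time steps (>= 1).
#' @param seed Optional seed applied before initialisation; when `NULL` the
#'   current RNG stream is used.
#' @param state Optional pre-initialised `animal_state` (e.g. when stations
#'   were placed at the population's homes); when `NULL` a fresh population
#'   is drawn.
#' @param log_events Keep the per-event log (animal, time, size)? Disable
#'   for large sweeps where only `T_mean` is needed.
#' @return An object of class `run_result`: list with `T_mean`, per-animal
#'   `transmitted`, `stored` and `generated` counts, the event log `events`
#'   (data frame `animal_id`, `time`, `size`), `final_positions`,
#'   `final_stations`, and the echoed parameters.
#' @examples
#' mp <- movement_params(a = 0.01, v = 0.001, n_animals = 20)
#' st <- place_random(30, radius = 0.05, seed = 1)
#' run_simulation(mp, st, n_steps = 200, seed = 2)$T_mean
#' @export
run_simulation <- function(movement, stations, n_steps, seed = NULL,
                           state = NULL, log_events = TRUE) {
  stopifnot(inherits(movement, "movement_params"),
            inherits(stations, "station_set"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("`n_steps` must be >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- init_population(movement)
  stopifnot(inherits(state, "animal_state"),
            nrow(state$positions) == movement$n_animals)

  res <- engine_run_cpp(
    state$positions[, 1L], state$positions[, 2L],
    state$homes[, 1L], state$homes[, 2L],
    movement$a, movement$v,
    stations$positions[, 1L], stations$positions[, 2L],
    stations$radius, stations$mobile, stations$station_speed,
    n_steps, log_events)

  events <- data.frame(animal_id = res$ev_animal, time = res$ev_time,
                       size = res$ev_size)
  structure(list(
    T_mean = res$T_mean,
    transmitted = res$transmitted,
    stored = res$stored,
    generated = rep(n_steps, movement$n_animals),
    events = events,
    final_positions = cbind(x = res$final_x, y = res$final_y),
    final_stations = cbind(x = res$station_x, y = res$station_y),
    homes = state$homes,
    movement = movement, stations = stations, n_steps = n_steps),
    class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "Simulation run: N = %d, %d steps, %d station(s) -> <T> = %.4f (%d events)\n",
    x$movement$n_animals, x$n_steps, nrow(x$stations$positions),
    x$T_mean, nrow(x$events)))
  invisible(x)
}

#' Analytic transfer function in the static limit
#'
#' For a = 1 and v << r the animals are effectively static on the circle of
#' radius v about their (uniformly placed) homes, so the expected transfer
#' function equals the expected covered fraction of the arena,
#' \eqn{f = 1 - (1 - \pi r^2)^x} for the unit square.
#'
#' @param movement A [movement_params()] object; must have `a == 1`. A
#'   warning is issued when `v >= r` (the static approximation breaks down).
#' @param stations A [station_set()] (only the count and radius are used).
#' @return The predicted mean transfer `f`.
#' @export
transfer_static_limit <- function(movement, stations) {
  stopifnot(inherits(movement, "movement_params"),
            inherits(stations, "station_set"))
  if (movement$a != 1)
    stop("the static-limit prediction requires a = 1", call. = FALSE)
  if (movement$v >= stations$radius)
    warning("v >= r: the static approximation is not valid", call. = FALSE)
  covered_fraction(stations$radius, A = 1, x = nrow(stations$positions))$f
}
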