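#' Movement parameters for the central-place model
#'
#' Bundles the parameters of the discrete-time equation of motion
#' \eqn{x_i(t+1) = x_i(t) + v\,\nu(t) - a\,(x_i(t) - x_{h_i})}.
#' Space is normalised so the deployment square is 1x1; `v` is in space units
#' per time step. `a = 0` gives a pure random walk; `a = 1` pins every
#' post-step position onto the circle of radius `v` about the home.
#'
#' @param a Home-attraction constant, in \[0, 1\].
#' @param v Step speed (space units per time step), non-negative.
#' @param n_animals Number of animals N (positive integer).
#' @return An object of class `movement_params`.
#' @examples
#' movement_params(a = 0.001, v = 0.001, n_animals = 500)
#' @export
movement_params <- function(a, v, n_animals) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stop("`a` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
    stop("`v` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n_animals) || length(n_animals) != 1L || is.na(n_animals) ||
      n_animals < 1 || n_animals != round(n_animals))
    stop("`n_animals` must be a positive integer", call. = FALSE)
  structure(list(a = a, v = v, n_animals = as.integer(n_animals)),
            class = "movement_params")
}

#' @export
print.movement_params <- function(x, ...) {
  cat(sprintf("Central-place movement: a = %g, v = %g, N = %d animals\n",
              x$a, x$v, x$n_animals))
  invisible(x)
}

#' Initialise a population of animals
#'
#' Homes are drawn i.i.d. uniform on the unit square and every animal starts
#' at its home (so the `a = 1` static limit holds exactly from t = 0).
#'
#' @param params A [movement_params()] object.
#' @param seed Optional integer seed; when given, `set.seed(seed)` is called
#'   first. When `NULL` the current RNG stream is used.
#' @return An object of class `animal_state`: a list with `positions` and
#'   `homes` (N x 2 matrices with columns `x`, `y`) and integer `time`.
#' @export
init_population <- function(params, seed = NULL) {
  stopifnot(inherits(params, "movement_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_animals
  homes <- cbind(x = runif(n), y = runif(n))
  structure(list(positions = homes, homes = homes, time = 0L),
            class = "animal_state")
}

#' Advance a population by one time step
#'
#' Applies the central-place update to every animal with one independent
#' random direction each (angles uniform on \[0, 2pi)), consuming the current
#' RNG stream. Homes are immutable.
#'
#' @param state An `animal_state`.
#' @param params The [movement_params()] used for the run.
#' @return The updated `animal_state` with `time` incremented.
#' @export
step_population <- function(state, params) {
  stopifnot(inherits(state, "animal_state"), inherits(params, "movement_params"))
  n <- nrow(state$positions)
  theta <- 2 * pi * runif(n)
  nu <- cbind(cos(theta), sin(theta))
  state$positions <- state$positions + params$v * nu -
    params$a * (state$positions - state$homes)
  state$time <- state$time + 1L
  state
}

#' Simulate trajectories for a population
#'
#' Runs the movement model for `n_steps` steps and returns all positions,
#' including the initial ones at t = 0. No transmission bookkeeping is done;
#' use [run_simulation()] for the coupled sensor/receiver dynamics.
#'
#' @inheritParams init_population
#' @param n_steps Number of steps (>= 1).
#' @return A data frame with columns `animal_id`, `t`, `x`, `y`, one row per
#'   animal per time point (t = 0..n_steps), with the home coordinates
#'   attached as attribute `"homes"`.
#' @export
simulate_trajectory <- function(params, n_steps, seed = NULL) {
  stopifnot(inherits(params, "movement_params"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("`n_steps` must be >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  state <- init_population(params, seed = seed)
  n <- params$n_animals
  xs <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n)
  ys <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n)
  xs[1L, ] <- state$positions[, 1L]
  ys[1L, ] <- state$positions[, 2L]
  for (t in seq_len(n_steps)) {
    state <- step_population(state, params)
    xs[t + 1L, ] <- state$positions[, 1L]
    ys[t + 1L, ] <- state$positions[, 2L]
  }
  out <- data.frame(
    animal_id = rep(seq_len(n), each = n_steps + 1L),
    t = rep(0:n_steps, times = n),
    x = as.vector(xs),
    y = as.vector(ys))
  attr(out, "homes") <- state$homes
  out
}
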