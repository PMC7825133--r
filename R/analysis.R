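#' Sweep the transfer function over station counts
#'
#' For each station count and each realization, draws a fresh population,
#' places stations under the requested strategy, runs the coupled
#' simulation, and records the transfer function. Realizations are seeded
#' deterministically: the cell (count i, realization k) uses
#' `base_seed + (i - 1) * n_realizations + (k - 1)`, so sweeps sharing
#' `base_seed`, counts and `n_realizations` see identical random streams
#' (useful when comparing radii or population sizes).
#'
#' @param movement A [movement_params()] object.
#' @param counts Vector of station counts to sweep (non-empty).
#' @param radius Reception radius r.
#' @param n_steps Steps per run.
#' @param n_realizations Realizations averaged per count.
#' @param base_seed Integer seed anchoring the sweep.
#' @param strategy One of `"random"`, `"at_home"`, `"mobile"`.
#' @param station_speed Speed of mobile stations (strategy `"mobile"`).
#' @return A data frame of class `sweep_result`, one row per count:
#'   `n_stations`, `covered_area` (x pi r^2), `a`, `v`, `n_animals`, `r`,
#'   `n_steps`, `strategy`, `n_realizations`, `T_mean`, `T_sd`, `T_se`.
#'   The per-realization transfers are attached as attribute
#'   `"realizations"` (matrix counts x realizations).
#' @export
sweep_stations <- function(movement, counts, radius, n_steps,
                           n_realizations = 10, base_seed = 1,
                           strategy = c("random", "at_home", "mobile"),
                           station_speed = 0) {
  stopifnot(inherits(movement, "movement_params"))
  strategy <- match.arg(strategy)
  if (length(counts) == 0L) stop("`counts` must be non-empty", call. = FALSE)
  if (any(counts < 0 | counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  Tmat <- matrix(NA_real_, nrow = length(counts), ncol = n_realizations)
  for (i in seq_along(counts)) {
    for (k in seq_len(n_realizations)) {
      set.seed(base_seed + (i - 1L) * n_realizations + (k - 1L))
      state <- init_population(movement)
      st <- switch(strategy,
        random = place_random(counts[i], radius),
        at_home = place_at_homes(state$homes, counts[i], radius),
        mobile = place_random(counts[i], radius, mobile = TRUE,
                              station_speed = station_speed))
      Tmat[i, k] <- run_simulation(movement, st, n_steps, state = state,
                                   log_events = FALSE)$T_mean
    }
  }
  out <- data.frame(
    n_stations = counts,
    covered_area = total_reception_area(counts, radius),
    a = movement$a, v = movement$v, n_animals = movement$n_animals,
    r = radius, n_steps = n_steps, strategy = strategy,
    n_realizations = n_realizations,
    T_mean = rowMeans(Tmat),
    T_sd = apply(Tmat, 1L, sd),
    T_se = apply(Tmat, 1L, sd) / sqrt(n_realizations))
  attr(out, "realizations") <- Tmat
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Per-realization transfers of a sweep
#'
#' Unpacks the realization-level detail stored on a `sweep_result` into a
#' long table, one row per (count, realization) run.
#'
#' @param sweep A `sweep_result` from [sweep_stations()].
#' @return A data frame with columns `realization`, `n_stations`,
#'   `covered_area`, `a`, `v`, `r`, `T`.
#' @export
sweep_realizations <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  Tmat <- attr(sweep, "realizations")
  if (is.null(Tmat))
    stop("sweep carries no realization-level detail", call. = FALSE)
  data.frame(
    realization = rep(seq_len(ncol(Tmat)), each = nrow(Tmat)),
    n_stations = rep(sweep$n_stations, ncol(Tmat)),
    covered_area = rep(sweep$covered_area, ncol(Tmat)),
    a = if ("a" %in% names(sweep)) rep(sweep$a, ncol(Tmat)) else NA,
    v = if ("v" %in% names(sweep)) rep(sweep$v, ncol(Tmat)) else NA,
    r = rep(sweep$r, ncol(Tmat)),
    T = as.vector(Tmat))
}

#' Smallest deployment reaching 90% data recovery
#'
#' R90 is the smallest swept station count whose mean transfer is at least
#' 0.9 (no interpolation between swept counts). Since one package is
#' generated per animal per step, mean transfer >= 0.9 is equivalent to
#' recovering at least 90% of all generated packages. Also reports the
#' expected covered fraction (from the coverage law) at that count.
#'
#' @param sweep A `sweep_result` from [sweep_stations()].
#' @param level Recovery level, default 0.9.
#' @return An object of class `r90_result`: list with `reached` (logical),
#'   `R90` (station count or `NA`), `covered_fraction_at_R90`, and `level`.
#' @export
compute_R90 <- function(sweep, level = 0.9) {
  stopifnot(inherits(sweep, "sweep_result"))
  ord <- order(sweep$n_stations)
  counts <- sweep$n_stations[ord]
  means <- sweep$T_mean[ord]
  hit <- which(means >= level)
  if (length(hit) == 0L) {
    return(structure(list(reached = FALSE, R90 = NA_integer_,
                          covered_fraction_at_R90 = NA_real_, level = level),
                     class = "r90_result"))
  }
  r90 <- counts[hit[1L]]
  structure(list(
    reached = TRUE, R90 = r90,
    covered_fraction_at_R90 = covered_fraction(sweep$r[1L], 1, r90)$f,
    level = level), class = "r90_result")
}

#' @export
print.r90_result <- function(x, ...) {
  if (x$reached)
    cat(sprintf("R%d = %d stations (expected covered fraction %.4f)\n",
                round(100 * x$level), x$R90, x$covered_fraction_at_R90))
  else
    cat(sprintf("R%d not reached within the swept counts\n",
                round(100 * x$level)))
  invisible(x)
}

#' Transfer-function phase diagram over home attraction and station count
#'
#' Runs [sweep_stations()] for every value of the home attraction and
#' stacks the results into one long table (one row per (a, count) cell),
#' the data behind the usual colour-map representation.
#'
#' @param a_values Home-attraction values to scan.
#' @param counts Station counts to scan.
#' @param radius Reception radius.
#' @param n_animals Population size N.
#' @param v Step speed.
#' @param n_steps Steps per run.
#' @param n_realizations Realizations per cell.
#' @param base_seed Integer seed; each `a` gets an offset stream.
#' @return A data frame of class `c("phase_diagram", "sweep_result")`.
#' @export
phase_diagram <- function(a_values, counts, radius, n_animals, v, n_steps,
                          n_realizations = 10, base_seed = 1) {
  if (length(a_values) == 0L || length(counts) == 0L)
    stop("`a_values` and `counts` must be non-empty", call. = FALSE)
  rows <- lapply(seq_along(a_values), function(j) {
    mp <- movement_params(a = a_values[j], v = v, n_animals = n_animals)
    sweep_stations(mp, counts, radius, n_steps, n_realizations,
                   base_seed = base_seed + (j - 1L) * 100000L)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("phase_diagram", "sweep_result", "data.frame")
  out
}

#' Inter-event times of a run
#'
#' Differences between consecutive flush-event times of the same animal,
#' pooled over animals (and, if a list of runs is given, over runs).
#'
#' @param runs A `run_result`, its `events` data frame, or a list of either.
#' @return Integer vector of inter-event times (steps); empty when no animal
#'   has two events.
#' @export
inter_event_times <- function(runs) {
  if (inherits(runs, "run_result") || is.data.frame(runs)) runs <- list(runs)
  taus <- lapply(runs, function(run) {
    ev <- if (inherits(run, "run_result")) run$events else run
    if (nrow(ev) == 0L) return(integer(0))
    unlist(lapply(split(ev$time, ev$animal_id), diff), use.names = FALSE)
  })
  as.integer(unlist(taus, use.names = FALSE))
}

#' Log-binned probability density of inter-event times
#'
#' Bins the pooled inter-event times into bins of equal width in
#' `log10(tau)` and normalises the histogram to a density (so that the sum
#' of `density * bin width` over bins is 1). A degenerate sample with a
#' single distinct value is returned as one unit-width bin (a point mass).
#'
#' @param taus Inter-event times from [inter_event_times()] (or any run /
#'   event input it accepts).
#' @param n_bins Number of logarithmic bins.
#' @return A data frame of class `inter_event_pdf` with columns `bin_lo`,
#'   `bin_hi`, `mid` (geometric midpoint), `count`, `density`; zero rows
#'   when there are no event pairs.
#' @export
inter_event_pdf <- function(taus, n_bins = 30) {
  if (!is.numeric(taus)) taus <- inter_event_times(taus)
  empty <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      mid = numeric(0), count = integer(0),
                      density = numeric(0))
  if (length(taus) == 0L)
    return(structure(empty, class = c("inter_event_pdf", "data.frame")))
  stopifnot(all(taus >= 1))
  if (min(taus) == max(taus)) {
    out <- data.frame(bin_lo = min(taus) - 0.5, bin_hi = min(taus) + 0.5,
                      mid = as.numeric(min(taus)), count = length(taus),
                      density = 1)
    return(structure(out, class = c("inter_event_pdf", "data.frame")))
  }
  edges <- 10^seq(log10(min(taus)), log10(max(taus)), length.out = n_bins + 1L)
  edges[1L] <- min(taus) * (1 - 1e-9)
  edges[length(edges)] <- max(taus) * (1 + 1e-9)
  h <- hist(taus, breaks = edges, plot = FALSE)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    mid = sqrt(edges[-length(edges)] * edges[-1L]),
                    count = h$counts, density = h$density)
  structure(out, class = c("inter_event_pdf", "data.frame"))
}

#' Decay rate of the transfer law across home attractions
#'
#' For each home-attraction value, sweeps station counts, fits the
#' saturating-exponential transfer law versus covered area, and tabulates
#' the fitted rate d (which decreases as the attraction grows).
#'
#' @param a_values Home-attraction values.
#' @param counts Station counts for each sweep.
#' @param radius Reception radius.
#' @param n_animals Population size.
#' @param v Step speed.
#' @param n_steps Steps per run.
#' @param n_realizations Realizations per count.
#' @param base_seed Integer seed; each `a` gets an offset stream.
#' @param fix_c Passed to [fit_transfer_vs_area()]; fixing the saturation
#'   level (usually at 1) makes rates comparable across `a`.
#' @return A data frame with one row per `a`: `a`, `d`, `d_se`, `c`, `c_se`,
#'   `rss`.
#' @export
d_vs_a <- function(a_values, counts, radius, n_animals, v, n_steps,
                   n_realizations = 10, base_seed = 1, fix_c = NULL) {
  rows <- lapply(seq_along(a_values), function(j) {
    mp <- movement_params(a = a_values[j], v = v, n_animals = n_animals)
    sw <- sweep_stations(mp, counts, radius, n_steps, n_realizations,
                         base_seed = base_seed + (j - 1L) * 100000L)
    fit <- fit_transfer_vs_area(sw, fix_c = fix_c)
    data.frame(a = a_values[j],
               d = unname(fit$estimate["d"]), d_se = unname(fit$se["d"]),
               c = unname(fit$estimate["c"]), c_se = unname(fit$se["c"]),
               rss = fit$rss)
  })
  do.call(rbind, rows)
}

#' Plot a transfer-function sweep
#'
#' @param x A `sweep_result`.
#' @param against Plot against `"area"` (covered area) or `"count"`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.sweep_result <- function(x, against = c("area", "count"), ...) {
  against <- match.arg(against)
  xs <- if (against == "area") x$covered_area else x$n_stations
  xl <- if (against == "area") "covered area" else "number of stations"
  plot(xs, x$T_mean, type = "b", pch = 19, xlab = xl,
       ylab = expression("mean transfer " * group(langle, T, rangle)),
       ylim = c(0, 1), ...)
  has_se <- is.finite(x$T_se) & x$T_se > 0
  if (any(has_se))
    arrows(xs[has_se], x$T_mean[has_se] - x$T_se[has_se],
           xs[has_se], x$T_mean[has_se] + x$T_se[has_se],
           angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @importFrom graphics hist arrows plot
NULL
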