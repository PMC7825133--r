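#' Fit the saturating-exponential transfer law
#'
#' Nonlinear least-squares fit of \eqn{T = c\,(1 - e^{-d\,x})} to mean
#' transfer versus covered area, via Levenberg-Marquardt. Starting values
#' default to `c0 = max(T)` and `d0 = 1 / mean(x)`.
#'
#' When the sweep stops well short of saturation, `c` and `d` trade off
#' strongly and the free fit inflates `d`; for quoting rates comparably
#' across sweeps, `fix_c` pins the saturation level (typically at the
#' physical ceiling 1, every generated package recovered) and estimates
#' `d` alone.
#'
#' @param area Covered areas (increasing), or a `sweep_result` from
#'   [sweep_stations()] whose `covered_area` and `T_mean` columns are used.
#' @param T_mean Mean transfer values matching `area` (ignored when `area`
#'   is a `sweep_result`).
#' @param start Optional named list with starting values `c` and `d`.
#' @param fix_c Optional value at which the saturation level `c` is held
#'   fixed; `NULL` (default) estimates it.
#' @return An object of class `fit_result`: list with `form`, `estimate`
#'   (named vector), `se` (standard errors from the parameter covariance),
#'   `rss`, `fitted`, `model` (the underlying `nls` object) and `data`.
#'   Non-convergence signals an error of class `deploysim_fit_failure`.
#' @examples
#' x <- seq(0, 0.06, length.out = 10)
#' fit_transfer_vs_area(x, 0.9 * (1 - exp(-14.5 * x)))$estimate
#' @export
fit_transfer_vs_area <- function(area, T_mean = NULL, start = NULL,
                                 fix_c = NULL) {
  if (inherits(area, "sweep_result")) {
    T_mean <- area$T_mean
    area <- area$covered_area
  }
  if (length(area) < 4L)
    stop("need at least 4 points to fit the transfer law", call. = FALSE)
  if (length(area) != length(T_mean))
    stop("`area` and `T_mean` lengths differ", call. = FALSE)
  if (is.null(start)) {
    start <- list(c = max(T_mean), d = 1 / mean(area[area > 0]))
    if (!is.null(fix_c)) start$c <- NULL
  }
  dat <- data.frame(x = area, y = T_mean)
  form <- if (is.null(fix_c)) y ~ c * (1 - exp(-d * x)) else {
    cfix <- fix_c
    y ~ cfix * (1 - exp(-d * x))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop(structure(class = c("deploysim_fit_failure", "error", "condition"),
                     list(message = paste0("saturating-exponential fit failed: ",
                                           conditionMessage(e)),
                          call = sys.call(-1))))
    })
  out <- new_fit_result("c*(1 - exp(-d*x))", fit, dat)
  if (!is.null(fix_c)) {
    out$estimate <- c(c = fix_c, d = unname(out$estimate["d"]))
    out$se <- c(c = NA_real_, d = unname(out$se["d"]))
  }
  out
}

#' Fit the exponential decay of R90 with the reception radius
#'
#' Fits \eqn{y = y_0 + A\,e^{-(x - x_0)/t_1}} to R90 versus radius. Because
#' \eqn{A} and \eqn{x_0} only enter through \eqn{A\,e^{x_0/t_1}}, the
#' four-parameter form is over-parameterised; by default \eqn{x_0} is fixed
#' at `min(radius)` and \eqn{y_0, A, t_1} are estimated. Pass
#' `fix_x0 = NULL` to fit all four parameters (the individual values of `A`
#' and `x0` are then not identifiable, only the fitted curve is).
#'
#' @param radius Reception radii (>= 5 points).
#' @param R90 R90 values matching `radius`.
#' @param fix_x0 Value at which `x0` is held fixed, or `NULL` to free it.
#' @param start Optional named list of starting values.
#' @return A `fit_result` (see [fit_transfer_vs_area()]); `estimate` has
#'   entries `y0`, `A`, `x0`, `t1` (the `se` of a fixed `x0` is `NA`).
#' @export
fit_R90_vs_radius <- function(radius, R90, fix_x0 = min(radius),
                              start = NULL) {
  if (length(radius) < 5L)
    stop("need at least 5 points to fit the R90 decay", call. = FALSE)
  if (length(radius) != length(R90))
    stop("`radius` and `R90` lengths differ", call. = FALSE)
  dat <- data.frame(x = radius, y = R90)
  if (is.null(start))
    start <- list(y0 = min(R90), A = diff(range(R90)),
                  t1 = diff(range(radius)) / 3)
  run_fit <- function(expr, start) tryCatch(
    minpack.lm::nlsLM(expr, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop(structure(class = c("deploysim_fit_failure", "error", "condition"),
                     list(message = paste0("R90 decay fit failed: ",
                                           conditionMessage(e)),
                          call = sys.call(-1))))
    })
  if (is.null(fix_x0)) {
    start$x0 <- min(radius)
    fit <- run_fit(y ~ y0 + A * exp(-(x - x0) / t1), start)
    out <- new_fit_result("y0 + A*exp(-(x - x0)/t1)", fit, dat)
  } else {
    x0 <- fix_x0
    fit <- run_fit(y ~ y0 + A * exp(-(x - x0) / t1), start)
    out <- new_fit_result("y0 + A*exp(-(x - x0)/t1)", fit, dat)
    out$estimate <- c(out$estimate[c("y0", "A")], x0 = x0,
                      t1 = unname(out$estimate["t1"]))
    out$se <- c(out$se[c("y0", "A")], x0 = NA_real_,
                t1 = unname(out$se["t1"]))
  }
  out
}

new_fit_result <- function(form, fit, dat) {
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(est)) else sqrt(diag(vc))
  names(se) <- names(est)
  structure(list(form = form, estimate = est, se = se,
                 rss = sum(residuals(fit)^2),
                 fitted = fitted(fit), model = fit, data = dat),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit:", x$form, "\n")
  tab <- data.frame(estimate = x$estimate, std.error = x$se)
  print(tab, digits = 4)
  cat(sprintf("RSS = %.4g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @importFrom stats residuals fitted
NULL
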