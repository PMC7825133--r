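make_sweep <- function(counts, means, r = 0.01) {
  df <- data.frame(n_stations = counts,
                   covered_area = total_reception_area(counts, r),
                   a = 0.001, v = 0.001, n_animals = 100, r = r,
                   n_steps = 1000, strategy = "random",
                   n_realizations = 10, T_mean = means, T_sd = 0, T_se = 0)
  class(df) <- c("sweep_result", "data.frame")
  df
}

test_that("R90 is the smallest swept count reaching 90% recovery", {
  r90 <- compute_R90(make_sweep(c(40, 50), c(0.85, 0.92)))
  expect_true(r90$reached)
  expect_equal(r90$R90, 50)
  expect_equal(r90$covered_fraction_at_R90, covered_fraction(0.01, 1, 50)$f)

  below <- compute_R90(make_sweep(c(10, 20, 40), c(0.2, 0.4, 0.6)))
  expect_false(below$reached)
  expect_true(is.na(below$R90))
})

test_that("saturating-exponential fit recovers known parameters", {
  x <- seq(0, 0.06, length.out = 12)
  y <- 0.9 * (1 - exp(-14.5 * x))
  fit <- fit_transfer_vs_area(x, y)
  expect_equal(unname(fit$estimate["c"]), 0.9, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["d"]), 14.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # Gaussian noise: the 2-SE interval covers the truth at its nominal rate
  # (per replicate the check holds with ~95% probability, so a large
  # majority of replicates must satisfy it)
  set.seed(77)
  ok <- replicate(20, {
    fitn <- fit_transfer_vs_area(x, y + rnorm(length(y), 0, 0.01))
    abs(fitn$estimate["d"] - 14.5) < 2 * fitn$se["d"] &&
      abs(fitn$estimate["c"] - 0.9) < 2 * fitn$se["c"]
  })
  expect_gte(sum(ok), 15)

  expect_error(fit_transfer_vs_area(c(0, 1, 2), c(0, 1, 1)), "at least 4")
})

test_that("R90 decay fit recovers known parameters", {
  x <- seq(0.005, 0.05, length.out = 10)
  y <- 5 + 100 * exp(-(x - 0.005) / 0.01)
  fit <- fit_R90_vs_radius(x, y, fix_x0 = 0.005)
  expect_equal(unname(fit$estimate["y0"]), 5, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["A"]), 100, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["t1"]), 0.01, tolerance = 1e-6)

  # fitted curve is decreasing over the data range for decreasing data
  expect_true(all(diff(fit$fitted) < 0))

  # noisy recovery: 2-SE interval for the decay scale covers the truth at
  # its nominal rate across replicates
  set.seed(88)
  ok <- replicate(20, {
    fitn <- fit_R90_vs_radius(x, y + rnorm(length(y), 0, 2))
    abs(fitn$estimate["t1"] - 0.01) < 2 * fitn$se["t1"]
  })
  expect_gte(sum(ok), 15)
  expect_error(fit_R90_vs_radius(x[1:4], y[1:4]), "at least 5")
})

test_that("inter-event times and their log-binned density behave", {
  ev <- data.frame(animal_id = c(1, 1, 1), time = c(3, 5, 10),
                   size = c(3, 2, 5))
  expect_equal(inter_event_times(ev), c(2L, 5L))

  # pooled over animals
  ev2 <- rbind(ev, data.frame(animal_id = 2, time = c(7, 8), size = c(7, 1)))
  expect_setequal(inter_event_times(ev2), c(2L, 5L, 1L))

  set.seed(5)
  taus <- sample(1:500, 400, replace = TRUE)
  pdf <- inter_event_pdf(taus, n_bins = 20)
  expect_equal(sum(pdf$density * (pdf$bin_hi - pdf$bin_lo)), 1,
               tolerance = 1e-6)
  expect_equal(sum(pdf$count), length(taus))

  # permanently-in-range animal: point mass at tau = 1
  mass <- inter_event_pdf(rep(1L, 50))
  expect_equal(nrow(mass), 1L)
  expect_equal(sum(mass$density * (mass$bin_hi - mass$bin_lo)), 1)

  none <- inter_event_pdf(integer(0))
  expect_equal(nrow(none), 0L)
})

test_that("sweeps record transfer per count and are deterministic", {
  mp <- movement_params(a = 0.01, v = 0.005, n_animals = 10)
  sw <- sweep_stations(mp, counts = c(0, 10), radius = 0.05, n_steps = 200,
                       n_realizations = 3, base_seed = 5)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$T_mean[sw$n_stations == 0], 0)
  expect_equal(sw$covered_area, c(0, 10) * pi * 0.05^2)
  sw2 <- sweep_stations(mp, counts = c(0, 10), radius = 0.05, n_steps = 200,
                        n_realizations = 3, base_seed = 5)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  # realization-level detail unpacks consistently with the summary
  det <- sweep_realizations(sw)
  expect_equal(nrow(det), 6L)
  expect_equal(as.numeric(tapply(det$T, det$n_stations, mean)),
               sw$T_mean, tolerance = 1e-12)
})

test_that("identical sweeps give identical fitted rates", {
  mp <- movement_params(a = 0.01, v = 0.005, n_animals = 10)
  args <- list(mp, counts = c(2, 5, 10, 20, 40), radius = 0.05,
               n_steps = 300, n_realizations = 3, base_seed = 2)
  d1 <- fit_transfer_vs_area(do.call(sweep_stations, args))$estimate["d"]
  d2 <- fit_transfer_vs_area(do.call(sweep_stations, args))$estimate["d"]
  expect_identical(d1, d2)
})

test_that("phase diagram rows are zero without stations and ordered in a", {
  pd <- phase_diagram(a_values = c(0.001, 0.5), counts = c(0, 15),
                      radius = 0.05, n_animals = 20, v = 0.005,
                      n_steps = 500, n_realizations = 5, base_seed = 3)
  expect_equal(nrow(pd), 4L)
  expect_true(all(pd$T_mean[pd$n_stations == 0] == 0))
  # transfer decreases with home attraction at fixed count
  t_low <- pd$T_mean[pd$a == 0.001 & pd$n_stations == 15]
  t_high <- pd$T_mean[pd$a == 0.5 & pd$n_stations == 15]
  expect_gt(t_low, t_high)
  # each row non-decreasing in count
  expect_true(all(tapply(pd$T_mean, pd$a, function(x) all(diff(x) >= 0))))
})
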