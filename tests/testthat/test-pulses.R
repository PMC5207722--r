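bump <- function(t, center, height, width = 0.3) {
  height * exp(-((t - center) / width)^2)
}

test_that("pulse detection recovers constructed bumps", {
  t <- seq(0, 10, 0.01)
  one <- bump(t, 5, 2)
  p <- detect_pulses(one, t, min_prominence = 0.1)
  expect_equal(nrow(p), 1)
  expect_equal(p$amplitude, 2, tolerance = 1e-3)
  expect_equal(p$peak_time, 5, tolerance = 0.02)

  expect_equal(nrow(detect_pulses(rep(1, length(t)), t)), 0)

  two <- bump(t, 3, 1.5) + bump(t, 7, 1.5)
  p2 <- detect_pulses(two, t, min_prominence = 0.1)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$amplitude, rep(1.5, 2), tolerance = 1e-3)
})

test_that("close peaks are merged by the separation rule, keeping the larger", {
  t <- seq(0, 10, 0.01)
  s <- bump(t, 5, 2, 0.1) + bump(t, 5.3, 1, 0.1)
  p <- detect_pulses(s, t, min_prominence = 0.1, min_separation = 0.5)
  expect_equal(nrow(p), 1)
  expect_equal(p$peak_time, 5, tolerance = 0.02)
  p2 <- detect_pulses(s, t, min_prominence = 0.1, min_separation = 0.2)
  expect_equal(nrow(p2), 2)
})

test_that("detection is amplitude-scale equivariant", {
  t <- seq(0, 20, 0.01)
  set.seed(5)
  s <- Reduce(`+`, lapply(1:6, function(i)
    bump(t, runif(1, 1, 19), runif(1, 0.5, 2))))
  p1 <- detect_pulses(s, t, min_prominence = 0.1)
  p3 <- detect_pulses(3 * s, t, min_prominence = 0.3)
  expect_equal(p3$amplitude, 3 * p1$amplitude, tolerance = 1e-10)
  expect_equal(p3$peak_time, p1$peak_time)
})

test_that("ensemble statistics count pulses per trace per unit time", {
  t <- seq(0, 10, 0.01)
  trace <- bump(t, 3, 1) + bump(t, 7, 1)
  sets <- replicate(50, detect_pulses(trace, t, 0.1), simplify = FALSE)
  st <- ensemble_pulse_stats(sets, 10)
  expect_equal(st$mean_frequency, 0.2)
  expect_equal(st$sd_frequency, 0)
  expect_equal(st$mean_amplitude, 1, tolerance = 1e-3)
  empty <- ensemble_pulse_stats(list(empty_set <- detect_pulses(rep(0, 11),
                                                                0:10)), 10)
  expect_equal(empty$mean_frequency, 0)
  expect_true(is.na(empty$mean_amplitude))
})

test_that("Hill fits recover noiseless parameters exactly", {
  x <- exp(seq(log(0.05), log(20), length.out = 25))
  for (n in c(0.5, 1, 3, 8)) {
    y <- 2 * x^n / (1 + x^n)   # K = 1, ymax = 2
    fit <- fit_hill(x, y)
    expect_equal(fit$n_Hill, n, tolerance = 1e-4)
    expect_equal(fit$K_half, 1, tolerance = 1e-4)
    expect_equal(fit$ymax, 2, tolerance = 1e-4)
    expect_equal(fit$fun(fit$K_half), fit$ymax / 2, tolerance = 1e-8)
  }
})

test_that("linear data below saturation fit with a Hill exponent near 1", {
  x <- seq(0.1, 1, length.out = 10)
  fit <- fit_hill(x, 0.3 * x)
  expect_equal(fit$n_Hill, 1, tolerance = 0.05)
})

test_that("decreasing Hill form fits ramp-style data", {
  x <- c(0, 0.5, 1, 2, 4, 8)
  y <- 1.5 * 2^3 / (2^3 + x^3)
  fit <- fit_hill(x, y, decreasing = TRUE)
  expect_equal(fit$n_Hill, 3, tolerance = 1e-4)
  expect_equal(fit$K_half, 2, tolerance = 1e-4)
})

test_that("amplitude CDF distance separates shifted ensembles", {
  t <- seq(0, 10, 0.01)
  mk <- function(h) list(detect_pulses(bump(t, 3, h) + bump(t, 7, h * 1.2),
                                       t, 0.05))
  a <- amplitude_cdf(mk(1))
  expect_equal(cdf_distance(a, amplitude_cdf(mk(1))), 0)
  expect_equal(cdf_distance(a, amplitude_cdf(mk(5))), 1)
})

test_that("target readouts track occupancy through the dilution filter", {
  tr <- sigb_simulate(kin_default, op_default, phos_step(0.5), horizon = 6,
                      init = ss_unstressed)
  tr <- add_target_readouts(tr)
  expect_equal(tr$target_activity, tr$sigB / (op_default$K + tr$sigB))
  expect_true(all(tr$target_expression >= 0 & tr$target_expression <= 1))
  # the filtered signal lags the raw occupancy: its peak comes later
  expect_gt(which.max(tr$target_expression), which.max(tr$target_activity))
})

test_that("headline pulse statistics are stable to detection settings", {
  # doubling/halving prominence and separation must not change the mean
  # amplitude by more than ~20% on a pulsing trace ensemble
  bp <- burst_params(a = 2, b = 0.5, T = 10)
  amps <- sapply(1:4, function(k) {
    inp <- sample_gamma_ou(modifyList(bp, list(seed = 100 + k)))
    tr <- sigb_simulate(kin_default, op_default, inp, horizon = 10,
                        init = ss_unstressed)
    sapply(list(c(0.025, 0.25), c(0.05, 0.5), c(0.1, 1)), function(pars)
      mean(detect_pulses(tr$sigB, tr$time, pars[1], pars[2])$amplitude))
  })
  m <- rowMeans(amps)
  expect_lt(max(abs(m / m[2] - 1)), 0.25)
})
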