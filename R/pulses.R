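# Pulse detection and encoding statistics: local-extremum pulse calling,
# ensemble amplitude/frequency moments, Hill-equation fits, amplitude CDFs
# and the ramp-duration (K_ramp) analysis.

#' Detect pulses in a trajectory signal
#'
#' Calls pulses as local maxima of the signal whose prominence (peak value
#' minus the preceding local minimum) exceeds `min_prominence`, enforcing a
#' minimum peak separation (smaller peaks within `min_separation` of a
#' larger one are discarded). Amplitude is peak minus preceding minimum.
#'
#' @param signal numeric signal on a uniform time grid.
#' @param time time grid (hr).
#' @param min_prominence minimum amplitude; default 5% of the signal's
#'   global range.
#' @param min_separation minimum peak-to-peak distance (hr).
#' @return Data frame of class `pulse_set`: `peak_time`, `amplitude`,
#'   `peak_value`, `base_value` (preceding minimum).
#' @export
detect_pulses <- function(signal, time, min_prominence = NULL,
                          min_separation = 0.5) {
  stopifnot(length(signal) == length(time), length(signal) >= 3)
  if (is.null(min_prominence))
    min_prominence <- 0.05 * diff(range(signal))
  if (min_prominence <= 0)   # flat signal
    return(empty_pulse_set())
  n <- length(signal)
  ds <- diff(signal)
  # interior local maxima/minima (plateaus resolved to their first point)
  is_max <- which(ds[-1] < 0 & ds[-(n - 1)] > 0) + 1
  is_min <- which(ds[-1] > 0 & ds[-(n - 1)] < 0) + 1
  if (!length(is_max)) return(empty_pulse_set())
  base_val <- vapply(is_max, function(i) {
    prev_min <- is_min[is_min < i]
    if (length(prev_min)) signal[max(prev_min)] else signal[1]
  }, numeric(1))
  amp <- signal[is_max] - base_val
  keep <- amp >= min_prominence
  is_max <- is_max[keep]; amp <- amp[keep]; base_val <- base_val[keep]
  # enforce separation, keeping the larger of two close peaks
  o <- order(amp, decreasing = TRUE)
  sel <- logical(length(is_max))
  for (j in o) {
    if (!any(sel & abs(time[is_max] - time[is_max[j]]) < min_separation))
      sel[j] <- TRUE
  }
  o2 <- order(time[is_max[sel]])
  structure(data.frame(peak_time = time[is_max[sel]][o2],
                       amplitude = amp[sel][o2],
                       peak_value = signal[is_max[sel]][o2],
                       base_value = base_val[sel][o2]),
            class = c("pulse_set", "data.frame"))
}

empty_pulse_set <- function() {
  structure(data.frame(peak_time = numeric(0), amplitude = numeric(0),
                       peak_value = numeric(0), base_value = numeric(0)),
            class = c("pulse_set", "data.frame"))
}

#' Ensemble pulse statistics
#'
#' Amplitude moments over all pulses of an ensemble and the pulse
#' frequency (pulses per trace per unit time, averaged over traces).
#'
#' @param pulse_sets list of `pulse_set` objects (one per trace).
#' @param total_time duration of each trace (hr).
#' @return List with `mean_amplitude`, `sd_amplitude`, `mean_frequency`
#'   (hr^-1), `sd_frequency`, `n_pulses`. Amplitude moments are `NA` when
#'   the ensemble has no pulses.
#' @export
ensemble_pulse_stats <- function(pulse_sets, total_time) {
  stopifnot(length(pulse_sets) >= 1, total_time > 0)
  amps <- unlist(lapply(pulse_sets, function(p) p$amplitude))
  freqs <- vapply(pulse_sets, nrow, numeric(1)) / total_time
  list(mean_amplitude = if (length(amps)) mean(amps) else NA_real_,
       sd_amplitude = if (length(amps) > 1) sd(amps) else NA_real_,
       mean_frequency = mean(freqs),
       sd_frequency = if (length(freqs) > 1) sd(freqs) else NA_real_,
       n_pulses = length(amps))
}

#' Fit a Hill equation
#'
#' Least-squares fit of `y = ymax * x^n / (K^n + x^n)` with multi-start
#' Levenberg-Marquardt over a log-spaced grid of `(n, K)` initial values;
#' ties are broken by lowest residual then lowest `n`.
#'
#' @param x,y data (x > 0, at least 4 points).
#' @param n_range search range for the Hill coefficient.
#' @param decreasing fit the decreasing form
#'   `y = ymax * K^n / (K^n + x^n)` instead (x = 0 rows allowed and kept).
#' @return List of class `hill_fit`: `n_Hill`, `K_half`, `ymax`,
#'   `residual` (RMS), and the fitted `fun(x)`.
#' @export
fit_hill <- function(x, y, n_range = c(0.3, 12), decreasing = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (!decreasing) stopifnot(all(x > 0)) else stopifnot(all(x >= 0))
  model <- if (decreasing) {
    function(p, x) p[3] * p[2]^p[1] / (p[2]^p[1] + x^p[1])
  } else {
    function(p, x) p[3] * x^p[1] / (p[2]^p[1] + x^p[1])
  }
  resid_fn <- function(lp) model(exp(lp), x) - y
  K_grid <- exp(seq(log(max(min(x[x > 0]), 1e-6)), log(max(x)), length.out = 5))
  n_grid <- exp(seq(log(n_range[1]), log(n_range[2]), length.out = 4))
  best <- NULL
  for (n0 in n_grid) for (K0 in K_grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(c(n0, K0, max(y))), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    p <- exp(fit$par)
    if (is.null(best) || rss < best$rss * (1 - 1e-8) ||
        (rss < best$rss * (1 + 1e-8) && p[1] < best$p[1])) {
      best <- list(rss = rss, p = p)
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  p <- best$p
  structure(list(n_Hill = p[1], K_half = p[2], ymax = p[3],
                 residual = sqrt(best$rss / length(x)),
                 decreasing = decreasing,
                 fun = function(xx) model(p, xx)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> n_Hill = %.3g, K_half = %.3g, ymax = %.3g (rms %.3g)%s\n",
              x$n_Hill, x$K_half, x$ymax, x$residual,
              if (x$decreasing) ", decreasing" else ""))
  invisible(x)
}

#' Empirical amplitude CDF and CDF distance
#'
#' `amplitude_cdf()` pools the pulse amplitudes of an ensemble into a
#' normalized empirical CDF; `cdf_distance()` is the sup-norm
#' (Kolmogorov) distance between two such CDFs.
#'
#' @param pulse_sets list of `pulse_set` objects with at least one pulse
#'   in total.
#' @return `amplitude_cdf()`: a function-bearing list with `amplitudes`
#'   (sorted) and `fun` (right-continuous CDF).
#' @export
amplitude_cdf <- function(pulse_sets) {
  amps <- sort(unlist(lapply(pulse_sets, function(p) p$amplitude)))
  if (!length(amps)) stop("no pulses in the ensemble")
  structure(list(amplitudes = amps, fun = stats::ecdf(amps)),
            class = "amplitude_cdf")
}

#' @rdname amplitude_cdf
#' @param cdf1,cdf2 objects from `amplitude_cdf()`.
#' @export
cdf_distance <- function(cdf1, cdf2) {
  grid <- sort(unique(c(cdf1$amplitudes, cdf2$amplitudes)))
  max(abs(cdf1$fun(grid) - cdf2$fun(grid)))
}

#' Target promoter activity and expression readouts
#'
#' In the core model (no explicit RNA polymerase), the activity of a
#' sigma-B target promoter is its occupancy `sigma / (K + sigma)` applied
#' to free sigma-B (same affinity `K` as the operon promoter). "Target
#' expression" is the corresponding steady-flux protein level: the
#' activity low-pass filtered at the dilution rate `k_deg` (first-order
#' exponential filter on the trajectory grid), so its time average is the
#' mean occupancy seen through protein turnover.
#'
#' @param traj a `sigb_traj`.
#' @param kin,op parameters; default those attached to `traj`.
#' @return `traj` with added columns `target_activity` and
#'   `target_expression`.
#' @export
add_target_readouts <- function(traj, kin = attr(traj, "kinetics"),
                                op = attr(traj, "operon")) {
  act <- traj$sigB / (op$K + traj$sigB)
  dt <- diff(traj$time)
  te <- numeric(length(act))
  te[1] <- act[1]
  a <- exp(-kin$k_deg * dt)
  for (i in seq_along(dt))
    te[i + 1] <- a[i] * te[i] + (1 - a[i]) * act[i + 1]
  traj$target_activity <- act
  traj$target_expression <- te
  traj
}

#' Ramp-duration encoding of pulse amplitude
#'
#' For each degradation/dilution rate, simulates ramped increases of the
#' environmental-stress phosphatase of fixed final level and varying
#' duration, measures the free sigma-B pulse amplitude, and fits a
#' decreasing Hill curve amplitude(T_ramp) whose half-max constant is
#' `K_ramp`. The basal synthesis rate is rescaled proportionally to
#' `k_deg` so steady-state totals are identical across rates.
#'
#' @param kin,op baseline parameters (the ramp experiments default to the
#'   environmental-stress dilution rate 0.72 hr^-1 via `k_deg_values`).
#' @param ramp_final_P_T final phosphatase level of every ramp (uM).
#' @param ramp_durations ramp durations (hr); 0 is a step.
#' @param k_deg_values degradation/dilution rates to compare (hr^-1).
#' @return Data frame with `k_deg`, `T_ramp`, `amplitude`, plus a list of
#'   per-k_deg `hill_fit`s in attribute `fits` (named by k_deg) whose
#'   `K_half` is K_ramp.
#' @export
ramp_response <- function(kin = sigb_kinetics(), op = sigb_operon(),
                          ramp_final_P_T = 0.5,
                          ramp_durations = c(0, 0.25, 0.5, 1, 2, 4, 8),
                          k_deg_values = c(0.36, 0.72, 1.44)) {
  rows <- list(); fits <- list()
  for (kd in k_deg_values) {
    kin_kd <- do.call(sigb_kinetics, modifyList(unclass(kin), list(k_deg = kd)))
    op_kd <- do.call(sigb_operon,
                     modifyList(unclass(op), list(v0 = op$v0 * kd / kin$k_deg)))
    init <- steady_state(kin_kd, op_kd, 0)
    amp <- vapply(ramp_durations, function(Tr) {
      inp <- if (Tr == 0) phos_step(ramp_final_P_T)
             else phos_ramp(ramp_final_P_T, t0 = 0, T_ramp = Tr)
      tr <- sigb_simulate(kin_kd, op_kd, inp, horizon = max(ramp_durations) + 12,
                          init = init)
      max(tr$sigB) - tr$sigB[1]
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(k_deg = kd, T_ramp = ramp_durations,
                                           amplitude = amp)
    fits[[as.character(kd)]] <- fit_hill(ramp_durations, amp, decreasing = TRUE)
  }
  structure(do.call(rbind, rows), fits = fits)
}
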