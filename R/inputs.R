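# Phosphatase input module: deterministic step/ramp inputs and the
# stochastic gamma-distributed Ornstein-Uhlenbeck burst process.

new_phos_input <- function(kind, fun, grid = NULL, params = list(), seed = NULL) {
  structure(list(kind = kind, fun = fun, grid = grid,
                 params = params, seed = seed),
            class = "phos_input")
}

#' @export
print.phos_input <- function(x, ...) {
  cat("<phos_input>", x$kind, "\n")
  if (length(x$params)) utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Deterministic phosphatase inputs
#'
#' `phos_step()` jumps from `P0` to `P1` at `t_step`; `phos_ramp()` rises
#' linearly from `P0` to `P1` over `[t0, t0 + T_ramp]` (a zero-duration
#' ramp is a step); `phos_decaying_step()` steps to `P1` and then relaxes
#' back towards `P0` at `decay_rate`, emulating dilution of the
#' phosphatase after a stress-induced step.
#'
#' @param P0,P1 initial and final total phosphatase (uM), non-negative.
#' @param t_step,t0 time of the step / start of the ramp (hr).
#' @param T_ramp ramp duration (hr), `>= 0`.
#' @param decay_rate exponential relaxation rate (hr^-1).
#' @return A `phos_input` object; its `$fun` evaluates P_T(t).
#' @export
phos_step <- function(P1, P0 = 0, t_step = 0) {
  stopifnot(P0 >= 0, P1 >= 0)
  new_phos_input("step",
                 function(t) ifelse(t < t_step, P0, P1),
                 params = list(P0 = P0, P1 = P1, t_step = t_step))
}

#' @rdname phos_step
#' @export
phos_ramp <- function(P1, P0 = 0, t0 = 0, T_ramp = 1) {
  stopifnot(P0 >= 0, P1 >= 0, T_ramp >= 0)
  fun <- if (T_ramp == 0) {
    function(t) ifelse(t < t0, P0, P1)
  } else {
    function(t) pmin(pmax((t - t0) / T_ramp, 0), 1) * (P1 - P0) + P0
  }
  new_phos_input("ramp", fun,
                 params = list(P0 = P0, P1 = P1, t0 = t0, T_ramp = T_ramp))
}

#' @rdname phos_step
#' @export
phos_decaying_step <- function(P1, P0 = 0, t_step = 0, decay_rate = 0.7) {
  stopifnot(P0 >= 0, P1 >= 0, decay_rate >= 0)
  new_phos_input("decaying_step",
                 function(t) ifelse(t < t_step, P0,
                                    P0 + (P1 - P0) * exp(-decay_rate * (t - t_step))),
                 params = list(P0 = P0, P1 = P1, t_step = t_step,
                               decay_rate = decay_rate))
}

#' Phosphatase input from a sampled trajectory
#'
#' Wraps a pre-computed trajectory (uniform time grid) for use as the
#' solver forcing; values are linearly interpolated and held constant
#' beyond the grid.
#'
#' @param time,P_T numeric vectors (hr, uM) of equal length.
#' @param seed optional integer recorded for provenance.
#' @return A `phos_input` of kind `"trajectory"`.
#' @export
phos_trajectory <- function(time, P_T, seed = NULL) {
  stopifnot(length(time) == length(P_T), all(diff(time) > 0), all(P_T >= 0))
  fun <- approxfun(time, P_T, rule = 2)
  new_phos_input("trajectory", fun,
                 grid = data.frame(time = time, P_T = P_T), seed = seed)
}

#' Burst-process parameters
#'
#' Parameters of the gamma-distributed Ornstein-Uhlenbeck process used for
#' the stochastic phosphatase input: production occurs in bursts
#' (compound-Poisson jumps with exponentially distributed sizes of mean
#' `b`) and decays exponentially at rate `gamma` between bursts. The jump
#' rate is `a * gamma`, so the stationary law is exactly
#' Gamma(shape = `a`, scale = `b`) with mean `a * b` and variance
#' `a * b^2`; `a` counts bursts per relaxation time, which at the default
#' `gamma` matches the ~1 hr cell cycle.
#'
#' @param a burst frequency (bursts per cell cycle), > 0.
#' @param b mean burst size (uM per burst), > 0.
#' @param gamma relaxation/dilution rate of the process (hr^-1).
#' @param cell_cycle cell-cycle duration (hr), documentation of the
#'   frequency convention.
#' @param dt sampling step of the pre-computed trajectory (hr).
#' @param T trajectory duration (hr).
#' @param seed integer seed, or `NULL`.
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(a = 2, b = 0.25, gamma = 0.7, cell_cycle = 1,
                         dt = 0.01, T = 10, seed = NULL) {
  stopifnot(a > 0, b > 0, gamma > 0, dt > 0, T > 0)
  structure(list(a = a, b = b, gamma = gamma, cell_cycle = cell_cycle,
                 dt = dt, T = T, seed = seed),
            class = "burst_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a gamma-OU phosphatase trajectory
#'
#' Draws burst times from a Poisson process of rate `a * gamma`, burst
#' sizes from Exp(mean `b`), applies exponential decay at rate `gamma`
#' between bursts, and samples the result on a uniform grid of step `dt`.
#' The process is initialized from its stationary Gamma(`a`, scale `b`)
#' law, so the trajectory is stationary from `t = 0`.
#'
#' @param bp a [burst_params()] object.
#' @return A `phos_input` of kind `"trajectory"` carrying the sampled grid.
#' @export
sample_gamma_ou <- function(bp) {
  stopifnot(inherits(bp, "burst_params"))
  rate <- bp$a * bp$gamma
  if (bp$dt > 1 / (10 * rate))
    warning("sampling step dt is coarse relative to the burst rate (aliasing)")
  with_seed(bp$seed, {
    tg <- seq(0, bp$T, by = bp$dt)
    n_jump <- stats::rpois(1, rate * bp$T)
    jt <- sort(runif(n_jump, 0, bp$T))
    js <- rexp(n_jump, rate = 1 / bp$b)
    P0 <- rgamma(1, shape = bp$a, scale = bp$b)
    # bin each jump's contribution, decayed to the end of its bin, then
    # run the exact one-step recursion P_i = P_{i-1} e^(-g dt) + s_i
    bin <- pmin(pmax(ceiling(jt / bp$dt), 1), length(tg) - 1)  # jump in (t_{bin-1}, t_bin]
    s <- numeric(length(tg) - 1)
    if (n_jump > 0) {
      decayed <- js * exp(-bp$gamma * (tg[bin + 1] - jt))
      s_agg <- tapply(decayed, bin, sum)
      s[as.integer(names(s_agg))] <- as.numeric(s_agg)
    }
    P <- as.numeric(stats::filter(s, exp(-bp$gamma * bp$dt),
                                  method = "recursive", init = P0))
    out <- phos_trajectory(tg, c(P0, P), seed = bp$seed)
    out$params <- unclass(bp)
    out
  })
}

#' Scale burst parameters to target stationary means
#'
#' Energy stress can raise the mean phosphatase either by producing larger
#' bursts (`mode = "size"`: `a` fixed, `b` scaled) or more frequent bursts
#' (`mode = "frequency"`: `b` fixed, `a` scaled). Each returned parameter
#' set has stationary mean `a * b` equal to its target.
#'
#' @param bp0 baseline [burst_params()].
#' @param target_means positive stationary means (uM).
#' @param mode `"size"` or `"frequency"`.
#' @return List of [burst_params()], one per target mean.
#' @export
sweep_mean <- function(bp0, target_means, mode = c("size", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(all(target_means > 0))
  lapply(target_means, function(m) {
    out <- bp0
    if (mode == "size") out$b <- m / out$a else out$a <- m / out$b
    out
  })
}

#' Solver forcing table for an input
#'
#' Materializes P_T(t) on `[0, t_max]` as the two-column matrix consumed
#' by the ODE solver. Discontinuities of step-like inputs are bracketed by
#' a narrow (1e-9 hr) linear segment.
#'
#' @param input a `phos_input`.
#' @param t_max horizon (hr).
#' @return Numeric matrix with columns time and P_T.
#' @keywords internal
input_forcing <- function(input, t_max) {
  if (input$kind == "trajectory") {
    g <- input$grid[input$grid$time <= t_max, , drop = FALSE]
    if (max(g$time) < t_max)
      g <- rbind(g, data.frame(time = t_max, P_T = g$P_T[nrow(g)]))
    return(as.matrix(g))
  }
  eps <- 1e-9
  brk <- switch(input$kind,
    step = input$params$t_step,
    decaying_step = input$params$t_step,
    ramp = c(input$params$t0, input$params$t0 + input$params$T_ramp),
    numeric(0))
  tt <- sort(unique(pmin(pmax(c(0, t_max, brk - eps, brk, brk + eps,
                                seq(0, t_max, length.out = 201)), 0), t_max)))
  cbind(tt, input$fun(tt + eps / 2))
}

#' Read or write a phosphatase trajectory file
#'
#' Two-column tab-separated text (`time_hr`, `P_T_uM`) with a header row.
#'
#' @param input a `phos_input` with a sampled grid.
#' @param path file path.
#' @return `read_phos_input()` returns a `phos_input` of kind
#'   `"trajectory"`.
#' @export
write_phos_input <- function(input, path) {
  g <- input$grid
  if (is.null(g)) {
    tt <- seq(0, 10, by = 0.01)
    g <- data.frame(time = tt, P_T = input$fun(tt))
  }
  write.table(setNames(g, c("time_hr", "P_T_uM")), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phos_input
#' @export
read_phos_input <- function(path) {
  d <- read.delim(path)
  phos_trajectory(d$time_hr, d$P_T_uM)
}
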