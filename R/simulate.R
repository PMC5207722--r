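# Simulation of the core network: stiff integration with deSolve using the
# compiled rhs, steady-state solution, and trajectory I/O.

core_ode <- function(y0, times, kin, op, input, rtol, atol, method, hmax) {
  forc <- input_forcing(input, max(times))
  out <- deSolve::ode(y = y0, times = times, parms = core_parvec(kin, op),
                      func = "sigb_derivs", dllname = "sigbnet",
                      initfunc = "sigb_initmod", initforc = "sigb_initforc",
                      forcings = forc, fcontrol = list(method = "linear", rule = 2),
                      nout = 2, outnames = c("P", "vB"),
                      rtol = rtol, atol = atol, method = method, maxsteps = 100000,
                      hmax = if (is.null(hmax)) Inf else hmax)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration failed near t = ", max(out[, "time"]), " hr")
  out
}

input_breakpoints <- function(input) {
  switch(input$kind,
    step = ,
    decaying_step = input$params$t_step,
    ramp = c(input$params$t0, input$params$t0 + input$params$T_ramp),
    numeric(0))
}

#' Simulate the sigma-B network
#'
#' Integrates the stiff mass-action ODE system under a prescribed total
#' phosphatase input P_T(t). Deterministic inputs are integrated piecewise
#' between their breakpoints (so step discontinuities are handled by solver
#' restarts); sampled burst trajectories are linearly interpolated with the
#' solver step bounded by the sampling interval.
#'
#' @param kin [sigb_kinetics()] parameters.
#' @param op [sigb_operon()] parameters.
#' @param input a `phos_input` (see [phos_step()], [sample_gamma_ou()]).
#' @param times output time grid (hr), or `NULL` to use
#'   `seq(0, horizon, by = 0.01)`.
#' @param horizon simulation horizon (hr) when `times` is `NULL`.
#' @param init named species state (uM); default is the unstressed steady
#'   state at `P_T = input$fun(0)`.
#' @param rtol,atol solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`, an
#'   adaptive stiff/non-stiff switching solver).
#' @return A data.frame of class `sigb_traj` with columns `time`, the nine
#'   species, integrated totals `B_T`, `RsbW_T`, `RsbV_T`, free phosphatase
#'   `P`, synthesis rate `vB` and the input `P_T`. Parameters and input are
#'   attached as attributes.
#' @export
sigb_simulate <- function(kin, op, input, times = NULL, horizon = 10,
                          init = NULL, rtol = 1e-8, atol = 1e-10,
                          method = "lsoda") {
  if (is.null(times)) times <- seq(0, horizon, by = 0.01)
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  # default: rest at the pre-input steady state (limit from below, so a
  # step at t = times[1] starts from its pre-step level)
  if (is.null(init)) init <- steady_state(kin, op, input$fun(times[1] - 1e-9))
  y0 <- c(init[sigb_species()], species_totals(init))
  names(y0) <- c(sigb_species(), sigb_totals_names())

  if (input$kind == "trajectory") {
    out <- core_ode(y0, times, kin, op, input, rtol, atol, method,
                    hmax = input$params$dt %||% median(diff(input$grid$time)))
  } else {
    brk <- input_breakpoints(input)
    brk <- brk[brk > times[1] & brk < max(times)]
    seg <- sort(unique(c(times[1], brk, max(times))))
    pieces <- list()
    ycur <- y0
    for (i in seq_len(length(seg) - 1)) {
      tt <- sort(unique(c(seg[i], times[times > seg[i] & times < seg[i + 1]],
                          seg[i + 1])))
      # freeze the input on the closed-open segment [seg_i, seg_{i+1})
      seg_fun <- input$fun
      seg_input <- new_phos_input(input$kind, function(t)
        seg_fun(pmin(pmax(t, seg[i]), seg[i + 1] - 1e-9)), params = input$params)
      o <- core_ode(ycur, tt, kin, op, seg_input, rtol, atol, method, NULL)
      ycur <- o[nrow(o), 2:13]
      pieces[[i]] <- if (i > 1) o[-1, , drop = FALSE] else o
    }
    out <- do.call(rbind, pieces)
  }
  d <- as.data.frame(out)
  if (min(d[, sigb_species()]) < -1e-8)
    warning("negative concentrations beyond tolerance in trajectory")
  d[sigb_species()][d[sigb_species()] < 0] <- 0
  d$P_T <- input$fun(d$time)
  d <- d[d$time %in% times | seq_len(nrow(d)) %in% c(1, nrow(d)), ]
  structure(d, class = c("sigb_traj", "data.frame"),
            kinetics = kin, operon = op, input = input,
            seed = input$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Steady state of the network at constant phosphatase
#'
#' Integrates the system for `200 / k_deg` hours at constant `P_T` and
#' refines the endpoint with a damped Newton iteration on the mass-action
#' rhs (numerical Jacobian). Convergence requires the infinity norm of the
#' rhs below `tol`.
#'
#' @param kin,op parameter objects.
#' @param P_T constant total phosphatase (uM).
#' @param init optional named starting state; default all species zero.
#' @param tol convergence tolerance on the rhs (uM hr^-1).
#' @return Named species vector with attributes `rhs_norm` and `totals`.
#' @export
steady_state <- function(kin, op, P_T, init = NULL, tol = 1e-8) {
  stopifnot(P_T >= 0)
  if (op$v0 == 0 && is.null(init)) {
    y <- sigb_state()
    return(structure(y, rhs_norm = 0, totals = species_totals(y)))
  }
  y0 <- if (is.null(init)) sigb_state() else init[sigb_species()]
  y0c <- c(y0, species_totals(y0))
  names(y0c) <- c(sigb_species(), sigb_totals_names())
  t_long <- 200 / kin$k_deg
  o <- core_ode(y0c, c(0, t_long / 2, t_long), kin, op, phos_step(P_T, P_T),
                rtol = 1e-8, atol = 1e-10, method = "lsoda", hmax = NULL)
  y <- pmax(o[nrow(o), 1 + seq_along(sigb_species())], 0)
  names(y) <- sigb_species()
  y <- newton_refine(y, kin, op, P_T, tol)
  res <- max(abs(sigb_rhs(y, kin, op, P_T)))
  if (res > tol)
    stop(sprintf(paste0("steady state did not converge (|rhs| = %.3g) at ",
                        "P_T = %g, lambda_W = %g, lambda_V = %g"),
                 res, P_T, op$lambda_W, op$lambda_V))
  structure(y, rhs_norm = res, totals = species_totals(y))
}

#' Direct root solve of the steady-state equations
#'
#' Damped Newton iteration on `rhs = 0` from a user-supplied start; used
#' as the algebraic route independent of long-horizon integration.
#'
#' @param kin,op,P_T as in [steady_state()].
#' @param start named species vector to start from.
#' @param tol convergence tolerance (uM hr^-1).
#' @return Named species vector at the root.
#' @export
steady_state_root <- function(kin, op, P_T, start, tol = 1e-10) {
  y <- newton_refine(start[sigb_species()], kin, op, P_T, tol)
  if (max(abs(sigb_rhs(y, kin, op, P_T))) > tol * 100)
    stop("Newton root solve failed to converge")
  y
}

newton_refine <- function(y, kin, op, P_T, tol, max_iter = 100) {
  fn <- function(x) unname(sigb_rhs(setNames(pmax(x, 0), sigb_species()),
                                    kin, op, P_T))
  x <- pmax(as.numeric(y), 0)
  fx <- fn(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) break
    J <- num_jacobian(fn, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn_new <- fn(xn)
      if (sum(fn_new^2) < sum(fx^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (sum(fn_new^2) >= sum(fx^2)) break
    x <- xn; fx <- fn_new
  }
  setNames(pmax(x, 0), sigb_species())
}

num_jacobian <- function(fn, x, rel = 1e-7) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Write or read a simulated trajectory
#'
#' Tab-separated text with a header (`time_hr`, then the species and
#' derived columns); parameters and seed go to a YAML sidecar
#' (`<path>.meta.yml`).
#'
#' @param traj a `sigb_traj`.
#' @param path file path for the table.
#' @return `read_trajectory()` returns a data.frame (attributes restored
#'   from the sidecar when present).
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  names(d)[names(d) == "time"] <- "time_hr"
  write.table(format(d, digits = 17, trim = TRUE, scientific = NA), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  kin <- attr(traj, "kinetics"); op <- attr(traj, "operon")
  meta <- list(parameters = c(unclass(kin), unclass(op)),
               seed = attr(traj, "seed"),
               input_kind = attr(traj, "input")$kind)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.delim(path)
  names(d)[names(d) == "time_hr"] <- "time"
  meta_path <- paste0(path, ".meta.yml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(d, "meta") <- meta
  }
  d
}
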