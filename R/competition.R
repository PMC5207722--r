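# RNA-polymerase competition: mechanistic sigma-A/sigma-B holoenzyme model
# with explicit promoter binding, and the phenomenological three-sigma
# (sigma-A, sigma-B, sigma-W) model with negative- or positive-feedback
# post-translational regulation of the stress factors.

#' Competition-model parameters
#'
#' Association/dissociation constants for sigma-factor/RNA-polymerase and
#' holoenzyme/promoter binding, total polymerase, target promoter sites
#' and total housekeeping sigma-A. Defaults are the published values:
#' diffusion-limited association 720 uM^-1 hr^-1 throughout;
#' sigma-B-holoenzyme affinity 1.2 uM (k_db = 864 hr^-1),
#' sigma-A-holoenzyme affinity 0.02 uM (k_da = 14.4 hr^-1), promoter
#' affinity 0.1 uM (k_dpb = 72 hr^-1).
#'
#' @param k_bb,k_ba,k_bpb association constants (uM^-1 hr^-1) for
#'   sigma-B/RNApol, sigma-A/RNApol and holoenzyme/promoter.
#' @param k_db,k_da,k_dpb matching dissociation constants (hr^-1).
#' @param p_B_tot total sigma-B target promoter sites (uM).
#' @param RNApol_tot total core RNA polymerase (uM).
#' @param A_T total housekeeping sigma-A (uM).
#' @return A list of class `comp_params`.
#' @export
comp_params <- function(k_bb = 720, k_db = 864, k_ba = 720, k_da = 14.4,
                        k_bpb = 720, k_dpb = 72, p_B_tot = 0.05,
                        RNApol_tot = 10, A_T = 10) {
  cp <- list(k_bb = k_bb, k_db = k_db, k_ba = k_ba, k_da = k_da,
             k_bpb = k_bpb, k_dpb = k_dpb, p_B_tot = p_B_tot,
             RNApol_tot = RNApol_tot, A_T = A_T)
  stopifnot(all(vapply(cp, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(cp, class = "comp_params")
}

comp_species <- function() c(sigb_species(), "RsigA", "RsigB", "RsigBpB")

comp_parvec <- function(kin, op, comp) {
  c(core_parvec(kin, op),
    comp$k_bb, comp$k_db, comp$k_ba, comp$k_da, comp$k_bpb, comp$k_dpb,
    comp$p_B_tot, comp$RNApol_tot, comp$A_T)
}

#' Time derivative of the competition model (reference implementation)
#'
#' Extends [sigb_rhs()] with reversible sigma-B/RNApol and sigma-A/RNApol
#' holoenzyme formation and holoenzyme-promoter binding. The operon fires
#' at the basal rate `v0` plus `(v0 f / p_B_tot) * [RNApol-sigB-pB]`, so
#' full promoter occupancy recovers the fold change `f`. Free polymerase,
#' free sigma-A and free promoter follow from conservation. Dilution of
#' sigma-B holoenzymes removes the sigma-B moiety and recycles core
#' polymerase (and promoter); sigma-A species are not diluted (`A_T` is a
#' fixed total with no synthesis term).
#'
#' @param y named state over [comp_species()].
#' @param kin,op core parameters.
#' @param comp [comp_params()].
#' @param P_T total phosphatase (uM).
#' @return Named derivative vector over `comp_species()`.
#' @export
comp_rhs <- function(y, kin, op, comp, P_T) {
  RsigA <- y[["RsigA"]]; RsigB <- y[["RsigB"]]; RsigBpB <- y[["RsigBpB"]]
  Rfree <- comp$RNApol_tot - RsigA - RsigB - RsigBpB
  sigA <- comp$A_T - RsigA
  pB <- comp$p_B_tot - RsigBpB
  prod <- op$v0 + op$v0 * op$f * RsigBpB / comp$p_B_tot
  op_const <- sigb_operon(v0 = prod, f = 0, K = op$K,
                          lambda_W = op$lambda_W, lambda_V = op$lambda_V)
  d <- sigb_rhs(y[sigb_species()], kin, op_const, P_T)
  rA <- comp$k_ba * sigA * Rfree - comp$k_da * RsigA
  rB <- comp$k_bb * y[["sigB"]] * Rfree - comp$k_db * RsigB
  rP <- comp$k_bpb * RsigB * pB - comp$k_dpb * RsigBpB
  d[["sigB"]] <- d[["sigB"]] - rB
  c(d, RsigA = rA,
    RsigB = rB - rP - kin$k_deg * RsigB,
    RsigBpB = rP - kin$k_deg * RsigBpB)
}

comp_ode <- function(y0, times, kin, op, comp, input, rtol, atol, hmax) {
  forc <- input_forcing(input, max(times))
  out <- deSolve::ode(y = y0, times = times, parms = comp_parvec(kin, op, comp),
                      func = "sigb_comp_derivs", dllname = "sigbnet",
                      initfunc = "sigb_comp_initmod", initforc = "sigb_initforc",
                      forcings = forc, fcontrol = list(method = "linear", rule = 2),
                      nout = 5, outnames = c("P", "prod", "Rfree", "sigA", "pB"),
                      rtol = rtol, atol = atol, method = "lsoda",
                      maxsteps = 100000, hmax = if (is.null(hmax)) Inf else hmax)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration failed near t = ", max(out[, "time"]), " hr")
  out
}

#' Simulate the sigma-A/sigma-B competition model
#'
#' As [sigb_simulate()] but for the extended state including the
#' holoenzymes `RsigA`, `RsigB` and the promoter-bound `RsigBpB`. Adds
#' the target promoter activity `[RNApol-sigB-pB] / p_B_tot`.
#'
#' @inheritParams sigb_simulate
#' @param comp [comp_params()].
#' @return Data frame of class `comp_traj`.
#' @export
comp_simulate <- function(kin, op, comp, input, times = NULL, horizon = 10,
                          init = NULL, rtol = 1e-8, atol = 1e-10) {
  if (is.null(times)) times <- seq(0, horizon, by = 0.01)
  if (is.null(init))
    init <- comp_steady_state(kin, op, comp, input$fun(times[1] - 1e-9))
  tot <- species_totals(init[sigb_species()])
  tot[["B_T"]] <- tot[["B_T"]] + init[["RsigB"]] + init[["RsigBpB"]]
  y0 <- c(init[comp_species()], tot)
  names(y0) <- c(comp_species(), sigb_totals_names())
  hmax <- if (input$kind == "trajectory")
    input$params$dt %||% median(diff(input$grid$time)) else NULL
  if (input$kind == "trajectory" || length(input_breakpoints(input)) == 0 ||
      all(input_breakpoints(input) <= times[1])) {
    out <- comp_ode(y0, times, kin, op, comp, input, rtol, atol, hmax)
  } else {
    stop("deterministic inputs with interior breakpoints are not supported ",
         "for the competition model; shift the step to t = 0")
  }
  d <- as.data.frame(out)
  d$P_T <- input$fun(d$time)
  d$target_activity <- d$RsigBpB / comp$p_B_tot
  structure(d, class = c("comp_traj", "data.frame"),
            kinetics = kin, operon = op, comp = comp, input = input,
            seed = input$seed)
}

#' Steady state of the competition model
#'
#' Long-horizon integration at constant phosphatase followed by damped
#' Newton refinement of the 12-species rhs.
#'
#' @inheritParams comp_simulate
#' @param P_T constant total phosphatase (uM).
#' @param tol convergence tolerance (uM hr^-1).
#' @return Named state over [comp_species()].
#' @export
comp_steady_state <- function(kin, op, comp, P_T, tol = 1e-8) {
  y0 <- setNames(numeric(12), comp_species())
  y0c <- c(y0, B_T = 0, RsbW_T = 0, RsbV_T = 0)
  t_long <- 200 / kin$k_deg
  o <- comp_ode(y0c, c(0, t_long / 2, t_long), kin, op, comp,
                phos_step(P_T, P_T), rtol = 1e-8, atol = 1e-10, hmax = NULL)
  y <- pmax(o[nrow(o), 1 + seq_along(comp_species())], 0)
  names(y) <- comp_species()
  fn <- function(x) unname(comp_rhs(setNames(pmax(x, 0), comp_species()),
                                    kin, op, comp, P_T))
  x <- as.numeric(y); fx <- fn(x)
  for (it in 1:60) {
    if (max(abs(fx)) < tol) break
    J <- num_jacobian(fn, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0); fn_new <- fn(xn)
      if (sum(fn_new^2) < sum(fx^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (sum(fn_new^2) >= sum(fx^2)) break
    x <- xn; fx <- fn_new
  }
  y <- setNames(pmax(x, 0), comp_species())
  if (max(abs(fn(x))) > tol)
    stop("competition steady state did not converge at P_T = ", P_T)
  y
}

#' Stochastic competition run over sigma-A levels
#'
#' Simulates the competition model under gamma-OU phosphatase bursts at
#' each total sigma-A level, reusing the same input realizations across
#' levels (paired comparison), and summarizes pulse amplitudes of the
#' target promoter activity and of free sigma-B, plus the time-averaged
#' target activity.
#'
#' @param kin,op,comp model parameters (`comp$A_T` is overridden).
#' @param A_T_values total sigma-A levels (uM), within the 5-15 uM range
#'   the model is built for.
#' @param bp [burst_params()] for the phosphatase input.
#' @param n_traces traces per sigma-A level.
#' @param seed master seed.
#' @param min_prominence_act,min_prominence_sig,min_separation pulse
#'   detection settings (occupancy / uM / hr).
#' @return Data frame: one row per `A_T` with mean pulse amplitudes
#'   (target activity and free sigma-B), pulse frequency, and mean target
#'   activity.
#' @export
competition_stochastic_run <- function(kin = sigb_kinetics(),
                                       op = sigb_operon(),
                                       comp = comp_params(),
                                       A_T_values = c(9, 12),
                                       bp = burst_params(), n_traces = 10,
                                       seed = 1,
                                       min_prominence_act = 0.05,
                                       min_prominence_sig = 0.05,
                                       min_separation = 0.5) {
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_traces))
  inputs <- lapply(sub_seeds, function(s) {
    b <- bp; b$seed <- s; sample_gamma_ou(b)
  })
  rows <- lapply(A_T_values, function(at) {
    cp <- comp; cp$A_T <- at
    init <- comp_steady_state(kin, op, cp, 0)
    sets_act <- list(); sets_sig <- list(); act_mean <- numeric(n_traces)
    for (k in seq_len(n_traces)) {
      tr <- comp_simulate(kin, op, cp, inputs[[k]], horizon = bp$T, init = init)
      sets_act[[k]] <- detect_pulses(tr$target_activity, tr$time,
                                     min_prominence_act, min_separation)
      sets_sig[[k]] <- detect_pulses(tr$sigB, tr$time,
                                     min_prominence_sig, min_separation)
      act_mean[k] <- mean(tr$target_activity[tr$time >= 1])
    }
    s_act <- ensemble_pulse_stats(sets_act, bp$T)
    s_sig <- ensemble_pulse_stats(sets_sig, bp$T)
    data.frame(A_T = at,
               amplitude_act = s_act$mean_amplitude,
               amplitude_sigB = s_sig$mean_amplitude,
               frequency = s_act$mean_frequency,
               mean_activity = mean(act_mean))
  })
  do.call(rbind, rows)
}

#' Steady-state dose response versus total sigma-A
#'
#' Free sigma-B and target promoter activity of the competition model at
#' constant phosphatase, as a function of total sigma-A.
#'
#' @param kin,op,comp model parameters.
#' @param A_T_grid total sigma-A levels (uM).
#' @param P_T constant phosphatase level (uM).
#' @return Data frame with `A_T`, `sigB`, `target_activity`, `B_T`.
#' @export
dose_response_vs_A_T <- function(kin = sigb_kinetics(), op = sigb_operon(),
                                 comp = comp_params(),
                                 A_T_grid = seq(5, 15, by = 1), P_T = 0.5) {
  rows <- lapply(A_T_grid, function(at) {
    cp <- comp; cp$A_T <- at
    ss <- comp_steady_state(kin, op, cp, P_T)
    data.frame(A_T = at, sigB = ss[["sigB"]],
               target_activity = ss[["RsigBpB"]] / comp$p_B_tot,
               B_T = ss[["sigB"]] + ss[["W2sigB"]] + ss[["RsigB"]] +
                 ss[["RsigBpB"]])
  })
  do.call(rbind, rows)
}

#' Equilibrium RNA-polymerase partition at clamped free sigma levels
#'
#' Solves the fast binding equilibrium of core polymerase with sigma-A
#' (titrated from its total), and with clamped free stress-sigma
#' concentrations (buffered by their partner-switching networks), plus
#' promoter binding of each stress holoenzyme.
#'
#' @param sig_free named vector of clamped free stress-sigma levels (uM),
#'   e.g. `c(B = 0.5)` or `c(B = 0.5, W = 1)`.
#' @param comp [comp_params()]; `A_T` is the sigma-A total.
#' @param promoter_tot promoter sites per stress sigma (uM).
#' @return List with `R_free`, `RsigA`, and per-sigma `Rsig`, `RsigP`
#'   (promoter-bound) and `activity` (promoter occupancy).
#' @export
rnapol_partition <- function(sig_free, comp = comp_params(),
                             promoter_tot = comp$p_B_tot) {
  KA <- comp$k_da / comp$k_ba
  KB <- comp$k_db / comp$k_bb
  Kp <- comp$k_dpb / comp$k_bpb
  holo <- function(R) sig_free * R / KB
  bound <- function(R) {
    h <- holo(R)
    pb <- promoter_tot * h / (Kp + h)
    list(h = h, pb = pb)
  }
  f <- function(R) {
    b <- bound(R)
    R + comp$A_T * R / (KA + R) + sum(b$h) + sum(b$pb) - comp$RNApol_tot
  }
  R <- uniroot(f, c(0, comp$RNApol_tot), tol = 1e-12)$root
  b <- bound(R)
  list(R_free = R, RsigA = comp$A_T * R / (KA + R),
       Rsig = b$h, RsigP = b$pb, activity = b$pb / promoter_tot)
}

#' Half-max constant of the sigma-B target dose response
#'
#' The free sigma-B concentration at which target promoter occupancy
#' reaches half its saturating value, at fixed competitor abundance.
#' Rising sigma-A (or sigma-W) levels draw polymerase away and increase
#' this constant.
#'
#' @param comp [comp_params()] (with the desired `A_T`).
#' @param sig_W_free additional clamped free sigma-W competing for
#'   polymerase (uM).
#' @param sig_max upper end of the scanned free-sigma-B range (uM).
#' @return `K_sigB` in uM.
#' @export
half_max_K_sigB <- function(comp = comp_params(), sig_W_free = 0,
                            sig_max = 200) {
  occ <- function(sig) {
    sf <- if (sig_W_free > 0) c(B = sig, W = sig_W_free) else c(B = sig)
    rnapol_partition(sf, comp)$activity[["B"]]
  }
  occ_max <- occ(sig_max)
  uniroot(function(s) occ(s) - occ_max / 2, c(1e-6, sig_max),
          tol = 1e-10)$root
}

#' Phenomenological free stress-sigma function
#'
#' `sigma_free = B_T / (1 + (B_T / K)^nb / P^mb)`: a non-monotonic
#' (for `nb > 0`) reduction of the partner-switching post-translational
#' response, gated by the signaling protein P. `nb = 7, mb = 5` is the
#' negative-feedback (wild-type-like) variant; `nb = 0, mb = 3` the
#' positive-feedback variant.
#'
#' @param B_T total sigma (uM).
#' @param P signaling-protein concentration (uM).
#' @param pp a [phenom_params()] object.
#' @return Free sigma concentration (uM).
#' @export
phenom_free_sigma <- function(B_T, P, pp) {
  stopifnot(all(B_T >= 0))
  if (pp$nb > 0 && any(P <= 0)) {
    if (any(P < 0)) stop("P must be non-negative")
    return(B_T * 0)  # limit P -> 0: fully sequestered
  }
  B_T / (1 + (B_T / pp$K)^pp$nb / P^pp$mb)
}

#' @rdname phenom_free_sigma
#' @param K half-max constant of the sequestration non-linearity (uM).
#' @param nb,mb exponents; use `variant` for the two published settings.
#' @param variant `"negative"` (nb 7, mb 5) or `"positive"` (nb 0, mb 3).
#' @export
phenom_params <- function(K = 5, nb = NULL, mb = NULL,
                          variant = c("negative", "positive")) {
  variant <- match.arg(variant)
  if (is.null(nb)) nb <- if (variant == "negative") 7 else 0
  if (is.null(mb)) mb <- if (variant == "negative") 5 else 3
  stopifnot(K > 0, nb >= 0, mb > 0)
  structure(list(K = K, nb = nb, mb = mb, variant = variant),
            class = "phenom_params")
}

three_sigma_rhs <- function(t, y, parlist) {
  with(parlist, {
    sigB <- phenom_free_sigma(unname(y[1]), P_B_fun(t), pp_B)
    sigW <- phenom_free_sigma(unname(y[2]), P_W, pp_W)
    part <- rnapol_partition(c(B = sigB, W = sigW), comp, promoter_tot)
    occ <- part$activity
    list(c(v0 * (1 + f * occ[["B"]]) - k_deg * y[1],
           v0 * (1 + f * occ[["W"]]) - k_deg * y[2]))
  })
}

#' Steady-state response of the three-sigma model
#'
#' Two generic stress sigma-factors (sigma-B, sigma-W) with identical
#' phenomenological post-translational regulation compete with sigma-A
#' and each other for core polymerase. Totals `B_T` and `W_T` evolve by
#' production proportional to their own promoter occupancy
#' (`v0 (1 + f occ)`) and first-order loss `k_deg`; the polymerase
#' partition is at fast equilibrium. Returns the steady state over a
#' grid of the sigma-B stress signal `P_B` at fixed `P_W`, with the
#' changes of each sigma-RNApol pool relative to the smallest `P_B`.
#'
#' @param pp_B,pp_W [phenom_params()] for the two stress factors.
#' @param comp [comp_params()]; `A_T` defaults to the published 12 uM
#'   for this analysis.
#' @param P_B_grid sigma-B signaling-protein levels (uM).
#' @param P_W fixed sigma-W signaling-protein level (uM).
#' @param v0,f,k_deg operon parameters shared by both stress modules.
#' @param promoter_tot promoter sites per stress sigma (uM).
#' @return Data frame with totals, free sigmas, activities, polymerase
#'   pools (`RsigA`, `RsigB`, `RsigW`, `R_free`) and deltas
#'   (`dRsigA`, `dRsigW`, `dRsigB`, `dR_free`) vs the smallest `P_B`.
#' @export
three_sigma_response <- function(pp_B = phenom_params(),
                                 pp_W = phenom_params(),
                                 comp = comp_params(A_T = 12),
                                 P_B_grid = seq(0.5, 3, by = 0.25),
                                 P_W = 2, v0 = 0.4, f = 30, k_deg = 0.7,
                                 promoter_tot = comp$p_B_tot) {
  rows <- lapply(P_B_grid, function(pb) {
    par <- list(pp_B = pp_B, pp_W = pp_W, comp = comp,
                promoter_tot = promoter_tot, P_B_fun = function(t) pb,
                P_W = P_W, v0 = v0, f = f, k_deg = k_deg)
    t_long <- 200 / k_deg
    o <- deSolve::ode(c(B_T = v0 / k_deg, W_T = v0 / k_deg),
                      c(0, t_long), three_sigma_rhs, par, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
    y <- o[nrow(o), 2:3]
    # Newton polish on the 2-d fixed point
    fn <- function(x) unlist(three_sigma_rhs(0, x, par))
    for (i in 1:20) {
      fx <- fn(y)
      if (max(abs(fx)) < 1e-10) break
      J <- num_jacobian(fn, y)
      st <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(st)) break
      y <- pmax(y + st, 0)
    }
    sigB <- phenom_free_sigma(unname(y[1]), pb, pp_B)
    sigW <- phenom_free_sigma(unname(y[2]), P_W, pp_W)
    part <- rnapol_partition(c(B = sigB, W = sigW), comp, promoter_tot)
    data.frame(P_B = pb, B_T = unname(y[1]), W_T = unname(y[2]),
               sigB_free = sigB, sigW_free = sigW,
               activity_B = part$activity[["B"]],
               activity_W = part$activity[["W"]],
               RsigA = part$RsigA,
               RsigB = part$Rsig[["B"]] + part$RsigP[["B"]],
               RsigW = part$Rsig[["W"]] + part$RsigP[["W"]],
               R_free = part$R_free)
  })
  d <- do.call(rbind, rows)
  d$dRsigA <- d$RsigA - d$RsigA[1]
  d$dRsigW <- d$RsigW - d$RsigW[1]
  d$dRsigB <- d$RsigB - d$RsigB[1]
  d$dR_free <- d$R_free - d$R_free[1]
  d
}

#' Simulate the three-sigma model under a time-varying stress signal
#'
#' @param pp_B,pp_W,comp,P_W,v0,f,k_deg,promoter_tot as in
#'   [three_sigma_response()].
#' @param P_B_input a `phos_input` giving P_B(t) (uM).
#' @param times output grid (hr).
#' @return Data frame with time, totals, free sigmas and activities.
#' @export
three_sigma_simulate <- function(pp_B = phenom_params(),
                                 pp_W = phenom_params(),
                                 comp = comp_params(A_T = 12),
                                 P_B_input, times = seq(0, 15, 0.02),
                                 P_W = 2, v0 = 0.4, f = 30, k_deg = 0.7,
                                 promoter_tot = comp$p_B_tot) {
  par <- list(pp_B = pp_B, pp_W = pp_W, comp = comp,
              promoter_tot = promoter_tot, P_B_fun = P_B_input$fun,
              P_W = P_W, v0 = v0, f = f, k_deg = k_deg)
  ss <- three_sigma_response(pp_B, pp_W, comp,
                             P_B_grid = P_B_input$fun(times[1] - 1e-9),
                             P_W = P_W, v0 = v0, f = f, k_deg = k_deg,
                             promoter_tot = promoter_tot)
  o <- deSolve::ode(c(B_T = ss$B_T[1], W_T = ss$W_T[1]), times,
                    three_sigma_rhs, par, method = "lsoda",
                    rtol = 1e-8, atol = 1e-10)
  d <- as.data.frame(o)
  d$sigB_free <- phenom_free_sigma(d$B_T, P_B_input$fun(d$time), pp_B)
  d$sigW_free <- phenom_free_sigma(d$W_T, P_W, pp_W)
  d$activity_B <- vapply(seq_len(nrow(d)), function(i)
    rnapol_partition(c(B = d$sigB_free[i], W = d$sigW_free[i]), comp,
                     promoter_tot)$activity[["B"]], numeric(1))
  d
}
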