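# Decoupled post-translational / transcriptional response analysis:
# response curves, logarithmic gain, feedback-region classification and the
# phosphatase threshold for pulsing.

#' Post-translational response curve F_P(B_T; P_T)
#'
#' Free sigma-B at steady state as a function of the total operon
#' expression level, with autoregulation disabled: for each total `B_T`
#' the operon is run at the constant synthesis rate `v = k_deg * B_T`
#' (which yields exactly that `B_T` at steady state, with `RsbW_T` and
#' `RsbV_T` in the fixed proportions `lambda_W`, `lambda_V`) while the
#' total phosphatase is held at `P_T`. Steady states are continued along
#' the (monotone in `B_T`) synthesis-rate parameterization with warm
#' starts, so folds of the curve in `sigma` are handled naturally.
#'
#' @param kin,op parameter objects (`op` supplies `lambda_W`, `lambda_V`).
#' @param P_T total phosphatase (uM) held fixed along the curve.
#' @param B_T_range range of total sigma-B to scan (uM).
#' @param n number of (log-spaced) points.
#' @return A data.frame of class `response_curve` with columns `B_T` and
#'   `sigB`; failed points are dropped with a warning.
#' @export
post_translational_response <- function(kin, op, P_T,
                                        B_T_range = c(0.05, 40), n = 80) {
  stopifnot(all(B_T_range > 0), n >= 2)
  B_T <- exp(seq(log(B_T_range[1]), log(B_T_range[2]), length.out = n))
  sig <- rep(NA_real_, n)
  start <- NULL
  for (i in seq_len(n)) {
    s <- tryCatch(fp_point(kin, op, P_T, B_T[i], start),
                  error = function(e) NULL)
    if (!is.null(s)) {
      sig[i] <- s[["sigB"]]
      start <- s
    }
  }
  if (anyNA(sig)) warning(sum(is.na(sig)), " steady-state point(s) dropped")
  structure(data.frame(B_T = B_T[!is.na(sig)], sigB = sig[!is.na(sig)]),
            class = c("response_curve", "data.frame"),
            role = "post_translational", P_T = P_T,
            lambda_W = op$lambda_W, lambda_V = op$lambda_V)
}

# single constant-synthesis steady state with prescribed total B_T
fp_point <- function(kin, op, P_T, B_T, start = NULL) {
  op_const <- sigb_operon(v0 = kin$k_deg * B_T, f = 0, K = op$K,
                          lambda_W = op$lambda_W, lambda_V = op$lambda_V)
  if (!is.null(start)) {
    s <- tryCatch(steady_state_root(kin, op_const, P_T, start, tol = 1e-10),
                  error = function(e) NULL)
    # warm-started Newton can converge to an unphysical branch; accept only
    # if the implied total matches the prescribed one
    if (!is.null(s) && abs(species_totals(s)[["B_T"]] - B_T) < 1e-6 * B_T)
      return(s)
  }
  steady_state(kin, op_const, P_T)
}

#' Transcriptional response curve F_T(sigma)
#'
#' Total operon expression at steady state as a function of free sigma-B,
#' from the closed form `B_T = v0 (1 + f sigma / (K + sigma)) / k_deg`.
#'
#' @param op,kin parameter objects (`kin` supplies `k_deg`).
#' @param sigma_grid free sigma-B values (uM), non-negative.
#' @return A `response_curve` with columns `sigB` and `B_T`.
#' @export
transcriptional_response <- function(op, kin, sigma_grid) {
  stopifnot(all(sigma_grid >= 0))
  structure(data.frame(sigB = sigma_grid,
                       B_T = operon_rate(sigma_grid, op) / kin$k_deg),
            class = c("response_curve", "data.frame"),
            role = "transcriptional")
}

#' Closed-loop steady state from the decoupled responses
#'
#' Solves the intersection of the post-translational and transcriptional
#' responses, `sigma = F_P(F_T(sigma); P_T)`, by bracketing the fixed
#' point in log-sigma. This is an independent route to the full-model
#' steady state.
#'
#' @param kin,op,P_T as in [steady_state()].
#' @param sigma_bounds log10 search bracket for free sigma-B (uM).
#' @return Named vector `c(sigB, B_T)`.
#' @export
closed_loop_steady_state <- function(kin, op, P_T,
                                     sigma_bounds = c(1e-7, 50)) {
  g <- function(ls) {
    sig <- exp(ls)
    B_T <- operon_rate(sig, op) / kin$k_deg
    s <- fp_point(kin, op, P_T, B_T)
    log(max(s[["sigB"]], 1e-300)) - ls
  }
  lo <- log(sigma_bounds[1]); hi <- log(sigma_bounds[2])
  ls <- seq(lo, hi, length.out = 25)
  gv <- vapply(ls, g, numeric(1))
  i <- which(diff(sign(gv)) != 0)
  if (!length(i)) stop("no intersection of F_P and F_T in the scanned range")
  r <- uniroot(g, c(ls[i[1]], ls[i[1] + 1]), tol = 1e-12)
  sig <- exp(r$root)
  c(sigB = sig, B_T = operon_rate(sig, op) / kin$k_deg)
}

#' Logarithmic gain of a response curve
#'
#' `LG = d log(ordinate) / d log(abscissa)` by centered finite differences,
#' either on an interpolated sampled curve or (for the post-translational
#' response) recomputed exactly from the model at `B_T (1 +/- h)`.
#'
#' @param curve a `response_curve` from [post_translational_response()],
#'   or `NULL` to use the exact model route (supply `kin`, `op`, `P_T`).
#' @param at_B_T abscissa value at which to evaluate the gain (uM).
#' @param h relative half-step of the centered difference (log-space).
#' @param kin,op,P_T model context for the exact route.
#' @return The dimensionless gain; `NA` if the ordinate vanishes.
#' @export
logarithmic_gain <- function(curve = NULL, at_B_T, h = 0.01,
                             kin = NULL, op = NULL, P_T = NULL) {
  if (is.null(curve)) {
    s_lo <- fp_point(kin, op, P_T, at_B_T * (1 - h))
    s_hi <- fp_point(kin, op, P_T, at_B_T * (1 + h))
    lo <- s_lo[["sigB"]]; hi <- s_hi[["sigB"]]
    if (lo <= 0 || hi <= 0) return(NA_real_)
    return((log(hi) - log(lo)) / (log(1 + h) - log(1 - h)))
  }
  x <- curve[[1]]; y <- curve[[2]]
  if (at_B_T < min(x) || at_B_T > max(x))
    stop("at_B_T outside the curve support")
  keep <- y > 0
  if (sum(keep) < 4) return(NA_real_)
  lf <- stats::splinefun(log(x[keep]), log(y[keep]), method = "natural")
  la <- log(at_B_T)
  dh <- log(1 + h)
  (lf(la + dh) - lf(la - dh)) / (2 * dh)
}

#' Classify the feedback region of a (lambda_W, lambda_V) pair
#'
#' Evaluates the logarithmic gain of the post-translational response at the
#' closed-loop steady state and labels the effective feedback: `"I"`
#' (positive, LG > dead zone), `"II"` (negative, LG < -dead zone) or
#' `"III"` (non-responsive, |LG| within the dead zone).
#'
#' In the strong-binding limit the non-responsive region is where free
#' sigma-B is identically zero along the whole post-translational curve;
#' with the finite (5 nM) complex affinity a small leakage remains, which
#' can carry a residual negative log-gain at the operating point even
#' though the response is negligible in absolute terms. A point is
#' therefore labelled `"III"` either when |LG| is inside the dead zone or
#' when free sigma-B never exceeds `resp_floor` of total sigma-B anywhere
#' on the scanned curve (sequestration is essentially complete for every
#' operon level).
#'
#' @param lambda_W,lambda_V relative synthesis rates.
#' @param kin,op parameter objects (the lambdas in `op` are overridden).
#' @param P_T_ref reference phosphatase level (uM).
#' @param dead_zone |LG| at or below this is "no feedback".
#' @param resp_floor responsiveness floor: max of sigma-B/B_T along the
#'   curve below this marks the non-responsive region.
#' @return List with `label`, `LG_P` and `responsiveness`
#'   (max of free/total sigma-B along the curve).
#' @export
classify_region <- function(lambda_W, lambda_V, kin = sigb_kinetics(),
                            op = sigb_operon(), P_T_ref = 0.5,
                            dead_zone = 0.05, resp_floor = 0.15) {
  op <- sigb_operon(v0 = op$v0, f = op$f, K = op$K,
                    lambda_W = lambda_W, lambda_V = lambda_V)
  cl <- closed_loop_steady_state(kin, op, P_T_ref)
  lg <- logarithmic_gain(NULL, cl[["B_T"]], kin = kin, op = op, P_T = P_T_ref)
  fp <- post_translational_response(kin, op, P_T_ref,
                                    B_T_range = c(op$v0 / kin$k_deg, 40),
                                    n = 40)
  resp <- max(fp$sigB / fp$B_T)
  label <- if (is.na(lg) || abs(lg) <= dead_zone || resp < resp_floor) "III"
           else if (lg > 0) "I" else "II"
  list(label = label, LG_P = lg, responsiveness = resp)
}

#' Feedback-region map over the synthesis-ratio plane
#'
#' @param lambda_W_grid,lambda_V_grid grid values.
#' @param kin,op,P_T_ref,dead_zone as in [classify_region()].
#' @return Data frame with `lambda_W`, `lambda_V`, `LG_P`, `label`.
#' @export
region_map <- function(lambda_W_grid, lambda_V_grid, kin = sigb_kinetics(),
                       op = sigb_operon(), P_T_ref = 0.5, dead_zone = 0.05,
                       resp_floor = 0.15) {
  g <- expand.grid(lambda_W = lambda_W_grid, lambda_V = lambda_V_grid)
  res <- lapply(seq_len(nrow(g)), function(i) {
    cl <- tryCatch(classify_region(g$lambda_W[i], g$lambda_V[i], kin, op,
                                   P_T_ref, dead_zone, resp_floor),
                   error = function(e) list(label = NA_character_,
                                            LG_P = NA_real_))
    data.frame(lambda_W = g$lambda_W[i], lambda_V = g$lambda_V[i],
               LG_P = cl$LG_P, label = cl$label)
  })
  do.call(rbind, res)
}

#' Analytic region boundaries
#'
#' The strong-binding approximation of the network gives two lines in the
#' (lambda_V, lambda_W) plane separating the feedback regions:
#' `lambda_W = 2 (1 + lambda_V k_deg / k_k)` (below it RsbW cannot bind
#' all partners even with fully active kinase flux: positive feedback) and
#' `lambda_W = 2 + lambda_V` (above it RsbW saturates all partners
#' regardless of phosphorylation: no response).
#'
#' @param kin [sigb_kinetics()]; uses `k_deg` and `k_k1`.
#' @return List of two functions of `lambda_V`: `lower(lambda_V)` and
#'   `upper(lambda_V)`.
#' @export
region_boundaries <- function(kin = sigb_kinetics()) {
  list(lower = function(lambda_V) 2 * (1 + lambda_V * kin$k_deg / kin$k_k1),
       upper = function(lambda_V) 2 + lambda_V)
}

#' Pulse amplitude of a step response
#'
#' Simulates a step in total phosphatase from the unstressed steady state
#' and returns the free sigma-B excursion (max minus initial value).
#'
#' @param kin,op parameter objects.
#' @param P_T step target (uM).
#' @param horizon simulation horizon (hr).
#' @param init optional pre-computed unstressed steady state.
#' @return Amplitude in uM, with the trajectory as attribute `traj`.
#' @export
step_amplitude <- function(kin, op, P_T, horizon = 15, init = NULL) {
  tr <- sigb_simulate(kin, op, phos_step(P_T), horizon = horizon, init = init)
  structure(max(tr$sigB) - tr$sigB[1], traj = tr)
}

#' Phosphatase threshold of the pulse response
#'
#' Pulse amplitudes are a threshold-linear function of the step size: the
#' numeric threshold is located by bisection on the step level at which
#' the amplitude first exceeds `amplitude_floor`. Also evaluates the
#' strong-binding analytic approximation
#' `P* = v0 k_k (lambda_W/2 - 1 - lambda_W k_deg/k_k) / (k_p / k_deg)`
#' at the same parameters.
#'
#' @param kin,op parameter objects.
#' @param amplitude_floor amplitude defining "pulsing" (uM); default 1% of
#'   the pre-step total sigma-B.
#' @param P_max upper end of the scanned step range (uM).
#' @param tol bisection tolerance on the threshold (uM).
#' @return List with `threshold` (numeric, uM), `analytic` (uM) and
#'   `basal_B_T` (= v0 / k_deg, uM).
#' @export
phosphatase_threshold <- function(kin, op, amplitude_floor = NULL,
                                  P_max = 0.5, tol = 1e-4) {
  init <- steady_state(kin, op, 0)
  if (is.null(amplitude_floor))
    amplitude_floor <- 0.01 * species_totals(init)[["B_T"]]
  amp <- function(P) step_amplitude(kin, op, P, init = init)
  lo <- 0; hi <- P_max
  if (amp(hi) < amplitude_floor)
    stop("no pulsing threshold found below P_max = ", P_max, " uM")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (amp(mid) >= amplitude_floor) hi <- mid else lo <- mid
  }
  list(threshold = (lo + hi) / 2,
       analytic = analytic_threshold(kin, op),
       basal_B_T = op$v0 / kin$k_deg)
}

#' @rdname phosphatase_threshold
#' @export
analytic_threshold <- function(kin, op) {
  op$v0 * kin$k_k1 * (op$lambda_W / 2 - 1 - op$lambda_W * kin$k_deg / kin$k_k1) /
    (kin$k_p / kin$k_deg)
}
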