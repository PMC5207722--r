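#' Species of the core network state
#'
#' Explicit ODE species of the partner-switching network, in the order used
#' throughout the package: free sigma-B, RsbW monomer (`W`), RsbW dimer
#' (`W2`), unphosphorylated and phosphorylated RsbV (`V`, `VP`), the
#' complexes `W2sigB`, `W2V`, `W2V2`, and the phosphatase-substrate complex
#' `VPP`. Free phosphatase `P` is not integrated; it follows from the
#' conservation `P = P_T(t) - VPP`.
#'
#' @return Character vector of species names.
#' @export
sigb_species <- function() {
  c("sigB", "W", "W2", "V", "VP", "W2sigB", "W2V", "W2V2", "VPP")
}

# names of the auxiliary integrated totals
sigb_totals_names <- function() c("B_T", "RsbW_T", "RsbV_T")

#' Construct a network state vector
#'
#' @param ... named species concentrations (uM); unnamed species default
#'   to 0. Names must be a subset of [sigb_species()].
#' @return Named numeric vector over [sigb_species()].
#' @export
sigb_state <- function(...) {
  vals <- c(...)
  y <- setNames(numeric(9), sigb_species())
  if (length(vals)) {
    unknown <- setdiff(names(vals), sigb_species())
    if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
    y[names(vals)] <- vals
  }
  if (any(y < 0)) stop("concentrations must be non-negative")
  y
}

#' Species totals implied by a state
#'
#' Sums each conserved moiety over its free and complexed forms: total
#' sigma-B, total RsbW (monomer units) and total RsbV.
#'
#' @param y named state vector over [sigb_species()].
#' @return Named vector `c(B_T, RsbW_T, RsbV_T)`.
#' @export
species_totals <- function(y) {
  c(B_T = unname(y["sigB"] + y["W2sigB"]),
    RsbW_T = unname(y["W"] + 2 * (y["W2"] + y["W2sigB"] + y["W2V"] + y["W2V2"])),
    RsbV_T = unname(y["V"] + y["W2V"] + 2 * y["W2V2"] + y["VP"] + y["VPP"]))
}

#' Time derivative of the core network (reference implementation)
#'
#' Assembles the mass-action right-hand side from the ten elementary
#' reactions: RsbW dimerization, RsbW_2 binding of RsbV (twice) and
#' sigma-B, partner displacement, RsbV phosphorylation by the RsbW_2
#' kinase, phosphatase binding and catalysis, uniform
#' degradation/dilution at `k_deg`, and operon synthesis at rates
#' `v_B`, `lambda_W * v_B`, `lambda_V * v_B`. Free phosphatase is
#' `max(P_T - VPP, 0)`.
#'
#' This R implementation is the readable reference; simulations run the
#' identical compiled version. A constant synthesis rate (autoregulation
#' disabled) is obtained with `f = 0`.
#'
#' @param y named state over [sigb_species()].
#' @param kin [sigb_kinetics()] parameters.
#' @param op [sigb_operon()] parameters.
#' @param P_T total phosphatase concentration (uM).
#' @return Named derivative vector (uM hr^-1) over [sigb_species()].
#' @export
sigb_rhs <- function(y, kin, op, P_T) {
  if (P_T < 0) stop("P_T must be non-negative")
  sigB <- y[["sigB"]]; W <- y[["W"]]; W2 <- y[["W2"]]
  V <- y[["V"]]; VP <- y[["VP"]]; W2sigB <- y[["W2sigB"]]
  W2V <- y[["W2V"]]; W2V2 <- y[["W2V2"]]; VPP <- y[["VPP"]]
  P <- max(P_T - VPP, 0)
  vB <- operon_rate(sigB, op)

  r_dim  <- kin$k_bw * W^2 - kin$k_dw * W2          # 2W <-> W2
  r1 <- kin$k_b1 * W2 * V - kin$k_d1 * W2V          # W2 + V <-> W2V
  r2 <- kin$k_b2 * W2V * V - kin$k_d2 * W2V2        # W2V + V <-> W2V2
  rk1 <- kin$k_k1 * W2V                             # W2V -> W2 + VP
  rk2 <- kin$k_k2 * W2V2                            # W2V2 -> W2V + VP
  r3 <- kin$k_b3 * W2 * sigB - kin$k_d3 * W2sigB    # W2 + sigB <-> W2sigB
  r4 <- kin$k_b4 * W2sigB * V - kin$k_d4 * W2V * sigB  # displacement
  r5 <- kin$k_b5 * VP * P - kin$k_d5 * VPP          # VP + P <-> VPP
  rp <- kin$k_p * VPP                               # VPP -> V + P

  deg <- kin$k_deg
  c(sigB = vB - r3 + r4 - deg * sigB,
    W = op$lambda_W * vB - 2 * r_dim - deg * W,
    W2 = r_dim - r1 + rk1 - r3 - deg * W2,
    V = op$lambda_V * vB - r1 - r2 - r4 + rp - deg * V,
    VP = rk1 + rk2 - r5 - deg * VP,
    W2sigB = r3 - r4 - deg * W2sigB,
    W2V = r1 - r2 + rk2 - rk1 + r4 - deg * W2V,
    W2V2 = r2 - rk2 - deg * W2V2,
    VPP = r5 - rp - deg * VPP)
}

#' Conservation residuals along a trajectory
#'
#' For each time point of a simulated trajectory, compares the species sums
#' of the four conserved moieties (sigma-B, RsbW, RsbV, phosphatase) with
#' the independently integrated totals (`B_T`, `RsbW_T`, `RsbV_T`, which
#' obey `dX_T/dt = lambda_X * v_B - k_deg * X_T`) and the prescribed input
#' `P_T(t)`. Residuals are normalized by the respective total (0 where the
#' total is below `eps`).
#'
#' @param traj a `sigb_traj` from [sigb_simulate()], or a data.frame with
#'   the species, totals and `P_T` columns.
#' @param eps totals below this are treated as zero (uM).
#' @return Data frame with columns `time`, `res_B`, `res_W`, `res_V`,
#'   `res_P`.
#' @export
conservation_residuals <- function(traj, eps = 1e-12) {
  d <- as.data.frame(traj)
  rel <- function(sum_sp, total) {
    r <- (sum_sp - total)
    ifelse(abs(total) > eps, r / total, r)
  }
  data.frame(
    time = d$time,
    res_B = rel(d$sigB + d$W2sigB, d$B_T),
    res_W = rel(d$W + 2 * (d$W2 + d$W2sigB + d$W2V + d$W2V2), d$RsbW_T),
    res_V = rel(d$V + d$W2V + 2 * d$W2V2 + d$VP + d$VPP, d$RsbV_T),
    res_P = rel(d$P + d$VPP, d$P_T))
}
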