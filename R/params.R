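#' Kinetic rate constants of the sigma-B partner-switching network
#'
#' Constructs the set of mass-action rate constants for the core network:
#' RsbW dimerization, RsbW_2 complex formation with RsbV and sigma-B,
#' partner displacement, RsbV phosphorylation/dephosphorylation, and
#' uniform degradation/dilution. Defaults are the published parameter set
#' for the wild-type network.
#'
#' @param k_bw RsbW dimerization rate constant (uM^-1 hr^-1).
#' @param k_dw RsbW_2 dissociation rate constant (hr^-1).
#' @param k_b1,k_b2,k_b3,k_b5 complex association rate constants
#'   (uM^-1 hr^-1): RsbW_2+RsbV, RsbW_2.RsbV+RsbV, RsbW_2+sigma-B and
#'   RsbV-P+phosphatase respectively.
#' @param k_d1,k_d2,k_d3,k_d5 matching dissociation rate constants (hr^-1).
#' @param k_b4 rate constant for displacement of sigma-B by RsbV in the
#'   RsbW_2.sigma-B complex (uM^-1 hr^-1).
#' @param k_d4 rate constant of the reverse displacement (uM^-1 hr^-1).
#' @param k_k1,k_k2 RsbV phosphorylation rate constants of the RsbW_2 kinase
#'   acting on RsbW_2.RsbV and RsbW_2.RsbV_2 (hr^-1).
#' @param k_p catalytic dephosphorylation rate of the phosphatase (hr^-1).
#' @param k_deg degradation/dilution rate applied to every protein and
#'   complex (hr^-1); the default corresponds to a ~1 hr doubling time.
#' @return A named list of class `sigb_kinetics`.
#' @export
#' @examples
#' kin <- sigb_kinetics()
#' kin$k_d1 / kin$k_b1   # 5 nM binding affinity of the partner complexes
sigb_kinetics <- function(k_bw = 3600, k_dw = 18,
                          k_b1 = 3600, k_b2 = 3600, k_b3 = 3600, k_b5 = 3600,
                          k_d1 = 18, k_d2 = 18, k_d3 = 18, k_d5 = 18,
                          k_b4 = 1800, k_d4 = 1800,
                          k_k1 = 36, k_k2 = 36,
                          k_p = 180, k_deg = 0.7) {
  kin <- list(k_bw = k_bw, k_dw = k_dw,
              k_b1 = k_b1, k_b2 = k_b2, k_b3 = k_b3, k_b5 = k_b5,
              k_d1 = k_d1, k_d2 = k_d2, k_d3 = k_d3, k_d5 = k_d5,
              k_b4 = k_b4, k_d4 = k_d4,
              k_k1 = k_k1, k_k2 = k_k2, k_p = k_p, k_deg = k_deg)
  # k_deg = 0 is the closed-system limit; every rate constant proper must
  # be strictly positive
  bad <- names(kin)[!vapply(kin, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                            logical(1))]
  bad <- setdiff(bad, if (is.numeric(k_deg) && k_deg >= 0) "k_deg")
  if (length(bad))
    stop("kinetic parameters must be positive scalars: ", paste(bad, collapse = ", "))
  structure(kin, class = "sigb_kinetics")
}

#' Operon synthesis parameters
#'
#' Parameters of the autoregulated sigma-B operon: basal transcription rate,
#' fold activation by sigma-B, promoter affinity and the relative synthesis
#' rates of RsbW and RsbV with respect to sigma-B.
#'
#' @param v0 basal operon synthesis rate (uM hr^-1).
#' @param f fold change of operon expression at full sigma-B activation
#'   (dimensionless); `f = 0` makes the operon constitutive.
#' @param K sigma-B/promoter binding affinity (uM).
#' @param lambda_W,lambda_V relative synthesis rates of RsbW and RsbV
#'   (dimensionless ratios to the sigma-B synthesis rate).
#' @return A named list of class `sigb_operon`.
#' @export
sigb_operon <- function(v0 = 0.4, f = 30, K = 0.2,
                        lambda_W = 4, lambda_V = 4.5) {
  stopifnot(is.numeric(v0), v0 >= 0, is.numeric(f), f >= 0,
            is.numeric(K), K > 0, lambda_W >= 0, lambda_V >= 0)
  structure(list(v0 = v0, f = f, K = K,
                 lambda_W = lambda_W, lambda_V = lambda_V),
            class = "sigb_operon")
}

#' Default parameter set
#'
#' Returns the published wild-type parameter values as a
#' `(kinetics, operon)` pair.
#'
#' @return A list with elements `kinetics` and `operon`.
#' @export
sigb_default_params <- function() {
  list(kinetics = sigb_kinetics(), operon = sigb_operon())
}

#' Operon synthesis rate
#'
#' Hyperbolic autoregulation of the sigma-B operon:
#' `v_B = v0 * (1 + f * sigma / (K + sigma))`.
#'
#' @param sigma free sigma-B concentration (uM), non-negative.
#' @param op an [sigb_operon()] object.
#' @return Synthesis rate in uM hr^-1.
#' @export
operon_rate <- function(sigma, op) {
  if (any(sigma < 0)) stop("free sigma-B concentration must be non-negative")
  op$v0 * (1 + op$f * sigma / (op$K + sigma))
}

param_config_keys <- function() {
  c(names(sigb_kinetics()), names(sigb_operon()))
}

#' Read or write a parameter configuration file
#'
#' Parameters are stored as YAML whose keys are the model symbol names
#' (`k_bw`, ..., `lambda_W`, `lambda_V`). Unknown keys are an error.
#'
#' @param path file path.
#' @param kin,op parameter objects to write.
#' @return `read_params_config()` returns a `list(kinetics, operon)`.
#' @export
write_params_config <- function(path, kin = sigb_kinetics(), op = sigb_operon()) {
  yaml::write_yaml(c(unclass(kin), unclass(op)), path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), param_config_keys())
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  kin_keys <- intersect(names(vals), names(sigb_kinetics()))
  op_keys <- intersect(names(vals), names(sigb_operon()))
  list(kinetics = do.call(sigb_kinetics, vals[kin_keys]),
       operon = do.call(sigb_operon, vals[op_keys]))
}

# Flattened parameter vector in the order expected by the compiled rhs.
core_parvec <- function(kin, op) {
  c(kin$k_bw, kin$k_dw, kin$k_b1, kin$k_d1, kin$k_b2, kin$k_d2,
    kin$k_b3, kin$k_d3, kin$k_b4, kin$k_d4, kin$k_b5, kin$k_d5,
    kin$k_k1, kin$k_k2, kin$k_p, kin$k_deg,
    op$v0, op$f, op$K, op$lambda_W, op$lambda_V)
}
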