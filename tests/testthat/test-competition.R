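cp_default <- comp_params()

test_that("holoenzyme affinities match the published estimates", {
  expect_equal(cp_default$k_da / cp_default$k_ba, 0.02)
  expect_equal(cp_default$k_db / cp_default$k_bb, 1.2)
  expect_equal(cp_default$k_dpb / cp_default$k_bpb, 0.1)
  expect_equal(cp_default$RNApol_tot, 10)
  expect_equal(cp_default$p_B_tot, 0.05)
})

test_that("competition trajectories conserve polymerase, sigma-A and promoter", {
  cp <- comp_params(A_T = 9)
  inp <- sample_gamma_ou(burst_params(T = 4, seed = 21))
  tr <- comp_simulate(kin_default, op_default, cp, inp, horizon = 4)
  holo <- tr$RsigA + tr$RsigB + tr$RsigBpB
  expect_lt(max(abs(tr$Rfree + holo - cp$RNApol_tot)) / cp$RNApol_tot, 1e-6)
  expect_lt(max(abs(tr$sigA + tr$RsigA - cp$A_T)) / cp$A_T, 1e-6)
  expect_lt(max(abs(tr$pB + tr$RsigBpB - cp$p_B_tot)) / cp$p_B_tot, 1e-6)
  expect_true(all(as.matrix(tr[, c("Rfree", "sigA", "pB")]) > -1e-9))
  # sigma-B bookkeeping: species sum (incl. holoenzymes) matches the
  # independently integrated total
  bsum <- tr$sigB + tr$W2sigB + tr$RsigB + tr$RsigBpB
  expect_lt(max(abs(bsum - tr$B_T) / tr$B_T), 1e-6)
})

test_that("compiled competition rhs agrees with the reference implementation", {
  ss <- comp_steady_state(kin_default, op_default, cp_default, 0.5)
  expect_lt(max(abs(comp_rhs(ss, kin_default, op_default, cp_default, 0.5))),
            1e-8)
  y <- ss * 1.3 + 0.01
  d_ref <- comp_rhs(y, kin_default, op_default, cp_default, 0.5)
  tr <- comp_simulate(kin_default, op_default, cp_default,
                      phos_step(0.5, 0.5), times = c(0, 1e-9), init = y)
  d_num <- (unlist(tr[2, comp_species()]) - y) / 1e-9
  expect_equal(unname(d_num), unname(d_ref), tolerance = 1e-4)
})

test_that("without sigma-A the polymerase pool is free of RsigA", {
  cp0 <- comp_params(A_T = 1e-9)
  ss <- comp_steady_state(kin_default, op_default, cp0, 0.5)
  expect_lt(ss[["RsigA"]], 1e-9)
  expect_gt(ss[["RsigB"]], 0)
})

test_that("wild-type free sigma-B rises with sigma-A while the no-feedback
           target activity collapses", {
  dd <- dose_response_vs_A_T(kin_default, op_default, cp_default,
                             A_T_grid = c(5, 9, 12, 15))
  expect_true(all(diff(dd$sigB) > 0))
  opn <- sigb_operon(v0 = 8.64, f = 0)
  dn <- dose_response_vs_A_T(kin_default, opn, cp_default,
                             A_T_grid = c(5, 9, 12, 15))
  expect_lt(max(abs(dn$sigB / dn$sigB[1] - 1)), 0.05)  # flat free sigma-B
  expect_true(all(diff(dn$target_activity) < 0))
  # sigma-A far above total polymerase starves the constitutive target
  dn_hi <- dose_response_vs_A_T(kin_default, opn, cp_default,
                                A_T_grid = c(25), P_T = 0.5)
  expect_lt(dn_hi$target_activity, 0.01)
})

test_that("negative feedback insulates target activity from sigma-A", {
  lg <- function(op) {
    d <- dose_response_vs_A_T(kin_default, op, cp_default,
                              A_T_grid = c(9, 12))
    abs(diff(log(d$target_activity)) / diff(log(d$A_T)))
  }
  expect_lt(lg(op_default), lg(sigb_operon(v0 = 8.64, f = 0)))
})

test_that("K_sigB grows with competitor abundance", {
  ks <- vapply(c(1e-6, 5, 9, 12), function(a)
    half_max_K_sigB(comp_params(A_T = max(a, 1e-6))), numeric(1))
  expect_true(all(diff(ks) > 0))
  # and with sigma-W at fixed sigma-A levels
  for (at in c(9, 12)) {
    ksw <- vapply(c(0, 1, 3), function(w)
      half_max_K_sigB(comp_params(A_T = at), sig_W_free = w), numeric(1))
    expect_true(all(diff(ksw) > 0))
  }
})

test_that("phenomenological free-sigma formula behaves at its limits", {
  pp <- phenom_params(variant = "negative")
  expect_equal(pp$nb, 7); expect_equal(pp$mb, 5); expect_equal(pp$K, 5)
  expect_equal(phenom_free_sigma(3, 1e9, pp), 3, tolerance = 1e-6)
  expect_equal(phenom_free_sigma(3, 0, pp), 0)
  ppp <- phenom_params(variant = "positive")
  B <- seq(0, 20, 0.25)
  fpos <- phenom_free_sigma(B, 2, ppp)
  expect_equal(fpos, B / (1 + 2^(-3)))
  expect_true(all(diff(fpos) > 0))
  # negative variant: interior maximum in B_T
  fneg <- phenom_free_sigma(B, 2, pp)
  i <- which.max(fneg)
  expect_gt(i, 2); expect_lt(i, length(B) - 1)
})

test_that("three-sigma model: negative feedback spares the other stress factor", {
  neg <- three_sigma_response(phenom_params(), phenom_params())
  expect_true(all(diff(neg$sigB_free) > 0))
  expect_true(all(diff(neg$sigW_free) > -1e-9))  # nondecreasing
  # polymerase for sigma-B drawn mainly from the sigma-A pool
  last <- nrow(neg)
  expect_gt(abs(neg$dRsigA[last]), abs(neg$dRsigW[last]))
  # accounting closes: gains and losses of the pools balance
  expect_lt(max(abs(neg$dRsigB + neg$dRsigA + neg$dRsigW + neg$dR_free)),
            1e-6)
})

test_that("three-sigma model: positive feedback lets sigma-W be suppressed", {
  pos <- three_sigma_response(phenom_params(variant = "positive"),
                              phenom_params(variant = "positive"))
  expect_true(all(diff(pos$sigW_free) < 1e-9))  # nonincreasing
  expect_true(all(diff(pos$sigB_free) > 0))
  # accounting closes here too
  expect_lt(max(abs(pos$dRsigB + pos$dRsigA + pos$dRsigW + pos$dR_free)),
            1e-6)
  # the sigma-W pool is proportionally depleted far more than under
  # negative feedback at the same stress span
  neg <- three_sigma_response(phenom_params(), phenom_params())
  last <- nrow(pos)
  expect_gt(abs(pos$dRsigW[last]) / pos$RsigW[1],
            5 * abs(neg$dRsigW[last]) / neg$RsigW[1])
})

test_that("a step in the stress signal pulses the negative-feedback model", {
  tr <- three_sigma_simulate(phenom_params(), phenom_params(),
                             P_B_input = phos_step(2.5, P0 = 0.5, t_step = 0),
                             times = seq(0, 20, 0.02))
  amp <- max(tr$sigB_free) - tr$sigB_free[1]
  expect_gt(amp, 0.1)
  # adaptive: peak clearly above the final level
  expect_gt(max(tr$sigB_free), tr$sigB_free[nrow(tr)] * 1.2)
})
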