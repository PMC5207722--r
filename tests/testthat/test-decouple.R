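test_that("transcriptional response matches its closed form", {
  sig <- seq(0, 50, by = 0.5)
  ft <- transcriptional_response(op_default, kin_default, sig)
  expect_equal(ft$B_T[1], 0.4 / 0.7, tolerance = 1e-12)
  expect_equal(max(ft$B_T), 0.4 * 31 / 0.7, tolerance = 0.02)
  expect_true(all(diff(ft$B_T) >= 0))
})

test_that("post-translational response is non-monotonic at wild-type ratios", {
  fp <- post_translational_response(kin_default, op_default, 0.5,
                                    B_T_range = c(0.1, 30), n = 50)
  i_max <- which.max(fp$sigB)
  expect_gt(i_max, 3)
  expect_lt(i_max, nrow(fp) - 3)  # interior maximum
  # stoichiometric ratios: monotone increasing, no interior maximum
  op2 <- sigb_operon(lambda_W = 2, lambda_V = 2)
  fp2 <- post_translational_response(kin_default, op2, 0.5,
                                     B_T_range = c(0.1, 30), n = 50)
  expect_equal(which.max(fp2$sigB), nrow(fp2))
})

test_that("without phosphatase the response is fully sequestered", {
  fp0 <- post_translational_response(kin_default, op_default, 0,
                                     B_T_range = c(1, 10), n = 25)
  expect_lt(max(fp0$sigB / fp0$B_T), 1e-2)
})

test_that("logarithmic gain is exact on power laws and zero on flat curves", {
  B <- exp(seq(log(0.1), log(10), length.out = 60))
  for (k in c(-2, 0.5, 1, 3)) {
    curve <- structure(data.frame(B_T = B, sigB = 0.7 * B^k),
                       class = c("response_curve", "data.frame"))
    expect_equal(logarithmic_gain(curve, 1.3), k, tolerance = 1e-6)
  }
  flat <- structure(data.frame(B_T = B, sigB = rep(2, length(B))),
                    class = c("response_curve", "data.frame"))
  expect_equal(logarithmic_gain(flat, 1), 0, tolerance = 1e-8)
  expect_error(logarithmic_gain(flat, 100), "outside")
})

test_that("closed-loop intersection matches the full-model steady state", {
  for (P_T in c(0.2, 0.5)) {
    cl <- closed_loop_steady_state(kin_default, op_default, P_T)
    ss <- steady_state(kin_default, op_default, P_T)
    expect_equal(cl[["sigB"]], ss[["sigB"]], tolerance = 1e-4)
    expect_equal(cl[["B_T"]], species_totals(ss)[["B_T"]], tolerance = 1e-4)
  }
})

test_that("closed loop at zero stress sits near 1 uM total sigma-B", {
  cl <- closed_loop_steady_state(kin_default, op_default, 0)
  expect_equal(cl[["B_T"]], 1, tolerance = 0.25)
  expect_lt(cl[["sigB"]], 0.05 * cl[["B_T"]])
})

test_that("a constitutive operon pins total sigma-B at v0 / k_deg", {
  op <- sigb_operon(f = 0, v0 = 8.64)
  cl <- closed_loop_steady_state(kin_default, op, 0.5)
  expect_equal(cl[["B_T"]], 8.64 / 0.7, tolerance = 1e-6)
})

test_that("wild-type operates in the ultrasensitive negative regime", {
  cl <- closed_loop_steady_state(kin_default, op_default, 0.5)
  lg <- logarithmic_gain(NULL, cl[["B_T"]], kin = kin_default,
                         op = op_default, P_T = 0.5)
  expect_lt(lg, -1)
})

test_that("representative synthesis ratios classify into the three regions", {
  expect_equal(classify_region(2, 2, kin_default, op_default)$label, "I")
  expect_equal(classify_region(4, 4.5, kin_default, op_default)$label, "II")
  expect_equal(classify_region(8, 4.5, kin_default, op_default)$label, "III")
})

test_that("analytic boundary lines evaluate to the printed expressions", {
  b <- region_boundaries(kin_default)
  expect_equal(b$upper(4.5), 6.5)
  expect_equal(b$lower(4.5), 2 * (1 + 4.5 * 0.7 / 36))
  expect_equal(b$lower(4.5), 2.175)
  expect_equal(b$lower(0), 2)
  expect_equal(b$upper(0), 2)
})

test_that("titration of sigma-B is the dominant ultrasensitive step", {
  # along the post-translational response near the operating point, both
  # the unphosphorylated-RsbV fraction and the free-sigma-B fraction fall
  # ultrasensitively with operon expression; the sigma-B branch is steeper
  cl <- closed_loop_steady_state(kin_default, op_default, 0.5)
  B0 <- cl[["B_T"]]
  frac <- function(B_T) {
    s <- sigbnet:::fp_point(kin_default, op_default, 0.5, B_T)
    tot <- species_totals(s)
    c(sig = s[["sigB"]] / tot[["B_T"]],
      v_unphos = (s[["V"]] + s[["W2V"]] + 2 * s[["W2V2"]]) / tot[["RsbV_T"]])
  }
  h <- 0.02
  lo <- frac(B0 * (1 - h)); hi <- frac(B0 * (1 + h))
  lg <- (log(hi) - log(lo)) / (log(1 + h) - log(1 - h))
  expect_lt(lg[["v_unphos"]], -1)
  expect_lt(lg[["sig"]], -1)
  expect_lt(lg[["sig"]], lg[["v_unphos"]])  # titration branch is steeper
})

test_that("pulsing threshold is positive and grows with basal expression", {
  th <- phosphatase_threshold(kin_default, op_default, tol = 2e-3)
  expect_gt(th$threshold, 0)
  expect_equal(th$basal_B_T, 0.4 / 0.7)
  op_hi <- sigb_operon(v0 = 0.8)
  th_hi <- phosphatase_threshold(kin_default, op_hi, tol = 2e-3)
  expect_gt(th_hi$threshold, th$threshold)
  expect_gt(th_hi$analytic, th$analytic)
})

test_that("numeric threshold trends follow the analytic approximation", {
  # the printed approximation says the threshold rises with lambda_W and
  # falls as the phosphatase/kinase rate ratio k_p/k_k grows
  th_ref <- phosphatase_threshold(kin_default, op_default, tol = 5e-3)
  op_lw <- sigb_operon(lambda_W = 5)
  th_lw <- phosphatase_threshold(kin_default, op_lw, tol = 5e-3)
  expect_gt(th_lw$threshold, th_ref$threshold)
  expect_gt(analytic_threshold(kin_default, op_lw),
            analytic_threshold(kin_default, op_default))
  kin_kp <- sigb_kinetics(k_p = 360)
  th_kp <- phosphatase_threshold(kin_kp, op_default, tol = 5e-3)
  expect_lt(th_kp$threshold, th_ref$threshold)
  expect_lt(analytic_threshold(kin_kp, op_default),
            analytic_threshold(kin_default, op_default))
})
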