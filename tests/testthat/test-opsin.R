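test_that("GtACR1 transition rates match their closed forms", {
  p <- opsin_params("GtACR1")
  # dark: numerator c_num + ln(e_offset) vanishes by construction
  expect_identical(gtacr1_opening_rate(0, p), 0)
  # direct scalar evaluation of the printed formula
  rate_ref <- function(ee)
    (1 / 1110) * (5.878134701 + log(ee + 0.0028)) /
      (0.369864 - 0.1072 * log(ee + 0.0028))
  expect_equal(gtacr1_opening_rate(1, p), rate_ref(1), tolerance = 1e-12)
  expect_equal(gtacr1_opening_rate(1, p), 1.43e-2, tolerance = 0.01)
  expect_equal(gtacr1_opening_rate(0.001, p), rate_ref(0.001),
               tolerance = 1e-12)
  expect_equal(gtacr1_opening_rate(0.001, p), 2.8e-4, tolerance = 0.02)
  # monotone non-decreasing over the protocol range
  ee <- c(0, 10^seq(-3, 1, by = 0.25))
  expect_true(all(diff(gtacr1_opening_rate(ee, p)) >= 0))
  expect_error(gtacr1_opening_rate(-0.1, p), "non-negative")
  # closing rate: light-independent 1/tau_off
  expect_equal(gtacr1_closing_rate(p), 1 / 119)
  expect_equal(gtacr1_closing_rate(opsin_params("GtACR1", tau_off = 1)), 1)
})

test_that("parameter constructor enforces the dark-silence construction", {
  expect_error(opsin_params("GtACR1", e_offset = 0.005), "c_num")
  expect_error(opsin_params("GtACR1", g_max = -1), "positive")
  expect_error(opsin_params("GtACR1", tau_onn = 5), "unknown")
})

test_that("GtACR1 stepping is the exact exponential relaxation", {
  p <- opsin_params("GtACR1")
  # fixed point
  kco <- gtacr1_opening_rate(0.5, p); koc <- gtacr1_closing_rate(p)
  pss <- kco / (kco + koc)
  expect_equal(gtacr1_step(pss, 0.5, 123.4, p), pss)
  # dark decay from fully open over one tau_off
  expect_equal(gtacr1_step(1, 0, 119, p), exp(-1), tolerance = 1e-12)
  # long-time limit at 1 mW/mm^2 -> P_ss ~ 0.63
  expect_equal(gtacr1_step(0, 1, 1e6, p),
               gtacr1_opening_rate(1, p) /
                 (gtacr1_opening_rate(1, p) + 1 / 119))
  expect_equal(gtacr1_step(0, 1, 1e6, p), 0.63, tolerance = 0.01)
  # analytic equivalence: stepped trajectory vs closed form over 500 steps
  dt <- 0.5; ee <- 0.2
  kco <- gtacr1_opening_rate(ee, p); tau <- 1 / (kco + koc)
  pss <- kco * tau
  po <- 0.1
  for (i in 1:500) {
    po <- gtacr1_step(po, ee, dt, p)
    expect_lt(abs(po - (pss + (0.1 - pss) * exp(-i * dt / tau))), 1e-10)
  }
  expect_true(po >= 0 && po <= 1)
})

test_that("GtACR1 current follows Ohm's law with chloride reversal", {
  p <- opsin_params("GtACR1")
  expect_equal(gtacr1_current(0.7, -40, p), 0)
  expect_equal(gtacr1_current(1, -80, p), -56)     # 1.4 * (-80 + 40)
  expect_equal(gtacr1_current(1, -80, p, expression = FALSE), 0)
  # steady state at 0.001 mW/mm^2, -80 mV: the ~2 pA/pF working point
  pss <- gtacr1_step(0, 0.001, 1e6, p)
  expect_equal(abs(gtacr1_current(pss, -80, p)), 2, tolerance = 0.25)
})

test_that("ChR2 four-state model conserves probability and is dark-silent", {
  p <- opsin_params("ChR2")
  s <- opsin_init(p)
  # dark: state unchanged, open states empty
  for (i in 1:100) s <- chr2_step(s, 0, -80, 0.1, p)
  expect_equal(unname(s[c("O1", "O2")]), c(0, 0))
  expect_equal(unname(s[["C1"]]), 1)
  expect_equal(chr2_current(s, -80, p), 0)
  # conservation over many lit steps
  s <- opsin_init(p)
  for (i in 1:20000) s <- chr2_step(s, 5, -80, 0.05, p)
  expect_equal(sum(s[c("C1", "O1", "O2", "C2")]), 1, tolerance = 1e-9)
  expect_true(all(s[1:4] >= 0 & s[1:4] <= 1))
  # expression gating and effective reversal near +10 mV
  expect_equal(chr2_current(s, -80, p, expression = FALSE), 0)
  expect_lt(abs(chr2_current(s, 10, p)), 0.06)
  expect_lt(chr2_current(s, -80, p), 0)  # inward when lit at -80
})

test_that("ChR2 stepping agrees with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- opsin_params("ChR2")
  ee <- 2; v <- -80
  rhs <- function(t, y, parms) {
    F <- p$flux_factor * ee
    S0 <- 0.5 * (1 + tanh(120 * (ee - p$theta_half)))
    k1 <- p$eps1 * F * y[5]; k2 <- p$eps2 * F * y[5]
    Gd1 <- p$Gd1_base + p$Gd1_amp * tanh(-(v + 20) / 20)
    Gr <- p$Gr0 * exp(-p$Gr_vdep * v)
    e12 <- p$e12_dark + p$e12_c * log(1 + ee / p$e12_scale)
    e21 <- p$e21_dark + p$e21_c * log(1 + ee / p$e21_scale)
    list(c(
      Gr * y[4] + Gd1 * y[2] - k1 * y[1],
      k1 * y[1] - (Gd1 + e12) * y[2] + e21 * y[3],
      k2 * y[4] + e12 * y[2] - (p$Gd2 + e21) * y[3],
      p$Gd2 * y[3] - (k2 + Gr) * y[4],
      (S0 - y[5]) / p$tau_p))
  }
  y0 <- c(1, 0, 0, 0, 0)
  sol <- deSolve::lsoda(y0, c(0, 250), rhs, NULL, rtol = 1e-10,
                        atol = 1e-12)
  s <- opsin_init(p)
  for (i in 1:25000) s <- chr2_step(s, ee, v, 0.01, p)
  expect_equal(unname(s[1:4]), unname(sol[2, 2:5]), tolerance = 2e-3)
})

test_that("voltage clamp reproduces the published polarity and ordering", {
  g <- opsin_params("GtACR1")
  # inward at -80, outward at 0 (reversal -40 between them)
  tr_neg <- run_voltage_clamp(g, -80, 0.1)
  tr_pos <- run_voltage_clamp(g, 0, 0.1)
  expect_lt(plateau_current(tr_neg), 0)
  expect_gt(plateau_current(tr_pos), 0)
  # zero before light onset from dark-adapted start, zero with no light
  expect_true(all(tr_neg$I_pA_pF[tr_neg$time_ms < 100] == 0))
  dark <- run_voltage_clamp(g, -80, 0)
  expect_true(all(dark$I_pA_pF == 0))
  # plateau magnitude strictly increasing with irradiance
  ee_grid <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1)
  plat <- vapply(ee_grid, function(e)
    abs(plateau_current(run_voltage_clamp(g, -80, e, dt = 0.5))), 0)
  expect_true(all(diff(plat) > 0))
  # plateau at t = 500 ms has reached >= 98% of steady state
  pss <- gtacr1_step(0, 0.001, 1e9, g)
  p500 <- gtacr1_step(0, 0.001, 500, g)
  expect_gte(p500 / pss, 0.98)
})

test_that("GtACR1 plateau currents dominate ChR2 at -80 mV everywhere", {
  g <- opsin_params("GtACR1")
  c2 <- opsin_params("ChR2")
  for (e in c(0.001, 0.01, 0.1, 0.5, 1)) {
    ig <- abs(plateau_current(run_voltage_clamp(g, -80, e, dt = 0.5)))
    ic <- abs(plateau_current(run_voltage_clamp(c2, -80, e, dt = 0.5)))
    expect_gt(ig, ic)
  }
})

test_that("conductance calibration recovers known values", {
  # round trip: measure the clamp current implied by g = 1.4, recalibrate
  g0 <- opsin_params("GtACR1")
  target <- abs(plateau_current(run_voltage_clamp(g0, -80, 0.1)))
  ghat <- calibrate_conductance("GtACR1", target, 0.1, -80,
                                bracket = c(0.01, 5))
  expect_equal(ghat, 1.4, tolerance = 1e-3)
  expect_error(calibrate_conductance("GtACR1", target, 0.1, -80,
                                     bracket = c(2, 5)),
               "bracket")
})
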