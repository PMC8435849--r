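test_that("resting states are physiologic, stationary and deterministic", {
  yv <- init_resting("ventricular")
  ya <- init_resting("atrial")
  expect_gt(yv[1], -90); expect_lt(yv[1], -80)
  expect_gt(ya[1], -85); expect_lt(ya[1], -75)
  expect_identical(init_resting("ventricular"), yv)
  # stationarity: 1000 ms unpaced drift below 0.01 mV/ms
  for (m in c("ventricular", "atrial")) {
    tr <- simulate_cell(m, duration = 1000, sample_ms = 1)
    expect_lt(max(abs(diff(tr$V_mV))), 0.01)
  }
  expect_error(init_resting("ventricular", "scar"), "scar")
  expect_error(init_resting("ventricular", "atrial_fibrotic"),
               "incompatible")
})

test_that("a 30 pA/pF stimulus elicits a full action potential", {
  for (m in c("ventricular", "atrial")) {
    tr <- simulate_cell(m, duration = 600,
                        stimuli = data.frame(start = 20, duration = 5,
                                             amplitude = 30))
    expect_gt(max(tr$V_mV), 0)               # overshoot
    expect_lt(tr$V_mV[nrow(tr)], -70)        # repolarized
  }
})

test_that("action potential duration converges under dt halving", {
  apd90 <- function(dt) {
    tr <- simulate_cell("ventricular", duration = 600, dt = dt,
                        stimuli = data.frame(start = 20, duration = 2,
                                             amplitude = 40),
                        sample_ms = 0.5)
    v <- tr$V_mV; t <- tr$time_ms
    lev <- max(v) - 0.9 * (max(v) - v[1])
    rng <- range(t[v > lev])
    diff(rng)
  }
  a1 <- apd90(0.025); a2 <- apd90(0.0125)
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("regional remodeling multipliers behave as configured", {
  expect_equal(unname(apply_region_remodeling("atrial_normal")),
               c(1, 1, 1, 1))
  bz <- apply_region_remodeling("ventricular_BZ")
  expect_equal(unname(bz[c("g_Na", "g_CaL", "g_Kr", "g_Ks")]),
               c(0.38, 0.69, 0.30, 0.20))
  fib <- apply_region_remodeling("atrial_fibrotic")
  expect_true(all(fib[c("g_Na", "g_CaL", "g_K1")] < 1))
  ov <- apply_region_remodeling("ventricular_BZ", list(g_Na = 0.5))
  expect_equal(unname(ov["g_Na"]), 0.5)
  expect_error(apply_region_remodeling("scar"), "scar")
  expect_error(apply_region_remodeling("ventricular_BZ", list(gNa = 1)),
               "unknown")
})

test_that("border-zone myocytes have longer APD than normal at CL 600", {
  apd_of <- function(region) {
    y <- init_resting("ventricular", region, equilibrate_ms = 5000)
    tr <- simulate_cell("ventricular", duration = 600 * 4, region = region,
                        state = y, sample_ms = 0.5,
                        stimuli = data.frame(
                          start = seq(20, by = 600, length.out = 4),
                          duration = 2, amplitude = 40))
    sel <- tr$time_ms >= 20 + 3 * 600
    v <- tr$V_mV[sel]; t <- tr$time_ms[sel]
    lev <- max(v) - 0.9 * (max(v) - min(v))
    diff(range(t[v > lev]))
  }
  expect_gt(apd_of("ventricular_BZ"), apd_of("ventricular_normal"))
})

test_that("single-step interface respects dt limits and stationarity", {
  y <- init_resting("atrial")
  expect_error(ionic_step(y, dt = 0.1, membrane = "atrial"), "dt")
  y2 <- ionic_step(y, 0, 0.05, "atrial")
  expect_lt(abs(y2[1] - y[1]), 1e-3)
})
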