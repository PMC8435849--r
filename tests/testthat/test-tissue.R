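test_that("diffusion operator is symmetric with zero row sums", {
  tis <- make_tissue(geometry_spec("ventricular", lateral = 4,
                                   thickness = 2, spacing = 0.5,
                                   disease = disease_fibrosis(0.2),
                                   seed = 2))
  A <- assemble_diffusion(tis)
  expect_lt(max(abs(A - Matrix::t(A))), 1e-14)
  expect_lt(max(abs(Matrix::rowSums(A))), 1e-12)
  # constant field diffuses to nothing
  v <- rep(3.7, nrow(A))
  expect_lt(max(abs(as.numeric(A %*% v))), 1e-11)
})

test_that("isotropic 1-D column reduces to the second-difference stencil", {
  h <- 0.5; D <- 0.04
  tis <- make_tissue(geometry_spec("ventricular", lateral = c(h, h),
                                   thickness = 5, spacing = h,
                                   cond = c(D, D)))
  A <- assemble_diffusion(tis)
  # interior rows: D/h^2 * (1, -2, 1) along z (grid is a 2x2xn column, so
  # lateral neighbors contribute zeros that cancel by symmetry)
  nz <- tis$dims[3]
  v <- as.numeric(A %*% rep(seq_len(nz)^2, each = 4))
  # second difference of i^2 is 2, scaled by D/h^2
  interior <- rep(c(FALSE, rep(TRUE, nz - 2), FALSE), each = 4)
  expect_equal(v[interior], rep(2 * D / h^2, sum(interior)),
               tolerance = 1e-10)
})

test_that("Crank-Nicolson diffusion conserves charge and damps extrema", {
  tis <- make_tissue(geometry_spec("ventricular", lateral = 5,
                                   thickness = 2, spacing = 0.5))
  A <- assemble_diffusion(tis)
  n <- nrow(A)
  c_cn <- 0.05  # dt/2 * operator scale
  M1 <- Matrix::Diagonal(n) - c_cn * A
  M2 <- Matrix::Diagonal(n) + c_cn * A
  v <- rnorm(n)
  for (i in 1:50) {
    v_new <- as.numeric(Matrix::solve(M1, M2 %*% v))
    expect_equal(sum(v_new), sum(v), tolerance = 1e-9)   # conservation
    expect_lte(max(v_new), max(v) + 1e-9)                # maximum principle
    expect_gte(min(v_new), min(v) - 1e-9)
    v <- v_new
  }
  expect_lt(max(v) - min(v), diff(range(rnorm(n))))  # spread has decayed
})

test_that("resting tissue stays at rest and scar stays decoupled", {
  tis <- atrial_slab()
  rec <- simulate_tissue(tis, 300, sample_ms = 5)
  drift <- max(abs(rec$final_state[1, ] - rec$final_state[1, 1]))
  expect_lt(drift, 0.5)
  expect_equal(rec$activity, rep(0, length(rec$activity)))
})

test_that("dark runs are bitwise independent of the expression map", {
  tis <- atrial_slab()
  ex <- build_expression_map(tis, 0.582, seed = 5)
  fld <- solve_attenuation(tis, light_preset("green"), "endo")
  op <- opsin_params("GtACR1")
  nd <- tissue_nodes(tis)
  stim <- stim_pulse(5, 2, 40, nd$active[nd$x <= 0.5])
  base <- simulate_tissue(tis, 120, stimuli = list(stim), probes = c(1, 50))
  dark <- simulate_tissue(tis, 120, stimuli = list(stim), probes = c(1, 50),
                          light = list(light_pulse(10, 100, 0)),
                          opsin = op, expression = ex, attenuation = fld)
  expect_identical(base$probe_V, dark$probe_V)
  expect_identical(base$final_state, dark$final_state)
})

test_that("wavelength mismatch is a configuration error before stepping", {
  tis <- atrial_slab()
  ex <- build_expression_map(tis, 0.5, seed = 1)
  blue <- solve_attenuation(tis, light_preset("blue"), "endo")
  expect_error(
    simulate_tissue(tis, 10, light = list(light_pulse(0, 5, 1)),
                    opsin = opsin_params("GtACR1"), expression = ex,
                    attenuation = blue),
    "wavelength")
})

test_that("point stimulation spreads anisotropically along fibers", {
  # fibers along x throughout; activation should reach distant x sooner
  # than equally distant y
  tis <- make_tissue(geometry_spec("ventricular", lateral = 12,
                                   thickness = 1.2001, spacing = 0.4,
                                   fiber_rotation = 0))
  nd <- tissue_nodes(tis)
  ctr <- nd$active[abs(nd$x - 6) < 0.21 & abs(nd$y - 6) < 0.21]
  rec <- simulate_tissue(tis, 60, stimuli = list(stim_pulse(5, 2, 60, ctr)),
                         record_activations = TRUE)
  at <- vapply(rec$activations, function(a) if (length(a)) a[1] else NA_real_,
               0)
  along <- at[nd$active[abs(nd$x - 10) < 0.21 & abs(nd$y - 6) < 0.21 &
                          nd$iz == 2]]
  across <- at[nd$active[abs(nd$x - 6) < 0.21 & abs(nd$y - 10) < 0.21 &
                           nd$iz == 2]]
  expect_true(all(is.finite(along)))
  expect_gt(min(across, na.rm = TRUE), max(along, na.rm = TRUE))
})

test_that("planar conduction velocity converges under refinement", {
  strip <- function(h, dt_ = NULL) {
    measure_cv(make_tissue(geometry_spec(
      "ventricular", lateral = c(16, 1.2001), thickness = 1.2001,
      spacing = h, fiber_rotation = 0)), "x", dt = dt_)
  }
  cv0 <- strip(0.4, 0.025)
  cv_dt <- strip(0.4, 0.0125)
  expect_lt(abs(cv0 - cv_dt) / cv_dt, 0.05)
  # spatial refinement: the sodium upstroke foot (~0.3 mm) is marginally
  # resolved by the second-order stencil at the 0.4 mm production spacing,
  # so halving the spacing shifts CV by ~14%; bound the error at 15% and
  # require the sign (coarse grids underestimate CV)
  cv_h <- strip(0.2, 0.025)
  expect_lt(abs(cv0 - cv_h) / cv_h, 0.15)
  expect_lt(cv0, cv_h)
})

test_that("identical runs are bitwise reproducible", {
  tis <- atrial_slab()
  nd <- tissue_nodes(tis)
  stim <- stim_pulse(5, 2, 40, nd$active[nd$x <= 0.5])
  r1 <- simulate_tissue(tis, 80, stimuli = list(stim), probes = 1:3)
  r2 <- simulate_tissue(tis, 80, stimuli = list(stim), probes = 1:3)
  expect_identical(r1$probe_V, r2$probe_V)
  expect_identical(r1$final_state, r2$final_state)
})
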