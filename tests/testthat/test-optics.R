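test_that("a parameter matches the published green-light value and limits", {
  a_green <- compute_a(1.42, 0.7, 0.9)
  expect_equal(round(a_green, 1), 0.5)
  # absorption-dominated limit: a -> 1 - 4/5
  expect_equal(compute_a(1e-6, 1e6, 0.5), 0.2, tolerance = 1e-4)
  # forward-scattering limit with negligible absorption:
  # a -> 1 - (4/5)/(1+g) -> 0.6 as g -> 1
  expect_equal(compute_a(1, 1e-9, 1 - 1e-9), 0.6, tolerance = 1e-6)
  expect_error(compute_a(-1, 0.7, 0.9), "positive")
  expect_error(compute_a(1.42, 0.7, 1.2), "g_anisotropy")
})

test_that("diffusion coefficient matches the published value and scales", {
  a <- compute_a(1.42, 0.7, 0.9)
  D <- compute_D(1.42, 0.7, a)
  # the published pipeline value is 0.189 mm; the closed form with the
  # published inputs lands within the 1e-3 consistency band of it
  expect_equal(round(D, 3), 0.188)
  expect_lt(abs(D - 0.189), 1e-3)
  expect_equal(compute_D(1, 1e-12, 0.5), 1 / 3, tolerance = 1e-9)
  # homogeneity: doubling (mu_s', mu_a * a) halves D
  expect_equal(compute_D(2 * 1.42, 2 * 0.7, a), D / 2)
})

test_that("penetration depths reproduce the printed values for all colors", {
  expect_equal(penetration_depth(0.189, 0.7) * 1000, 519.6, tolerance = 1e-4)
  expect_equal(penetration_depth(0.183, 0.52) * 1000, 593.2, tolerance = 1e-4)
  expect_equal(penetration_depth(0.34, 0.1), 1.844, tolerance = 1e-3)
  # presets carry the same numbers
  expect_equal(light_preset("green")$delta, sqrt(0.189 / 0.7),
               tolerance = 1e-9)
  expect_equal(light_preset("red")$delta, 1.844, tolerance = 1e-3)
})

test_that("optical_properties validates consistency of D with (mu_s', g)", {
  expect_error(
    optical_properties(515, mu_a = 0.7, D = 0.5, mu_s_prime = 1.42,
                       g_anisotropy = 0.9),
    "inconsistent")
  op <- optical_properties(515, mu_a = 0.7, mu_s_prime = 1.42,
                           g_anisotropy = 0.9)
  expect_equal(op$D, compute_D(1.42, 0.7, op$a_param))
  expect_lt(abs(op$D - 0.189), 1e-3)
})

test_that("attenuation solve matches the discrete 1-D closed form to 1e-6", {
  # 20-node homogeneous column; the finite-difference screened-Poisson
  # recurrence D (phi[i+1] - 2 phi[i] + phi[i-1])/h^2 = mu_a phi[i] has the
  # exact solution A r^i + B r^-i with r from its characteristic equation;
  # fit A, B to the boundary conditions (phi = 1 at the surface node,
  # mirror/zero-flux at the far end) and compare node by node.
  op <- light_preset("green")
  h <- 0.25
  nz <- 20L
  tis <- make_tissue(geometry_spec("ventricular", lateral = c(h, h),
                                   thickness = (nz - 1) * h, spacing = h))
  expect_equal(tis$dims[3], nz)
  fld <- solve_attenuation(tis, op, "endo")
  nd <- tissue_nodes(tis, "grid")
  phi <- vapply(seq_len(nz), function(k)
    mean(fld$factor[nd$grid[nd$iz == k]]), 0)
  q <- op$mu_a * h^2 / op$D
  r <- 1 + q / 2 + sqrt(q + q^2 / 4)
  # boundary conditions: phi_1 = 1 (Dirichlet surface); the one-sided
  # zero-flux row at i = nz reads D(phi[nz-1] - phi[nz]) = mu_a h^2 phi[nz],
  # i.e. phi[nz-1] = (1+q) phi[nz]; solve the 2x2 for A, B
  M <- rbind(c(r, 1 / r),
             c(r^(nz - 1) - (1 + q) * r^nz,
               r^(1 - nz) - (1 + q) * r^(-nz)))
  ab <- solve(M, c(1, 0))
  phi_exact <- ab[1] * r^seq_len(nz) + ab[2] * r^-seq_len(nz)
  expect_lt(max(abs(phi - phi_exact)), 1e-6)
})

test_that("attenuation approximates continuum exponential decay", {
  op <- light_preset("green")
  h <- 0.1
  # wall much thicker than the tested depth range so the far-boundary
  # reflection stays negligible
  tis <- make_tissue(geometry_spec("ventricular", lateral = c(h, h),
                                   thickness = 3.5, spacing = h))
  fld <- solve_attenuation(tis, op, "endo")
  nd <- tissue_nodes(tis, "grid")
  depth <- nd$z
  sel <- depth >= h & depth <= 3 * op$delta
  rel <- fld$factor[nd$grid[sel]] / exp(-depth[sel] / op$delta) - 1
  expect_lt(max(abs(rel)), 0.02)
})

test_that("attenuation field obeys the maximum principle and ordering", {
  tis <- make_tissue(geometry_spec("ventricular", lateral = 2,
                                   thickness = 4, spacing = 0.4))
  cols <- c("green", "blue", "red")
  flds <- lapply(cols, function(cc)
    solve_attenuation(tis, light_preset(cc), "endo"))
  names(flds) <- cols
  for (f in flds) {
    expect_true(all(f$factor >= 0 & f$factor <= 1))
    expect_equal(unname(f$factor[tis$surfaces$endo]),
                 rep(1, length(tis$surfaces$endo)))
  }
  interior <- setdiff(seq_len(prod(tis$dims)), tis$surfaces$endo)
  expect_true(all(flds$red$factor[interior] >=
                    flds$green$factor[interior]))
  expect_gt(mean(flds$red$factor[interior]),
            mean(flds$blue$factor[interior]))
  expect_gt(mean(flds$blue$factor[interior]),
            mean(flds$green$factor[interior]))
})

test_that("local irradiance is an elementwise product", {
  tis <- make_tissue(geometry_spec("ventricular", lateral = 1,
                                   thickness = 1.6, spacing = 0.4))
  fld <- solve_attenuation(tis, light_preset("green"), "endo")
  expect_equal(local_irradiance(fld, 0), rep(0, prod(tis$dims)))
  e1 <- local_irradiance(fld, 0.05)
  expect_equal(local_irradiance(fld, 0.1), 2 * e1)
  expect_error(local_irradiance(fld, -1), ">= 0")
  expect_error(solve_attenuation(tis, light_preset("green"), "valve"),
               "no surface")
})
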