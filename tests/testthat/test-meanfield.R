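test_that("isolated-polymer free energy has the known limiting minimizers", {
  # the non-interacting part 3x/2 - log x alone is minimized at x = 2/3
  x_ni <- optimize(function(x) 1.5 * x - log(x), c(0.01, 10))$minimum
  expect_equal(x_ni, 2 / 3, tolerance = 1e-4)
  # with the three-body term (x^-3/6 in these units) the v_p = 0 minimizer
  # satisfies 3/2 - 1/x - 1/(2 x^4) = 0, i.e. x* = 1 exactly, at any large N
  for (n in c(1e6, 1e8)) {
    p <- mean_field_params(n_p = n, v_p = 0)
    m <- minimize_fpoly(p)
    expect_equal(m$rg^2 / p$n_p, 1, tolerance = 0.01)
  }
  # good solvent: Flory scaling R_g ~ N^(3/5)
  p1 <- mean_field_params(v_p = 1)
  ns <- 10^seq(3, 6, by = 0.5)
  rg <- vapply(ns, function(n) {
    p1$n_p <- n
    minimize_fpoly(p1)$rg
  }, numeric(1))
  slope <- unname(coef(lm(log(rg) ~ log(ns)))[2])
  expect_lt(abs(slope - 0.6), 0.01)
  # poor solvent: globule density -3 v_p / 2
  p2 <- mean_field_params(n_p = 1e6, v_p = -1)
  expect_equal(minimize_fpoly(p2)$rho, 1.5, tolerance = 0.01)
})

test_that("bulk free energy minima and tie-breaking are correct", {
  p <- mean_field_params(t_b = -1, u = 6, mu_b = 0)
  m <- f_bulk_minima(p)
  expect_equal(m$phi, c(-1, 1), tolerance = 1e-9)
  expect_equal(m$f, c(-0.25, -0.25), tolerance = 1e-9)
  pi0 <- phi_inf(p)
  expect_equal(as.numeric(pi0), -1, tolerance = 1e-9) # tie toward lower phi
  expect_true(attr(pi0, "tie"))
  # supercritical single well
  p2 <- mean_field_params(t_b = 1, u = 6, mu_b = 0)
  expect_equal(as.numeric(phi_inf(p2)), 0, tolerance = 1e-12)
  # mu_b -> -mu_b maps phi_inf -> -phi_inf
  p3 <- mean_field_params(t_b = -1, u = 6, mu_b = 0.2)
  p4 <- mean_field_params(t_b = -1, u = 6, mu_b = -0.2)
  expect_equal(as.numeric(phi_inf(p3)), -as.numeric(phi_inf(p4)),
               tolerance = 1e-9)
})

test_that("coupled free energy decouples at h = 0 and shifts phi linearly", {
  p <- mean_field_params(n_p = 1e4, v_p = -0.5, t_b = 1, u = 6, mu_b = 0,
                         h = 0)
  expect_equal(f_sys(10, as.numeric(phi_inf(p)), p), f_poly0(10, p),
               tolerance = 1e-12)
  mm <- minimize_fsys(p)
  iso <- minimize_fpoly(p)
  expect_equal(mm$rho[1], iso$rho, tolerance = 1e-4)
  expect_equal(mm$phi[1], as.numeric(phi_inf(p)), tolerance = 1e-6)
  # near-quadratic bulk (small u): minimizing phi = phi_inf + h rho / t_b
  p2 <- mean_field_params(n_p = 1e4, v_p = -0.5, t_b = 2, u = 0.5,
                          mu_b = 0.1, h = 0.4)
  mm2 <- minimize_fsys(p2)
  pred <- as.numeric(phi_inf(p2)) + p2$h * mm2$rho[1] / p2$t_b
  expect_equal(mm2$phi[1], pred, tolerance = 0.01)
})

test_that("v_eff follows the printed formula and rejects subcritical bulks", {
  expect_equal(v_eff(1, 0, 1), 1)
  expect_equal(v_eff(1, 1, 1), 0)
  expect_equal(v_eff(1, 1, 2), 0.5)
  expect_error(v_eff(1, 1, -1), "t_b > 0")
})

test_that("a supercritical bulk shifts the continuous collapse to h^2/t_b", {
  p <- mean_field_params(n_p = 1e6, v_p = 0, t_b = 1, u = 6, mu_b = 0,
                         h = 0.5)
  expected <- 0.25
  tr <- scan_transition(p, "v_p", seq(expected + 0.1, expected - 0.1,
                                      by = -0.02), n_starts = 6)
  expect_true(tr$found)
  expect_equal(tr$order, "continuous")
  expect_lt(abs(tr$location - expected), 2 * 0.02)
})

test_that("a subcritical bulk drives a first-order transition matching the branch crossing", {
  p <- mean_field_params(n_p = 1e6, v_p = 0.5, t_b = -1, u = 6, mu_b = -0.3,
                         h = 0.3)
  vals <- seq(-0.3, -0.02, by = 0.02)
  tr <- scan_transition(p, "mu_b", vals, n_starts = 8)
  expect_true(tr$found)
  expect_equal(tr$order, "first_order")
  # two coexisting minima near the crossing, with a finite density gap
  p$mu_b <- tr$location
  mm <- minimize_fsys(p)
  expect_gte(nrow(mm), 2)
  expect_gt(abs(mm$rho[1] - mm$rho[2]), 0.2)
  # branch free energies are nearly equal at the detected point
  qb <- quadratic_branches(p)
  expect_lt(abs(diff(qb$f_branch)) / abs(mean(qb$f_branch)), 0.2)
  # independent branch-crossing estimate agrees within one scan step
  bt <- branch_transition(p, "mu_b", vals)
  expect_true(bt$found)
  expect_lt(abs(bt$location - tr$location), 0.021)
  # the quadratic approximation needs a double well
  p$t_b <- 1
  expect_error(quadratic_branches(p), "double-well")
})

test_that("symmetric double well with h = 0 has degenerate branches at mu_b = 0", {
  p <- mean_field_params(n_p = 1e3, v_p = 1, t_b = -1, u = 6, mu_b = 0, h = 0)
  qb <- quadratic_branches(p)
  expect_equal(qb$f_branch[1], qb$f_branch[2], tolerance = 1e-6)
  expect_equal(qb$v_eff, c(1, 1), tolerance = 1e-9) # h = 0: v_eff = v_p
})
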