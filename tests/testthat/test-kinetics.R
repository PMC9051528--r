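test_that("zero input with zero initial conditions stays at zero", {
  g <- default_grid()
  sol <- solve_2cxm(kinetic_params(1, 0.05, 0.2, 1.5), rep(0, 100), g)
  expect_equal(sol$Cp, rep(0, 100))
  expect_equal(sol$Ce, rep(0, 100))
  expect_equal(sol$Cmyo, rep(0, 100))
})

test_that("PS = 0 decouples the interstitium", {
  g <- default_grid()
  aif <- default_aif(g)
  p <- c(1.2, 0.08, 0.3, 0)
  sol <- solve_2cxm(p, aif, g)
  expect_equal(sol$Ce, rep(0, 100))
  # Cp then solves the one-compartment equation vp dCp/dt = Fp (CAIF - Cp)
  ref <- solve_2cxm_desolve(p, aif, g$t)
  expect_lt(max(abs(sol$Cp - ref$Cp)) / max(ref$Cp), 1e-6)
})

test_that("solver matches an independent adaptive integrator", {
  g <- default_grid()
  aif <- default_aif(g)
  p <- c(1.0, 0.05, 0.2, 1.5)
  ref <- solve_2cxm_desolve(p, aif, g$t)
  for (m in c("exact", "rk4")) {
    sol <- solve_2cxm(p, aif, g, method = m)
    expect_lt(max(abs(sol$Cmyo - ref$Cmyo)) / max(abs(ref$Cmyo)), 1e-4,
              label = paste("relative error, method", m))
  }
})

test_that("solution is linear in the input and non-negative", {
  g <- default_grid()
  aif <- default_aif(g)
  p <- kinetic_params(1.5, 0.1, 0.2, 2.5)
  s1 <- solve_2cxm(p, aif, g)
  s3 <- solve_2cxm(p, 3 * aif, g)
  expect_equal(s3$Cmyo, 3 * s1$Cmyo, tolerance = 1e-10)
  expect_true(all(s1$Cp > -1e-10) && all(s1$Ce > -1e-10))
})

test_that("tracer conservation holds at interior points", {
  # d(vp Cp + ve Ce)/dt = Fp (CAIF - Cp); central differences on a grid
  # fine enough that their truncation error is negligible
  t <- seq(0, 1.98, by = 0.002)
  aif <- gamma_variate_aif(t)
  p <- c(2.0, 0.1, 0.5, 1.5)
  sol <- solve_2cxm(p, aif, t)
  lhs <- fd_derivative(sol$Cmyo, t)
  rhs <- p[1] * (aif - sol$Cp)
  i <- 2:(length(t) - 1)
  expect_lt(max(abs(lhs[i] - rhs[i])), 2e-3 * max(abs(rhs)))
})

test_that("compartment residuals vanish on the solved system", {
  g <- default_grid()
  aif <- default_aif(g)
  p <- c(1.0, 0.05, 0.2, 1.5)
  sol <- solve_2cxm(p, aif, g)
  r <- residuals_2cxm(sol$Cp, sol$Ce, fd_derivative(sol$Cp, g$t),
                      fd_derivative(sol$Ce, g$t), aif, p)
  i <- 2:99   # central differences only at interior points
  scale <- max(abs(p[1] * (aif - sol$Cp)))
  expect_lt(max(abs(r$rp[i])), 0.05 * scale)
  expect_lt(max(abs(r$re[i])), 0.05 * scale)
  rm <- residual_reduced(fd_derivative(sol$Cmyo, g$t), sol$Cp, aif, p)
  expect_lt(max(abs(rm[i])), 0.05 * scale)
})

test_that("residual identities hold on arbitrary inputs", {
  set.seed(7)
  n <- 50
  Cp <- runif(n); Ce <- runif(n); dCp <- rnorm(n); dCe <- rnorm(n)
  aif <- runif(n)
  p <- c(1.3, 0.07, 0.25, 0.8)
  r <- residuals_2cxm(Cp, Ce, dCp, dCe, aif, p)
  # all-zero input: every term vanishes
  r0 <- residuals_2cxm(rep(0, n), rep(0, n), rep(0, n), rep(0, n),
                       rep(0, n), p)
  expect_equal(r0$rp, rep(0, n))
  expect_equal(r0$re, rep(0, n))
  # equal compartments: the exchange term cancels in re
  re_eq <- residuals_2cxm(Cp, Cp, dCp, dCe, aif, p)$re
  expect_equal(re_eq, p[3] * dCe)
  # summing the compartment residuals gives the reduced form
  rm <- residual_reduced(p[2] * dCp + p[3] * dCe, Cp, aif, p)
  expect_equal(r$rp + r$re, rm, tolerance = 1e-12)
  # flow term cancels when Cp equals the AIF
  rm2 <- residual_reduced(p[2] * dCp + p[3] * dCe, aif, aif, p)
  expect_equal(rm2, p[2] * dCp + p[3] * dCe)
})

test_that("plasma-to-blood conversion applies haematocrit and density", {
  p <- kinetic_params(1, 0.05, 0.2, 1.5)
  id <- plasma_to_blood(p, hct = 0, density = 1)
  expect_equal(id$Fb, 1)
  expect_equal(id$vb, 0.05)
  conv <- plasma_to_blood(p)
  expect_equal(conv$Fb, 1 / 0.55 / 1.05)
  expect_equal(conv$vb, 0.05 / 0.55 / 1.05)
  expect_equal(plasma_to_blood(c(0, 0.05, 0.2, 1))$Fb, 0)
  expect_error(plasma_to_blood(p, hct = 1), "hct")
})

test_that("invalid inputs are rejected", {
  g <- default_grid()
  aif <- default_aif(g)
  expect_error(solve_2cxm(c(1, 0, 0.2, 1), aif, g), "singular")
  expect_error(solve_2cxm(c(1, 0.05, 0.2, 1), c(NA, aif[-1]), g),
               "finite")
  expect_error(solve_2cxm(c(1, 0.05, 0.2, 1), aif[-1], g), "length")
  expect_error(kinetic_params(-1, 0.05, 0.2, 1), "non-negative")
  expect_warning(kinetic_params(1, 0.6, 0.6, 1), "physiological")
})
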