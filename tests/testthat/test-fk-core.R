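test_that("alpha parameter matches its closed form and limits", {
  sys <- thermal_system(1)
  # hbar*Omega*beta = 2  =>  alpha = coth(1) - 1
  expect_equal(alpha_parameter(4, sys), 1 / tanh(1) - 1, tolerance = 1e-12)
  # ground-state limit alpha -> 1 (the correction is 2/(hbar*Omega*beta))
  expect_equal(alpha_parameter(1e12, sys), 1 - 2e-6, tolerance = 1e-9)
  expect_equal(alpha_parameter(1e14, sys), 1, tolerance = 1e-6)
  # high-temperature Taylor limit alpha ~ hbar*Omega*beta/6
  expect_equal(alpha_parameter(1e-8, sys), 1e-4 / 6, tolerance = 1e-8)
  expect_error(alpha_parameter(-1, sys), "barrier")
  # always inside (0, 1)
  a <- alpha_parameter(10^seq(-6, 6, length.out = 50), sys)
  expect_true(all(a > 0 & a < 1))
})

test_that("smearing width matches Eq.-level closed form and both limits", {
  sys <- thermal_system(1)
  expect_equal(smearing_width(1, sys), 0.5 / tanh(0.5) - 1, tolerance = 1e-12)
  # high-temperature limit hbar^2 beta / 12 M
  expect_equal(smearing_width(1e-6, sys), 1 / 12, tolerance = 1e-6)
  # low-temperature (ground-state) limit hbar / 2 M Omega; the finite-beta
  # correction is -1/(M Omega^2 beta), so beta = 1e8 sits inside 1e-6
  sys_cold <- thermal_system(1e8)
  expect_equal(smearing_width(1, sys_cold), 0.5, tolerance = 1e-6)
  # continuity across Omega^2 = 0 and positivity on the barrier side
  lo <- smearing_width(-1e-9, sys); hi <- smearing_width(1e-9, sys)
  expect_equal(lo, hi, tolerance = 1e-6)
  expect_true(all(smearing_width(seq(-30, 30, length.out = 101), sys) > 0))
  # out-of-range continuation (hbar|Omega|beta >= 2pi) errors
  expect_error(smearing_width(-(2 * pi + 0.01)^2, sys), "out of range")
})

test_that("smeared Hessian quadrature is exact for polynomial potentials", {
  expect_equal(smeared_hessian_quadrature(fix_harmonic(omega = 1.3), 0.4, 0.37),
               1.69, tolerance = 1e-12)
  # V = x^4/4: V'' = 3x^2, Gaussian second moment gives 3*(xc^2 + a2)
  expect_equal(smeared_hessian_quadrature(fix_quartic(), 0, 1), 3,
               tolerance = 1e-10)
  expect_equal(smeared_hessian_quadrature(fix_quartic(), 0.5, 0.2),
               3 * (0.25 + 0.2), tolerance = 1e-10)
  # double well at the barrier top: -1 + 3*a2
  expect_equal(smeared_hessian_quadrature(fix_double_well(), 0, 1), 2,
               tolerance = 1e-10)
})

test_that("gradient-sampling estimator agrees with quadrature (integration by parts)", {
  set.seed(7)
  for (m in list(fix_morse(De = 3, a = 1.1), fix_double_well())) {
    for (xc in c(-0.4, 0.6)) {
      a2 <- 0.15
      ref <- smeared_hessian_quadrature(m, xc, a2)
      est <- smeared_hessian_force_sampling(m, xc, a2, n_samples = 1e5)
      expect_lt(abs(est$omega2 - ref), 3 * est$stderr)
      expect_gt(est$stderr, 0)
    }
  }
  # harmonic: linear force makes every per-sample value omega^2 in mean
  h <- fix_harmonic(omega = 2)
  est <- smeared_hessian_force_sampling(h, 0.3, 0.1, n_samples = 2e4,
                                        seed = 5)
  expect_lt(abs(est$omega2 - 4), 3 * est$stderr)
  expect_error(smeared_hessian_force_sampling(h, 0, 0.1, n_samples = 1),
               "at least 2")
})

test_that("effective-frequency fixed point: harmonic exactness and quartic scan oracle", {
  sys <- thermal_system(2.5)
  h <- fix_harmonic(omega = 1.7)
  e <- solve_effective_frequency(h, 0.9, sys)
  expect_true(e$converged)
  expect_identical(e$iterations, 1L)
  expect_equal(e$omega2, 1.7^2, tolerance = 1e-12)
  # harmonic W1 = kT ln[sinh(u)/u] + M w^2 xc^2 / 2 (smearing terms cancel)
  u <- 1.7 * 2.5 / 2
  expect_equal(e$W1, log(sinh(u) / u) / 2.5 + 0.5 * 1.7^2 * 0.81,
               tolerance = 1e-10)
  # quartic fixed point against a dense scan of Omega^2 = 3 a^2(Omega)
  sysq <- thermal_system(1)
  eq <- solve_effective_frequency(fix_quartic(), 0, sysq)
  resid <- function(om2) om2 - 3 * smearing_width(om2, sysq)
  scan <- seq(0.01, 2, length.out = 2000)
  sgn <- which(diff(sign(resid(scan))) != 0)[1]
  root <- uniroot(resid, scan[c(sgn, sgn + 1)], tol = 1e-12)$root
  expect_true(eq$converged)
  expect_equal(eq$omega2, root, tolerance = 1e-7)
  expect_lte(eq$iterations, 10L)
  # exact residual at the reported fixed point
  expect_lt(abs(eq$omega2 - 3 * smearing_width(eq$omega2, sysq)),
            1e-7 * eq$omega2)
})

test_that("centroid potential limits: free particle and classical limit", {
  sys <- thermal_system(1)
  free <- make_model_potential("external", list(
    dimension = 1, value_fn = function(x) 0 * x,
    gradient_fn = function(x) 0 * x, hessian_fn = function(x) 0 * x,
    vectorized = TRUE))
  ef <- solve_effective_frequency(free, 1.3, sys)
  expect_equal(ef$omega2, 0, tolerance = 1e-10)
  expect_equal(ef$W1, 0, tolerance = 1e-10)
  # classical (high-T) limit: W1 -> V(xc); the residual is O(beta)
  sys_hot <- thermal_system(1e-5)
  mo <- fix_morse(De = 2, a = 1)
  eh <- solve_effective_frequency(mo, 0.4, sys_hot)
  expect_lt(abs(eh$W1 - mo$value(0.4)), 1e-6)
})

test_that("quartic smearing width shrinks with temperature and W1 is continuous at Omega^2=0", {
  betas <- c(4, 2, 1, 0.5, 0.25)
  a2s <- vapply(betas, function(b)
    solve_effective_frequency(fix_quartic(), 0, thermal_system(b))$a2,
    numeric(1))
  expect_true(all(diff(a2s) < 0))   # beta decreasing => a2 decreasing
  # continuity of W1 across Omega^2 = 0 for a near-flat quadratic
  sys <- thermal_system(1)
  for (k in c(1e-8, -1e-8)) {
    m <- make_model_potential("external", list(
      dimension = 1, value_fn = function(x) 0.5 * k * x^2,
      gradient_fn = function(x) k * x, hessian_fn = function(x) rep(k, length(x)),
      vectorized = TRUE))
    e <- solve_effective_frequency(m, 0.7, sys)
    expect_equal(e$W1, 0.5 * k * 0.49, tolerance = 1e-7)
  }
})

test_that("centroid log-weight reproduces Gaussian moments and ignores constants", {
  sys <- thermal_system(2, masses = 1.5)
  # harmonic W1 implies <xc^2> = 1/(beta M w^2), <pc^2> = M/beta; check by
  # quadrature over the weight
  omega <- 1.2
  xs <- seq(-6, 6, length.out = 4001)
  W1 <- 0.5 * 1.5 * omega^2 * xs^2
  w <- exp(vapply(seq_along(xs), function(i)
    centroid_log_weight(xs[i], 0, W1[i], sys), numeric(1)))
  expect_equal(sum(xs^2 * w) / sum(w), 1 / (2 * 1.5 * omega^2),
               tolerance = 1e-8)
  ps <- seq(-8, 8, length.out = 4001)
  wp <- exp(vapply(ps, function(p) centroid_log_weight(0, p, 0, sys),
                   numeric(1)))
  expect_equal(sum(ps^2 * wp) / sum(wp), 1.5 / 2, tolerance = 1e-8)
  # additive constants in W1 shift every log-weight equally
  lw1 <- centroid_log_weight(0.3, 0.1, 2, sys)
  lw2 <- centroid_log_weight(0.3, 0.1, 7, sys)
  expect_equal(lw2 - lw1, -sys$beta * 5)
})

test_that("multi-mode solver: uncoupled and bilinearly coupled oscillators", {
  sys <- thermal_system(2, masses = c(1, 1))
  m2 <- make_model_potential("harmonic", list(M = c(1, 1), omega = c(1, 2.5)))
  r <- effective_frequency_matrix(m2, c(0, 0), sys)
  expect_true(r$converged)
  expect_equal(sort(r$omega2), c(1, 6.25), tolerance = 1e-8)
  # bilinear coupling: modes are mass-weighted K eigenvalues at any T
  K <- matrix(c(2, 0.7, 0.7, 3), 2, 2)
  mb <- make_model_potential("external", list(
    dimension = 2,
    value_fn = function(x) 0.5 * sum(x * (K %*% x)),
    gradient_fn = function(x) as.numeric(K %*% x),
    hessian_fn = function(x) K))
  sysm <- thermal_system(1.3, masses = c(1, 4))
  rb <- effective_frequency_matrix(mb, c(0.2, -0.1), sysm)
  Kmw <- K / sqrt(tcrossprod(c(1, 4)))
  expect_equal(rb$omega2, sort(eigen(Kmw, symmetric = TRUE)$values),
               tolerance = 1e-8)
  expect_true(all(rb$alpha > 0 & rb$alpha < 1))
})

test_that("pair-liquid dimer: free-particle translational width, 1D-solver vibrational mode", {
  # moderately quantum masses keep the smearing local on the stiff
  # Lennard-Jones wall
  sys <- thermal_system(1, masses = c(50, 50))
  dimer <- fix_pair_liquid(N = 2L, L = 12)
  r0 <- 2^(1 / 6)
  r <- effective_frequency_matrix(dimer, c(0, r0), sys, tol = 1e-8)
  expect_true(r$converged)
  # translational zero mode gets the free-particle width hbar^2 beta/12
  i0 <- which.min(abs(r$omega2))
  expect_lt(abs(r$omega2[i0]), 1e-6)
  expect_equal(r$a2[i0], 1 / 12, tolerance = 1e-6)
  # vibrational mode equals the 1D solve on the relative coordinate
  # (reduced mass 1/2): relative potential phi(|x|) at displacement around r0
  pairf <- dimer$pair
  rel <- make_model_potential("external", list(
    dimension = 1,
    value_fn = function(x) pairf$phi(abs(x)),
    gradient_fn = function(x) pairf$dphi(abs(x)) * sign(x),
    hessian_fn = function(x) pairf$d2phi(abs(x)),
    vectorized = TRUE))
  sys_rel <- thermal_system(1, masses = 25)
  e1 <- solve_effective_frequency(rel, r0, sys_rel)
  i1 <- which.max(r$omega2)
  expect_equal(r$omega2[i1], e1$omega2, tolerance = 1e-3)
})
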