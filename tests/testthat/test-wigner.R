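make_centroid <- function(model, xc, pc, system, ...) {
  list(xc = xc, pc = pc,
       eff = solve_effective_frequency(model, xc, system, ...))
}

test_that("QDO Wigner transform: center value, unit trace, marginal widths", {
  sys <- thermal_system(2)
  c0 <- make_centroid(fix_harmonic(omega = 1.3), 0.4, -0.2, sys)
  al <- c0$eff$alpha
  expect_equal(qdo_wigner_value(0.4, -0.2, c0, sys), 2 / al)
  # phase-space integral over dq dp / (2 pi hbar) = 1 (2D trapezoid)
  om <- 1.3
  sq <- sqrt(al / (2 * om)); sp <- sqrt(om * al / 2)
  qg <- seq(0.4 - 8 * sq, 0.4 + 8 * sq, length.out = 301)
  pg <- seq(-0.2 - 8 * sp, -0.2 + 8 * sp, length.out = 301)
  W <- outer(qg, pg, function(q, p) qdo_wigner_value(q, p, c0, sys))
  Z <- sum(W) * diff(qg)[1] * diff(pg)[1] / (2 * pi)
  expect_equal(Z, 1, tolerance = 1e-8)
  # marginal variances: hbar alpha / 2 M Omega and M Omega alpha hbar / 2
  vq <- sum(outer((qg - 0.4)^2, rep(1, 301)) * W) / sum(W)
  vp <- sum(outer(rep(1, 301), (pg + 0.2)^2) * W) / sum(W)
  expect_equal(vq, al / (2 * om), tolerance = 1e-8)
  expect_equal(vp, om * al / 2, tolerance = 1e-8)
})

test_that("centroid Metropolis reproduces harmonic moments and is deterministic", {
  sys <- thermal_system(2)
  m <- fix_harmonic()
  ens <- sample_centroid_ensemble(m, sys, 5000, seed = 13)
  # <xc^2> = 1/(beta M w^2), <pc^2> = M/beta, each within 3 sigma
  se_x <- sd(ens$xc^2) / sqrt(length(ens$xc) / 10)  # allow for chain correlation
  expect_lt(abs(mean(ens$xc^2) - 0.5), 3 * se_x)
  se_p <- sd(ens$pc^2) / sqrt(length(ens$pc))
  expect_lt(abs(mean(ens$pc^2) - 0.5), 3 * se_p)
  expect_gt(ens$acceptance, 0.2)
  expect_lt(ens$acceptance, 0.7)
  ens2 <- sample_centroid_ensemble(m, sys, 5000, seed = 13)
  expect_identical(ens$xc, ens2$xc)
  expect_identical(ens$pc, ens2$pc)
  # field-backed sampling agrees in distribution with the exact solve
  fld <- centroid_field(m, sys, c(-4, 4))
  ensf <- sample_centroid_ensemble(m, sys, 5000, seed = 13, field = fld)
  expect_identical(ens$xc, ensf$xc)
})

test_that("fluctuation sampling matches analytic widths and the total-variance identity", {
  sys <- thermal_system(3)
  m <- fix_harmonic(omega = 1.4)
  c0 <- make_centroid(m, 0.7, 0.1, sys)
  fl <- sample_qdo_fluctuations(c0, 1e5, sys, seed = 21)
  al <- c0$eff$alpha; om <- 1.4
  vq <- al / (2 * om); vp <- om * al / 2
  # sample variances within 3 sigma (var estimator sd ~ v * sqrt(2/n))
  expect_lt(abs(var(fl$q) - vq), 3 * vq * sqrt(2 / 1e5))
  expect_lt(abs(var(fl$p) - vp), 3 * vp * sqrt(2 / 1e5))
  # Var(xc) + Var(q - xc) = (hbar/2Mw) coth(beta hbar w / 2), analytically
  u <- 3 * 1.4 / 2
  expect_equal(1 / (3 * om^2) + vq, 1 / (2 * om * tanh(u)),
               tolerance = 1e-12)
  # high temperature: the cloud collapses onto the centroid
  hot <- make_centroid(m, 0.7, 0.1, thermal_system(1e-4))
  expect_lt(hot$eff$alpha, 1e-4)
})

test_that("barrier branch: positivity exactly below the pi bound, Maxwell limit", {
  sys <- thermal_system(1)
  om2 <- -seq(0.05, 9.8, length.out = 400)
  v <- barrier_momentum_variance(om2, sys)
  expect_identical(v > 0, sqrt(-om2) < pi)
  # high-T barrier: variance -> M/beta (classical Maxwell)
  sysh <- thermal_system(1e-4)
  expect_equal(barrier_momentum_variance(-4, sysh), 1 / 1e-4,
               tolerance = 1e-4)
  # sampling succeeds arbitrarily close to the bound and fails beyond it
  mk <- function(wb) {
    mb <- make_model_potential("parabolic_barrier", list(M = 1, omega_b = wb))
    list(xc = 0, pc = 0, eff = solve_effective_frequency(mb, 0, sys))
  }
  near <- mk(pi - 1e-6)
  s <- sample_barrier_marginal(near, sys, 2000, seed = 3)
  expect_true(all(is.finite(s$p)))
  # the combined variance closes continuously to zero at the bound
  expect_gt(var(s$p), 0)
  expect_lt(var(s$p), 1 / sys$beta)
  expect_error(sample_barrier_marginal(mk(1.1 * pi), sys, 10), "pi")
  expect_error(sample_qdo_fluctuations(near, 10, sys), "barrier")
})

test_that("Moyal estimators reproduce the numeric Boltzmann-operator Wigner transform", {
  sys <- thermal_system(2)
  m <- fix_harmonic()
  # numeric oracle: Wigner transform of the kernel rho(x,x') x' on the DVR grid
  sol <- grid_eigensolve(m, c(-10, 10), 481, 15, sys)
  xi <- which(abs(sol$grid) <= 1.5 + 1e-9)
  qg <- sol$grid[xi]
  pg <- seq(-1.5, 1.5, length.out = 11)
  wB <- exp(-sys$beta * (sol$energies - sol$energies[1]))
  psi <- sol$wavefunctions
  oracle_den <- matrix(0, length(qg), length(pg))
  oracle_op <- matrix(0i, length(qg), length(pg))
  for (ii in seq_along(xi)) {
    i0 <- xi[ii]
    J <- min(i0 - 1L, length(sol$grid) - i0)
    j <- seq(-J, J)
    rho <- as.numeric((psi[i0 + j, , drop = FALSE] *
                       psi[i0 - j, , drop = FALSE]) %*% wB)
    xr <- sol$grid[i0 - j]                 # right argument -> operator kernel
    ph <- exp(-1i * outer(2 * j * sol$dx, pg) / sol$hbar)
    oracle_den[ii, ] <- Re(drop(t(ph) %*% rho)) * 2 * sol$dx
    oracle_op[ii, ] <- drop(t(ph) %*% (rho * xr)) * 2 * sol$dx
  }
  # FK representation with the standard-position Moyal estimator
  fk_den <- fk_wigner_density(m, sys, qg, pg, seq(-6, 6, length.out = 241))
  fk_op <- fk_wigner_density(m, sys, qg, pg, seq(-6, 6, length.out = 241),
                             estimator = "position")
  ratio_fk <- fk_op / fk_den
  ratio_or <- oracle_op / oracle_den
  expect_lt(max(Mod(ratio_fk - ratio_or)), 1e-4)
  # at p = pc the standard-position estimator is the real position
  est <- operator_estimator("position", "standard")
  v <- est(q = 0.9, p = 0.3, xc = 0.1, pc = 0.3, omega2 = 2, alpha = 0.4,
           mass = 1.2)
  expect_identical(Im(v), 0)
  expect_identical(Re(v), 0.9)
  # kubo flavor: centroid variables
  estk <- operator_estimator("momentum", "kubo")
  expect_identical(estk(1, 2, 3, 4, 1, 0.5, 1), as.complex(4))
})

test_that("FK harmonic Boltzmann-Wigner reconstruction matches the closed form", {
  sys <- thermal_system(2)
  m <- fix_harmonic()
  qg <- seq(-2, 2, length.out = 41)
  pg <- seq(-2, 2, length.out = 41)
  fk <- Re(fk_wigner_density(m, sys, qg, pg, seq(-7, 7, length.out = 281)))
  u <- sys$beta / 2
  cl <- exp(-(2 * tanh(u)) * (outer(qg^2 / 2, rep(1, 41)) +
                              outer(rep(1, 41), pg^2 / 2)))
  expect_lt(max(abs(fk / sum(fk) - cl / sum(cl))) / max(cl / sum(cl)), 1e-6)
})
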