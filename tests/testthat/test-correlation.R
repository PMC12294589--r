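sys_h <- thermal_system(2)
mod_h <- fix_harmonic()
ens_h <- sample_centroid_ensemble(mod_h, sys_h, 2000, seed = 7)

test_that("harmonic universality: CW, planetary and Kubo CFs match closed forms", {
  dt <- 0.05; nsteps <- 200
  ex <- harmonic_position_cf(dt * (0:nsteps), sys_h, 1)
  exk <- harmonic_position_cf(dt * (0:nsteps), sys_h, 1, kind = "kubo")
  cw <- classical_wigner_correlation(mod_h, sys_h, ens_h, A = "position",
                                     B = "position", n_planets = 20,
                                     dt = dt, nsteps = nsteps, seed = 11)
  expect_lt(max(Mod(cw$values - ex$values) / cw$stderr), 3)
  # t = 0: the real part is the exact quantum <x^2>
  expect_lt(abs(Re(cw$values[1]) - 0.5 / tanh(1)), 3 * cw$stderr[1])
  pl <- planetary_correlation(mod_h, sys_h, ens_h, A = "position",
                              B = "position", n_planets = 20,
                              dt = dt, nsteps = nsteps, seed = 11)
  expect_lt(max(Mod(pl$values - ex$values) / pl$stderr), 3)
  # planetary and CW agree within combined sigma for the harmonic model
  expect_lt(max(Mod(pl$values - cw$values) /
                  sqrt(pl$stderr^2 + cw$stderr^2 + 1e-18)), 3)
  ku <- kubo_correlation(mod_h, sys_h, ens_h, A = "position", B = "position",
                         n_planets = 20, dt = dt, nsteps = nsteps, seed = 11)
  expect_lt(max(Mod(ku$values - exk$values) / ku$stderr), 3)
  expect_lt(abs(Re(ku$values[1]) - 1 / 2), 3 * ku$stderr[1])
  # Kubo momentum CF: (M/beta) cos(w t)
  kup <- kubo_correlation(mod_h, sys_h, ens_h, A = "momentum", B = "momentum",
                          n_planets = 20, dt = dt, nsteps = nsteps, seed = 11)
  expect_lt(max(Mod(kup$values - 0.5 * cos(kup$times)) / kup$stderr), 3.5)
  # B = identity: constant in time
  cid <- classical_wigner_correlation(mod_h, sys_h, ens_h, A = "position",
                                      B = "identity", n_planets = 5,
                                      dt = dt, nsteps = 50, seed = 11)
  expect_lt(max(Mod(cid$values - cid$values[1])), 1e-12)
})

test_that("Monte Carlo convergence is 1/sqrt(n)", {
  dt <- 0.1; nsteps <- 60
  ex <- harmonic_position_cf(dt * (0:nsteps), sys_h, 1)
  errs <- vapply(c(500, 2000, 8000), function(n) {
    ens <- sample_centroid_ensemble(mod_h, sys_h, n, seed = 3)
    cf <- classical_wigner_correlation(mod_h, sys_h, ens, A = "position",
                                       B = "position", n_planets = 4,
                                       dt = dt, nsteps = nsteps, seed = 5)
    sqrt(mean(Mod(cf$values - ex$values)^2))
  }, numeric(1))
  # error ratio over a 16-fold sample increase should be ~4 (loose band)
  expect_gt(errs[1] / errs[3], 2)
  expect_lt(errs[1] / errs[3], 9)
})

test_that("estimator/flavor guards reject invalid combinations", {
  expect_error(correlation_function(mod_h, sys_h, ens_h, propagator = "fk_cmd",
                                    flavor = "standard", dt = 0.1, nsteps = 5),
               "kubo")
  empty <- list(xc = numeric(0), pc = numeric(0), eff = list())
  expect_error(correlation_function(mod_h, sys_h, empty, dt = 0.1, nsteps = 5),
               "empty")
})

test_that("spectra: peaks, Parseval, Lorentzian width, QH relation", {
  ts <- seq(0, 80, 0.05)
  pure <- correlation_series(ts, cos(1.3 * ts))
  sp <- spectrum_from_cf(pure, window = "none", zero_pad = 4L)
  ipk <- order(Mod(sp$intensity), decreasing = TRUE)[1:2]
  expect_equal(sort(abs(sp$omega[ipk])), c(1.3, 1.3), tolerance = 0.01)
  # Parseval with no window, no padding
  spn <- spectrum_from_cf(pure, window = "none", zero_pad = 1L)
  two_sided <- c(pure$values, Conj(rev(pure$values[-1])))
  lhs <- sum(Mod(two_sided)^2) * 0.05
  rhs <- sum(Mod(spn$intensity)^2) * diff(spn$omega[1:2]) / (2 * pi)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # damped cosine -> Lorentzian of half-width gamma
  gam <- 0.2
  damp <- correlation_series(ts, exp(-gam * ts) * cos(2 * ts))
  sd2 <- spectrum_from_cf(damp, window = "none", zero_pad = 8L)
  pk <- which.max(Re(sd2$intensity))
  half <- Re(sd2$intensity[pk]) / 2
  above <- which(Re(sd2$intensity) > half & sd2$omega > 0)
  width <- (max(sd2$omega[above]) - min(sd2$omega[above])) / 2
  expect_equal(width, gam, tolerance = 0.05 * gam + 0.02)
  # harmonic standard/Kubo spectra are related pointwise by QH
  cs <- harmonic_position_cf(ts, sys_h, 1)
  ck <- harmonic_position_cf(ts, sys_h, 1, kind = "kubo")
  ss <- spectrum_from_cf(cs); sk <- spectrum_from_cf(ck)
  for (w0 in c(1, -1)) {
    i0 <- which.min(abs(ss$omega - w0))
    expect_equal(Re(ss$intensity[i0] / sk$intensity[i0]),
                 harmonic_qcf(w0, sys_h)$intensity, tolerance = 1e-4)
  }
})

test_that("harmonic quantum correction factor values and limits", {
  sys <- thermal_system(1)
  expect_identical(harmonic_qcf(0, sys)$intensity, 1)
  expect_equal(harmonic_qcf(1, sys)$intensity, 1 / (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(harmonic_qcf(1e-12, sys)$intensity, 1, tolerance = 1e-9)
  expect_equal(harmonic_qcf(50, sys)$intensity, 50, tolerance = 1e-6)
})

test_that("spectral ratio: identity, harmonic QH recovery, floor flags", {
  ts <- seq(0, 80, 0.05)
  cs <- harmonic_position_cf(ts, sys_h, 1)
  ss <- spectrum_from_cf(cs)
  r <- qcf_ratio(ss, ss)
  unflagged <- setdiff(seq_along(r$omega), r$flagged)
  expect_equal(unname(Mod(r$intensity[unflagged])),
               rep(1, length(unflagged)), tolerance = 1e-10)
  # FK-LPI-vs-classical surrogate: standard over Kubo recovers QH at +omega
  sk <- spectrum_from_cf(harmonic_position_cf(ts, sys_h, 1, kind = "kubo"))
  rq <- qcf_ratio(ss, sk)
  i1 <- which.min(abs(rq$omega - 1))
  expect_equal(Re(rq$intensity[i1]), harmonic_qcf(1, sys_h)$intensity,
               tolerance = 1e-3)
  expect_gt(length(rq$flagged), 0)   # noise tail engages the floor
  other <- spectrum_from_cf(harmonic_position_cf(seq(0, 40, 0.05), sys_h, 1))
  expect_error(qcf_ratio(ss, other), "common frequency grid")
})

test_that("intermediate scattering: Q = 0, stationary particle, ideal-gas self part", {
  box <- 10
  # Q = 0 gives N^2 at all times
  pos <- array(runif(5 * 4 * 6, 0, box), c(5, 4, 6))
  f0 <- intermediate_scattering(pos, 0, box, dt = 0.1)
  expect_equal(Re(f0$values), rep(16, 6), tolerance = 1e-12)
  expect_error(intermediate_scattering(pos, 0.37, box, dt = 0.1),
               "commensurate")
  # single stationary particle: unity for all t
  one <- array(2.2, c(3, 1, 5))
  f1 <- intermediate_scattering(one, 2 * pi / box, box, dt = 0.1)
  expect_equal(Re(f1$values), rep(1, 5), tolerance = 1e-12)
  # classical ideal gas self part: exp(-Q^2 kBT t^2 / 2M)
  set.seed(9)
  n_s <- 4000; N <- 1; nt <- 9
  beta <- 2; Q <- 2 * pi * 3 / box
  x0 <- runif(n_s, 0, box); v <- rnorm(n_s, 0, sqrt(1 / beta))
  tgrid <- seq(0, 0.8, length.out = nt)
  pos <- array(0, c(n_s, 1, nt))
  for (k in seq_len(nt)) pos[, 1, k] <- x0 + v * tgrid[k]
  fs <- intermediate_scattering(pos, Q, box, dt = tgrid[2], component = "self")
  ref <- exp(-Q^2 * tgrid^2 / (2 * beta))
  expect_lt(max(Mod(fs$values - ref)), 3 / sqrt(n_s) + 0.02)
})

test_that("diffusion estimates: bound motion, exponential VACF, MSD cross-check", {
  # bound harmonic motion: D = 0 within error (window = whole periods; the
  # undecayed oscillation also trips the tail warning)
  ts <- seq(0, 60, 0.01)
  tsp <- seq(0, 20 * pi, pi / 200)
  vac_h <- correlation_series(tsp, 0.5 * cos(tsp))
  d_h <- suppressWarnings(diffusion_from_vacf(vac_h))
  expect_lt(abs(d_h$D), 0.01)
  # synthetic exponential VACF: D = kBT / (M gamma) within 1%
  kT <- 0.7; gam <- 0.9
  vac_e <- correlation_series(ts, kT * exp(-gam * ts))
  d_e <- diffusion_from_vacf(vac_e)
  expect_equal(d_e$D, kT / gam, tolerance = 0.01)
  # MSD slope cross-check on simulated Langevin-free ballistic/diffusive toy:
  # velocities refreshed by an OU process with the same VACF
  set.seed(4)
  n <- 400; dt <- 0.01; nt <- 6000
  v <- rnorm(n, 0, sqrt(kT))
  x <- numeric(n)
  msd_t <- numeric(nt)
  a <- exp(-gam * dt); sdn <- sqrt(kT * (1 - a^2))
  xs <- matrix(0, nt, n)
  for (k in seq_len(nt)) {
    x <- x + v * dt
    v <- a * v + rnorm(n, 0, sdn)
    xs[k, ] <- x
  }
  tt <- dt * seq_len(nt)
  msd <- rowMeans(xs^2)
  sl <- unname(coef(lm(msd[tt > 30] ~ tt[tt > 30]))[2])
  expect_equal(sl / 2, kT / gam, tolerance = 0.15)  # 2 D t in 1D
  # non-decayed tail warns
  expect_warning(diffusion_from_vacf(correlation_series(ts, 1 + 0 * ts)),
                 "not decayed|plateau")
})

test_that("radial distribution: ideal gas, clamped pair, sum rule", {
  box <- 12; N <- 24
  set.seed(11)
  cfg <- matrix(runif(200 * N, 0, box), 200, N)
  g <- radial_distribution(cfg, bins = 24, box = box)
  # ideal gas: g = (N-1)/N ~ 1 within 3 sigma of the bin noise
  counts_per_bin <- 200 * N * (N - 1) / 24
  expect_lt(max(abs(g$g - (N - 1) / N)), 3.5 / sqrt(counts_per_bin / 24) )
  expect_lt(abs(mean(g$g) - (N - 1) / N), 0.02)
  # counting sum rule: integral rho g dV = N - 1
  dr <- diff(g$r[1:2])
  expect_equal(sum((N / box) * g$g * 2 * dr), N - 1, tolerance = 0.01)
  # two particles clamped at distance d: single-bin peak
  cfg2 <- matrix(rep(c(1, 1 + 2.7), each = 50), 50, 2)
  g2 <- radial_distribution(cfg2, bins = 30, box = box)
  expect_identical(sum(g2$g > 0), 1L)
  expect_lt(abs(g2$r[which.max(g2$g)] - 2.7), diff(g2$r[1:2]))
  expect_error(radial_distribution(matrix(0, 0, 2), box = 5), "zero config")
})
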