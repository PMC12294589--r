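# Shared fixtures and small numerical oracles for the suite.

fix_harmonic <- function(M = 1, omega = 1) {
  make_model_potential("harmonic", list(M = M, omega = omega))
}

fix_double_well <- function(a = 1, b = 1) {
  make_model_potential("double_well", list(a = a, b = b))
}

fix_quartic <- function(c = 1) make_model_potential("quartic", list(c = c))

fix_morse <- function(De = 2, a = 1, x0 = 0) {
  make_model_potential("morse", list(De = De, a = a, x0 = x0))
}

fix_pair_liquid <- function(N = 4L, L = N * 2^(1 / 6)) {
  make_model_potential("pair_liquid", list(
    n_particles = N, box_length = L,
    pair = list(type = "lennard_jones", epsilon = 1, sigma = 1)))
}

# central-difference derivative oracle
num_deriv <- function(f, x, h = 1e-4) (f(x + h) - f(x - h)) / (2 * h)

num_hess_scalar <- function(f, x, h = 1e-5) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# time-averaged absolute discrepancy between two correlation series
cf_discrepancy <- function(cf, ref) mean(Mod(cf$values - ref$values))
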