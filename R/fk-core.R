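#' Quantum width parameter of the quasi-density operator
#'
#' \eqn{\alpha(\Omega) = \coth(\hbar\Omega\beta/2) - 2/(\hbar\Omega\beta)} for
#' a real effective frequency \eqn{\Omega > 0}.  \eqn{\alpha} is dimensionless
#' and lies in (0, 1): it tends to \eqn{\hbar\Omega\beta/6} at high
#' temperature (the fluctuation cloud collapses onto the centroid) and to 1
#' in the ground-state limit.
#'
#' @param omega2 Squared effective frequency, strictly positive.  For
#'   barrier modes (\code{omega2 < 0}) use the analytically continued
#'   magnitude via \code{\link{barrier_alpha}} inside the barrier sampling
#'   branch instead.
#' @param system A \code{\link{thermal_system}}.
#' @return Dimensionless \eqn{\alpha}, vectorized over \code{omega2}.
#' @export
alpha_parameter <- function(omega2, system) {
  if (any(!is.finite(omega2)) || any(omega2 <= 0)) {
    stop("alpha_parameter requires omega2 > 0; barrier modes take the ",
         "analytically continued branch", call. = FALSE)
  }
  u <- system$hbar * sqrt(omega2) * system$beta / 2
  # series branch avoids the (u coth u - 1)/u cancellation at small u
  ifelse(u < 1e-3, u / 3 - u^3 / 45, (ucoth_sq(u^2) - 1) / u)
}

# Magnitude of the analytically continued alpha for a barrier mode
# (Omega = i|Omega|): alpha = i * barrier_alpha, barrier_alpha = 1/v - cot(v)
# with v = hbar*|Omega|*beta/2, positive for 0 < v < pi.
barrier_alpha <- function(omega2, system) {
  if (any(omega2 >= 0)) stop("barrier_alpha requires omega2 < 0", call. = FALSE)
  v <- system$hbar * sqrt(-omega2) * system$beta / 2
  (1 - ucoth_sq(-v^2)) / v
}

#' Gaussian smearing width of quantum position fluctuations
#'
#' The temperature-dependent variance of the Gaussian that smears the
#' potential around a centroid:
#' \deqn{a^2 = \frac{1}{M\Omega^2\beta}\left\{\frac{\hbar\Omega\beta}{2}
#'   \coth\frac{\hbar\Omega\beta}{2} - 1\right\},}
#' analytically continued through \eqn{\Omega^2 = 0} (free-particle limit
#' \eqn{\hbar^2\beta/12M}) to negative \eqn{\Omega^2} (the \eqn{\coth}
#' becomes a \eqn{\cot}), where it stays positive for
#' \eqn{\hbar|\Omega|\beta < 2\pi}.  At low temperature with \eqn{\Omega}
#' fixed it tends to the ground-state width \eqn{\hbar/2M\Omega}.
#'
#' @param omega2 Squared effective frequency (any finite real; negative
#'   values must satisfy \eqn{\hbar\sqrt{|\Omega^2|}\beta < 2\pi}).
#' @param system A \code{\link{thermal_system}}.
#' @param mass Mass of the mode (default: first system mass).
#' @return Smearing width \eqn{a^2 > 0} (length squared), vectorized.
#' @export
smearing_width <- function(omega2, system, mass = system$masses[1]) {
  if (any(!is.finite(omega2))) stop("omega2 must be finite", call. = FALSE)
  u2 <- (system$hbar * system$beta / 2)^2 * omega2
  # a^2 = (hbar^2 beta / 4M) * (u coth u - 1)/u^2, series-safe at u2 = 0
  h <- ifelse(abs(u2) < 1e-6,
              1 / 3 + u2 / 45 * (-1) + 2 * u2^2 / 945,
              (ucoth_sq(u2) - 1) / u2)
  (system$hbar^2 * system$beta / (4 * mass)) * h
}

#' Smeared Hessian by Gauss-Hermite quadrature
#'
#' Evaluates \eqn{\Omega^2 = \frac{1}{M}\,E[V''(x_c + y)]} with
#' \eqn{y \sim N(0, a^2)} by Gauss-Hermite quadrature, exact for polynomial
#' integrands up to the quadrature order.  The order is doubled automatically
#' when a self-consistency check between order \code{order} and
#' \code{2*order} exceeds \code{1e-8} relative.
#'
#' @param model 1D model potential.
#' @param xc Centroid position (scalar).
#' @param a2 Smearing width, positive.
#' @param mass Mode mass.
#' @param order Base Gauss-Hermite order (default 40).
#' @return Smeared squared-frequency candidate (scalar).
#' @export
smeared_hessian_quadrature <- function(model, xc, a2, mass = 1, order = 40L) {
  stopifnot_scalar(a2, "a2", positive = TRUE)
  f <- function(y) hessian_1d(model, xc + y)
  v1 <- gauss_expectation(f, 0, sqrt(a2), order) / mass
  v2 <- gauss_expectation(f, 0, sqrt(a2), 2L * order) / mass
  if (abs(v2 - v1) > 1e-8 * max(1, abs(v2))) v2 else v1
}

# Smeared potential value E[V(xc + y)], same quadrature ("V replaces V''").
smeared_potential_quadrature <- function(model, xc, a2, order = 40L) {
  f <- function(y) value_1d(model, xc + y)
  v1 <- gauss_expectation(f, 0, sqrt(a2), order)
  v2 <- gauss_expectation(f, 0, sqrt(a2), 2L * order)
  if (abs(v2 - v1) > 1e-8 * max(1, abs(v2))) v2 else v1
}

#' Smeared Hessian by gradient ("black-box") sampling
#'
#' Monte Carlo estimate of the integration-by-parts form
#' \eqn{\Omega^2 = \frac{1}{M a^2} E[V'(x_c+y)\, y]}, \eqn{y \sim N(0,a^2)},
#' which needs only force calls and therefore works with any external force
#' routine.  The estimator is unbiased; its standard error is reported from
#' the sample variance.  2500 samples are typically sufficient for
#' liquid-scale use.
#'
#' @inheritParams smeared_hessian_quadrature
#' @param n_samples Number of Gaussian displacement samples (>= 2; default
#'   2500).
#' @param seed Optional integer seed for the displacement draws.
#' @return List with \code{omega2} (estimate) and \code{stderr}.
#' @export
smeared_hessian_force_sampling <- function(model, xc, a2, mass = 1,
                                           n_samples = 2500L, seed = NULL) {
  stopifnot_scalar(a2, "a2", positive = TRUE)
  if (n_samples < 2L) stop("n_samples must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- stats::rnorm(n_samples, 0, sqrt(a2))
  vals <- gradient_1d(model, xc + y) * y / (mass * a2)
  list(omega2 = mean(vals), stderr = stats::sd(vals) / sqrt(n_samples))
}

#' Variational effective frequency at a centroid (1D)
#'
#' Iterates the coupled equations for the smearing width \eqn{a^2(\Omega)}
#' and the smeared Hessian \eqn{\Omega^2(a^2)} to a fixed point.  The
#' iteration starts from the bare Hessian (or, when that is non-positive,
#' from the high-temperature width \eqn{a^2 = \hbar^2\beta/12M}) and applies
#' a 0.5 damping factor if it oscillates.  Typically 5-10 iterations suffice
#' for anharmonic models at the default tolerance.
#'
#' @param model 1D model potential.
#' @param xc Centroid position.
#' @param system A \code{\link{thermal_system}}.
#' @param smearing \code{"quadrature"} (Gauss-Hermite; default) or
#'   \code{"force_sampling"} (gradient sampling).
#' @param tol Relative convergence tolerance on \eqn{\Omega^2}
#'   (default \code{1e-8}; absolute floor \code{1e-12} near
#'   \eqn{\Omega^2 = 0}).
#' @param max_iter Maximum iterations (default 200).
#' @param n_force_samples Sample count for \code{smearing =
#'   "force_sampling"}.
#' @param gh_order Gauss-Hermite base order.
#' @param seed Seed for force sampling draws.
#' @return Object of class \code{"fklpi_eff"}: list with \code{xc},
#'   \code{omega2}, \code{a2}, \code{alpha} (\code{NA} for barrier modes),
#'   \code{W1}, \code{smeared_V}, \code{iterations}, \code{converged}.
#' @export
solve_effective_frequency <- function(model, xc, system,
                                      smearing = c("quadrature",
                                                   "force_sampling"),
                                      tol = 1e-8, max_iter = 200L,
                                      n_force_samples = 2500L,
                                      gh_order = 40L, seed = NULL) {
  smearing <- match.arg(smearing)
  mass <- system$masses[1]
  smear <- function(a2) {
    if (smearing == "quadrature") {
      smeared_hessian_quadrature(model, xc, a2, mass, gh_order)
    } else {
      smeared_hessian_force_sampling(model, xc, a2, mass,
                                     n_force_samples, seed)$omega2
    }
  }
  bare <- hessian_1d(model, xc)[1L] / mass
  omega2 <- if (is.finite(bare) && bare > 0) {
    bare
  } else {
    smear(system$hbar^2 * system$beta / (12 * mass))
  }
  converged <- FALSE
  iter <- 0L
  prev_delta <- NA_real_
  damping <- 1
  while (iter < max_iter) {
    iter <- iter + 1L
    a2 <- smearing_width(omega2, system, mass)
    candidate <- smear(a2)
    delta <- candidate - omega2
    # damp only a non-contracting oscillation; a sign-alternating but
    # shrinking delta converges fastest undamped
    if (!is.na(prev_delta) && delta * prev_delta < 0 &&
        abs(delta) > 0.7 * abs(prev_delta)) damping <- 0.5
    omega2_new <- omega2 + damping * delta
    if (abs(omega2_new - omega2) <= max(tol * abs(omega2_new), 1e-12)) {
      omega2 <- omega2_new
      converged <- TRUE
      break
    }
    prev_delta <- delta
    omega2 <- omega2_new
  }
  a2 <- smearing_width(omega2, system, mass)
  res <- structure(list(
    xc = xc, omega2 = omega2, a2 = a2,
    alpha = if (omega2 > 0) alpha_parameter(omega2, system) else NA_real_,
    W1 = NA_real_, smeared_V = NA_real_,
    iterations = iter, converged = converged, mass = mass
  ), class = "fklpi_eff")
  res$smeared_V <- smeared_potential_quadrature(model, xc, a2, gh_order)
  res$W1 <- .w1_from_parts(res, system)
  res
}

#' @export
print.fklpi_eff <- function(x, ...) {
  cat(sprintf(
    "<fklpi_eff> xc = %g: omega2 = %g, a2 = %g, W1 = %g (%d iter%s)\n",
    x$xc, x$omega2, x$a2, x$W1, x$iterations,
    if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

# W1 = kT ln[sinh(u)/u] + V_a2(xc) - M Omega^2 a2 / 2, with the sin branch
# for barrier modes (valid for hbar|Omega|beta < 2pi).
.w1_from_parts <- function(eff, system) {
  u2 <- (system$hbar * system$beta / 2)^2 * eff$omega2
  lsinhc_sq(u2) / system$beta + eff$smeared_V -
    0.5 * eff$mass * eff$omega2 * eff$a2
}

#' Centroid potential from a converged effective-frequency result
#'
#' \deqn{W_1(x_c) = k_BT \ln\frac{\sinh(\hbar\Omega\beta/2)}
#'   {\hbar\Omega\beta/2} + V_{a^2}(x_c) - \frac{1}{2}M\Omega^2 a^2,}
#' where \eqn{V_{a^2}} is the potential smeared with the same width as the
#' Hessian.  For barrier modes the \eqn{\sinh} becomes a \eqn{\sin}
#' (requires \eqn{\hbar|\Omega|\beta < 2\pi}).  Harmonic models cancel the
#' smearing terms analytically, leaving the classical harmonic free energy
#' plus \eqn{\frac{1}{2}M\omega^2 x_c^2}.
#'
#' @param eff A converged \code{\link{solve_effective_frequency}} result.
#' @param model The model potential used for \code{eff} (only needed when
#'   the smeared potential has to be recomputed).
#' @param system A \code{\link{thermal_system}}.
#' @return Centroid potential \eqn{W_1(x_c)} (energy).
#' @export
centroid_potential <- function(eff, model = NULL, system) {
  if (!inherits(eff, "fklpi_eff")) stop("need an fklpi_eff result", call. = FALSE)
  if (!eff$converged) {
    warning("effective-frequency result is not converged", call. = FALSE)
  }
  if (is.na(eff$smeared_V)) {
    if (is.null(model)) stop("smeared potential missing; supply the model",
                             call. = FALSE)
    eff$smeared_V <- smeared_potential_quadrature(model, eff$xc, eff$a2)
  }
  .w1_from_parts(eff, system)
}

#' Log of the unnormalized centroid phase-space weight
#'
#' \eqn{-\beta p_c^2/2M - \beta W_1(x_c)} up to an additive constant; the
#' partition function is never computed because all ensemble averages are
#' ratios of weighted Monte Carlo sums.
#'
#' @param xc,pc Centroid position and momentum (vectors, per DOF).
#' @param W1 Centroid potential at \code{xc}.
#' @param system A \code{\link{thermal_system}}.
#' @return Log-weight (scalar).
#' @export
centroid_log_weight <- function(xc, pc, W1, system) {
  m <- system_masses(system, length(xc))
  -system$beta * (sum(pc^2 / (2 * m)) + W1)
}
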