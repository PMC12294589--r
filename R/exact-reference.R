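# Independent quantum-mechanical oracles: exact 1D statics/dynamics on a
# grid and closed-form harmonic results.  These exist for validation of the
# FK-LPI machinery and are never called from production sampling or
# propagation paths.

#' Exact 1D eigenstates on a grid
#'
#' Diagonalizes the 1D Hamiltonian in a Fourier-grid (Colbert-Miller
#' discrete variable representation) basis, whose kinetic matrix converges
#' exponentially with grid density for smooth potentials.
#'
#' @param model 1D model potential.
#' @param x_range Length-2 range; must contain the support of all requested
#'   states (checked via the boundary amplitude).
#' @param n_points Number of grid points (>= 200).
#' @param n_states Number of low-lying states to return.
#' @param system A \code{\link{thermal_system}} (mass and hbar).
#' @param boundary_tol Maximum allowed relative wavefunction amplitude at
#'   the grid edge (default 1e-8).
#' @return Object of class \code{"fklpi_spectral"}: \code{grid} (positions),
#'   \code{dx}, ascending \code{energies}, \code{wavefunctions} (columns,
#'   orthonormal with weight \code{dx}).
#' @export
grid_eigensolve <- function(model, x_range, n_points = 401L, n_states = 20L,
                            system, boundary_tol = 1e-8) {
  if (n_points < 200L) stop("n_points must be >= 200", call. = FALSE)
  if (model$dimension != 1L) stop("grid_eigensolve is 1D only", call. = FALSE)
  m <- system$masses[1]; hb <- system$hbar
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  dx <- x[2] - x[1]
  i <- seq_len(n_points)
  D <- outer(i, i, function(a, b) {
    ifelse(a == b, pi^2 / 3, 2 / (a - b)^2) * (-1)^(a - b)
  })
  Tm <- hb^2 / (2 * m * dx^2) * D
  H <- Tm + diag(value_1d(model, x))
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(eg$values)
  k <- seq_len(min(n_states, n_points))
  E <- eg$values[ord][k]
  psi <- eg$vectors[, ord[k], drop = FALSE] / sqrt(dx)
  # sign convention: make the largest-amplitude component positive
  for (j in seq_along(k)) {
    imax <- which.max(abs(psi[, j]))
    if (psi[imax, j] < 0) psi[, j] <- -psi[, j]
  }
  edge <- apply(abs(psi[c(1L, n_points), , drop = FALSE]), 2L, max) /
    apply(abs(psi), 2L, max)
  if (any(edge > boundary_tol)) {
    stop(sprintf(
      "state(s) %s not converged within x_range (boundary amplitude > %g)",
      paste(which(edge > boundary_tol) - 1L, collapse = ", "), boundary_tol),
      call. = FALSE)
  }
  structure(list(grid = x, dx = dx, energies = E, wavefunctions = psi,
                 mass = m, hbar = hb),
            class = "fklpi_spectral")
}

#' @export
print.fklpi_spectral <- function(x, ...) {
  cat(sprintf("<fklpi_spectral> %d states on %d-point grid [%g, %g]\n",
              length(x$energies), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

# Position and momentum matrices in the eigenbasis.  The momentum matrix
# uses the commutator identity P_nm = i M omega_nm X_nm (exact on the
# eigenbasis), avoiding numerical differentiation.
.op_matrix <- function(sol, op) {
  psi <- sol$wavefunctions
  if (op == "identity") return(diag(ncol(psi)) + 0i)
  X <- crossprod(psi, sol$grid * psi) * sol$dx
  if (op == "position") return(X + 0i)
  if (op == "momentum" || op == "velocity") {
    wnm <- outer(sol$energies, sol$energies, `-`) / sol$hbar
    P <- 1i * sol$mass * wnm * X
    if (op == "velocity") P <- P / sol$mass
    return(P)
  }
  stop(sprintf("unsupported operator '%s'", op), call. = FALSE)
}

#' Exact quantum correlation function from a spectral solution
#'
#' Spectral sum over thermally occupied states,
#' \deqn{C(t) = Z^{-1}\sum_{n,m} e^{-\beta E_n} A_{nm} B_{mn}
#'   e^{i\omega_{mn} t},\quad \omega_{mn} = (E_m - E_n)/\hbar,}
#' with the time-evolution sign convention fixed against the numeric
#' Wigner-transform oracle so that the harmonic position autocorrelation
#' equals \eqn{(\hbar/2M\omega)[\coth(\beta\hbar\omega/2)\cos\omega t
#' + i\sin\omega t]}.  The Kubo variant applies the per-transition weight
#' \eqn{(1 - e^{-\beta\hbar\omega_{mn}})/(\beta\hbar\omega_{mn})}.
#'
#' @param sol A \code{\link{grid_eigensolve}} solution.
#' @param opA,opB \code{"position"}, \code{"momentum"}, \code{"velocity"} or
#'   \code{"identity"}.
#' @param system A \code{\link{thermal_system}}.
#' @param times Numeric time grid.
#' @param kind \code{"standard"} or \code{"kubo"}.
#' @param tail_tol Maximum Boltzmann weight allowed in the last computed
#'   state (truncation check, default 1e-8).
#' @return A \code{\link{correlation_series}}.
#' @export
exact_correlation <- function(sol, opA, opB, system, times,
                              kind = c("standard", "kubo"),
                              tail_tol = 1e-8) {
  kind <- match.arg(kind)
  E <- sol$energies
  beta <- system$beta
  wB <- exp(-beta * (E - E[1]))
  if (wB[length(wB)] > tail_tol) {
    stop("insufficient states: Boltzmann tail not converged", call. = FALSE)
  }
  occ <- which(wB >= 1e-10)
  A <- .op_matrix(sol, opA); B <- .op_matrix(sol, opB)
  Z <- sum(wB[occ])
  wnm <- outer(E[occ], E, function(en, em) (em - en) / sol$hbar)
  coef <- (wB[occ] / Z) * A[occ, , drop = FALSE] *
    t(B[, occ, drop = FALSE])
  if (kind == "kubo") {
    bhw <- beta * sol$hbar * wnm
    f <- ifelse(abs(bhw) < 1e-8, 1 - bhw / 2, (1 - exp(-bhw)) / bhw)
    coef <- coef * f
  }
  vals <- vapply(times, function(t) {
    sum(coef * exp(1i * wnm * t))
  }, complex(1))
  correlation_series(times, vals, kind = kind, n_samples = NA_integer_)
}

#' Exact Boltzmann-Wigner function on a phase grid
#'
#' Numerically Wigner-transforms the (unnormalized) thermal density matrix
#' \eqn{\rho(x,x') = \sum_n e^{-\beta E_n}\psi_n(x)\psi_n(x')} via the
#' off-diagonal integral
#' \eqn{W(x,p)=\int d\eta\, e^{-ip\eta/\hbar}\rho(x+\eta/2, x-\eta/2)},
#' evaluated on the eigensolver grid (\eqn{\eta} runs over even multiples of
#' the grid spacing so both arguments stay on the grid).
#'
#' @param sol A \code{\link{grid_eigensolve}} solution.
#' @param system A \code{\link{thermal_system}}.
#' @param x_idx Indices of the grid points at which to evaluate (default:
#'   every grid point away from the edges).
#' @param p Momentum grid (numeric vector).
#' @return List with \code{x}, \code{p} and the real matrix \code{W}
#'   (\code{length(x) x length(p)}), unnormalized.
#' @export
exact_wigner_boltzmann <- function(sol, system, x_idx = NULL, p) {
  n <- length(sol$grid)
  wB <- exp(-system$beta * (sol$energies - sol$energies[1]))
  psi <- sol$wavefunctions
  if (is.null(x_idx)) x_idx <- seq(2L, n - 1L)
  W <- matrix(0, length(x_idx), length(p))
  hb <- sol$hbar
  for (ii in seq_along(x_idx)) {
    i0 <- x_idx[ii]
    J <- min(i0 - 1L, n - i0)
    j <- seq(-J, J)
    # rho(x + j dx, x - j dx), eta_j = 2 j dx
    rho <- as.numeric((psi[i0 + j, , drop = FALSE] *
                       psi[i0 - j, , drop = FALSE]) %*% wB)
    eta <- 2 * j * sol$dx
    ph <- exp(-1i * outer(eta, p) / hb)
    W[ii, ] <- Re(drop(t(ph) %*% rho)) * 2 * sol$dx
  }
  list(x = sol$grid[x_idx], p = p, W = W)
}

#' Closed-form harmonic position autocorrelation function
#'
#' Reference result used throughout the tests: standard flavor
#' \eqn{(\hbar/2M\omega)[\coth(\beta\hbar\omega/2)\cos\omega t + i
#' \sin\omega t]}, Kubo flavor \eqn{\cos(\omega t)/(\beta M \omega^2)}.
#'
#' @param times Time grid.
#' @param system A \code{\link{thermal_system}}.
#' @param omega Oscillator angular frequency.
#' @param mass Oscillator mass.
#' @param kind \code{"standard"} or \code{"kubo"}.
#' @return A \code{\link{correlation_series}}.
#' @export
harmonic_position_cf <- function(times, system, omega, mass = 1,
                                 kind = c("standard", "kubo")) {
  kind <- match.arg(kind)
  u <- system$beta * system$hbar * omega / 2
  vals <- if (kind == "standard") {
    (system$hbar / (2 * mass * omega)) *
      (cos(omega * times) / tanh(u) + 1i * sin(omega * times))
  } else {
    as.complex(cos(omega * times) / (system$beta * mass * omega^2))
  }
  correlation_series(times, vals, kind = kind, n_samples = NA_integer_)
}
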