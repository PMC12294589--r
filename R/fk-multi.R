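#' Effective-frequency matrix for multi-dimensional systems
#'
#' Multi-mode generalization of \code{\link{solve_effective_frequency}}:
#' iterates (i) the Gaussian-smeared, mass-weighted Hessian matrix,
#' (ii) its diagonalization into mode frequencies and vectors, and (iii)
#' per-mode smearing widths, until the mode frequencies are stable.
#' Displacements are drawn along the current normal modes with the per-mode
#' Gaussian widths.  Zero (translational) modes are assigned the
#' free-particle width \eqn{\hbar^2\beta/12} in mass-weighted coordinates;
#' imaginary modes outside the validity window of the analytic continuation
#' are flagged per mode and fall back to the free-particle width.
#'
#' Smearing uses a tensor-product Gauss-Hermite rule in normal-mode
#' coordinates for dimension <= 2 and common-random-number Monte Carlo
#' averaging of the Hessian for higher dimensions (the same standard-normal
#' draws are reused across iterations so the fixed point is deterministic
#' given the seed).
#'
#' @param model Model potential with dimension >= 2.
#' @param xc Centroid coordinate vector.
#' @param system A \code{\link{thermal_system}}.
#' @param tol Relative tolerance on the mode frequencies (default 1e-6).
#' @param max_iter Maximum iterations (default 100).
#' @param n_samples Monte Carlo sample count for dimension > 2 (default 400).
#' @param gh_order Per-axis Gauss-Hermite order for dimension <= 2.
#' @param seed Seed for the Monte Carlo displacement draws.
#' @return Object of class \code{"fklpi_eff_multi"}: \code{xc},
#'   \code{omega2} (mass-weighted mode eigenvalues, ascending), \code{a2}
#'   and \code{alpha} per mode, orthonormal \code{mode_vectors} (columns),
#'   \code{mode_valid}, \code{W1}, \code{iterations}, \code{converged}.
#' @export
effective_frequency_matrix <- function(model, xc, system, tol = 1e-6,
                                       max_iter = 100L, n_samples = 400L,
                                       gh_order = 16L, seed = NULL) {
  d <- model$dimension
  if (d < 2L) stop("use solve_effective_frequency for 1D models", call. = FALSE)
  xc <- as.numeric(xc)
  if (length(xc) != d) stop("xc length must equal model dimension", call. = FALSE)
  m <- system_masses(system, d)
  inv_sqrt_m <- 1 / sqrt(m)
  mw <- function(H) H * tcrossprod(inv_sqrt_m)  # M^{-1/2} H M^{-1/2}

  use_quad <- d <= 2L
  if (!use_quad) {
    if (!is.null(seed)) set.seed(seed)
    Z <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  } else {
    gh <- gauss_hermite_rule(gh_order)
    nodes <- as.matrix(expand.grid(rep(list(gh$x), d)))
    wts <- apply(as.matrix(expand.grid(rep(list(gh$w), d))), 1L, prod) /
      pi^(d / 2)
  }

  smear_matrices <- function(U, a2) {
    # returns list(K = E[mass-weighted Hessian], V = E[V]) under
    # y = M^{-1/2} U eta, eta_k ~ N(0, a2_k)
    sd_eta <- sqrt(a2)
    if (use_quad) {
      K <- matrix(0, d, d); V <- 0
      for (i in seq_len(nrow(nodes))) {
        eta <- sqrt(2) * sd_eta * nodes[i, ]
        y <- inv_sqrt_m * as.numeric(U %*% eta)
        K <- K + wts[i] * mw(potential_hessian(model, xc + y))
        V <- V + wts[i] * as.numeric(model$value(xc + y))
      }
      list(K = K, V = V)
    } else {
      K <- matrix(0, d, d); V <- 0
      for (i in seq_len(n_samples)) {
        eta <- sd_eta * Z[i, ]
        y <- inv_sqrt_m * as.numeric(U %*% eta)
        K <- K + mw(potential_hessian(model, xc + y))
        V <- V + as.numeric(model$value(xc + y))
      }
      list(K = K / n_samples, V = V / n_samples)
    }
  }

  widths_for <- function(lam) {
    ztol <- 1e-10 * max(1, max(abs(lam)))
    valid <- rep(TRUE, d)
    a2 <- numeric(d)
    for (k in seq_len(d)) {
      lk <- if (abs(lam[k]) < ztol) 0 else lam[k]
      a2[k] <- tryCatch(smearing_width(lk, system, mass = 1),
                        error = function(e) {
                          valid[k] <<- FALSE
                          system$hbar^2 * system$beta / 12
                        })
    }
    list(a2 = a2, valid = valid)
  }

  eg <- eigen(mw(potential_hessian(model, xc)), symmetric = TRUE)
  ord <- order(eg$values)
  lam <- eg$values[ord]; U <- eg$vectors[, ord, drop = FALSE]
  w <- widths_for(lam)
  converged <- FALSE
  iter <- 0L
  sm <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    sm <- smear_matrices(U, w$a2)
    eg <- eigen((sm$K + t(sm$K)) / 2, symmetric = TRUE)
    ord <- order(eg$values)
    lam_new <- eg$values[ord]; U <- eg$vectors[, ord, drop = FALSE]
    if (max(abs(lam_new - lam)) <= tol * max(1, max(abs(lam_new)))) {
      lam <- lam_new
      w <- widths_for(lam)
      converged <- TRUE
      break
    }
    lam <- lam_new
    w <- widths_for(lam)
  }
  alpha <- ifelse(lam > 0,
                  vapply(pmax(lam, .Machine$double.eps),
                         function(l2) alpha_parameter(l2, system), numeric(1)),
                  NA_real_)
  alpha[lam <= 0] <- NA_real_
  u2 <- (system$hbar * system$beta / 2)^2 * lam
  W1 <- sum(lsinhc_sq(u2)) / system$beta + (sm$V %||% NA_real_) -
    0.5 * sum(lam * w$a2)
  structure(list(
    xc = xc, omega2 = lam, a2 = w$a2, alpha = alpha,
    mode_vectors = U, mode_valid = w$valid, mass = m,
    W1 = W1, smeared_V = sm$V, iterations = iter, converged = converged
  ), class = "fklpi_eff_multi")
}

#' @export
print.fklpi_eff_multi <- function(x, ...) {
  cat(sprintf("<fklpi_eff_multi> %d modes, omega2 in [%g, %g], W1 = %g (%d iter%s)\n",
              length(x$omega2), min(x$omega2), max(x$omega2), x$W1,
              x$iterations, if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}
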