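#' Analytic Wigner transform of the quasi-density operator
#'
#' Per mode with \eqn{\Omega^2 > 0}:
#' \deqn{(\hat\delta_{FK})_W(q,p) = \frac{2}{\alpha}
#'   \exp\left(-\frac{M\Omega}{\hbar\alpha}(q-x_c)^2
#'   - \frac{1}{M\Omega\alpha\hbar}(p-p_c)^2\right),}
#' whose phase-space integral over \eqn{dq\,dp/2\pi\hbar} is exactly 1
#' (unit trace).  Multi-mode results multiply over modes.
#'
#' @param q,p Phase-space point (vectors per DOF, or vectors of scalar
#'   points for a 1D mode).
#' @param centroid A centroid sample: list with \code{xc}, \code{pc} and an
#'   effective-frequency result \code{eff} (fields \code{omega2},
#'   \code{alpha}, \code{mass}).
#' @param system A \code{\link{thermal_system}}.
#' @return Positive Wigner-transform value(s).
#' @export
qdo_wigner_value <- function(q, p, centroid, system) {
  eff <- centroid$eff
  if (any(eff$omega2 <= 0)) {
    stop("barrier mode present (omega2 <= 0): use sample_barrier_marginal",
         call. = FALSE)
  }
  omega <- sqrt(eff$omega2); alpha <- eff$alpha
  m <- eff$mass; hb <- system$hbar
  if (length(eff$omega2) == 1L) {
    (2 / alpha) * exp(-(m * omega / (hb * alpha)) * (q - centroid$xc)^2 -
                      (1 / (m * omega * alpha * hb)) * (p - centroid$pc)^2)
  } else {
    prod((2 / alpha) *
           exp(-(m * omega / (hb * alpha)) * (q - centroid$xc)^2 -
               (1 / (m * omega * alpha * hb)) * (p - centroid$pc)^2))
  }
}

#' Metropolis sampling of the FK centroid ensemble
#'
#' Runs a Metropolis chain in the centroid position targeting
#' \eqn{\exp(-\beta W_1(x_c))} and draws centroid momenta exactly from the
#' Maxwell distribution \eqn{N(0, M/\beta)}.  Each retained sample carries
#' its converged effective-frequency result.  Proposals are isotropic
#' Gaussians; the step is auto-tuned during burn-in to a 30-50\% acceptance
#' rate and then frozen.  A proposal where the effective-frequency solve
#' fails (e.g. a barrier continuation out of range) is rejected and counted.
#'
#' @param model 1D model potential.
#' @param system A \code{\link{thermal_system}}.
#' @param n Number of retained samples.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param x0 Chain start (default 0).
#' @param step Initial proposal standard deviation (default: thermal width
#'   estimate).
#' @param burn_in Burn-in sweeps (default 500).
#' @param thin Thinning stride (default 5).
#' @param field Optional \code{\link{centroid_field}}; when supplied,
#'   \eqn{W_1} and the attached effective-frequency data are interpolated
#'   from the field's splines (fast path for production runs).
#' @param ... Further options for \code{\link{solve_effective_frequency}}.
#' @return Object of class \code{"fklpi_centroids"}: vectors \code{xc},
#'   \code{pc}, \code{log_weight}, list \code{eff}, plus \code{acceptance},
#'   \code{step} and \code{n_eff_failures} attributes.
#' @export
sample_centroid_ensemble <- function(model, system, n, seed, x0 = 0,
                                     step = NULL, burn_in = 500L, thin = 5L,
                                     field = NULL, ...) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  mass <- system$masses[1]
  eff_at <- function(xc) {
    if (!is.null(field)) field_eff(field, xc)
    else solve_effective_frequency(model, xc, system, ...)
  }
  if (is.null(step)) step <- 1 / sqrt(system$beta * mass)
  cur <- eff_at(x0)
  if (!is.null(cur$converged) && !cur$converged) {
    stop("effective-frequency solve failed at the chain start", call. = FALSE)
  }
  n_fail <- 0L
  accept_window <- 0L
  n_window <- 0L
  n_acc_total <- 0L
  n_prop_total <- 0L
  xs <- numeric(n)
  effs <- vector("list", n)
  kept <- 0L
  sweep <- 0L
  total_sweeps <- burn_in + n * thin
  while (kept < n) {
    sweep <- sweep + 1L
    xp <- cur$xc + stats::rnorm(1L, 0, step)
    prop <- tryCatch(eff_at(xp), error = function(e) NULL)
    ok <- !is.null(prop) && isTRUE(prop$converged %||% TRUE) &&
      is.finite(prop$W1)
    if (!ok) {
      n_fail <- n_fail + 1L
    } else if (log(stats::runif(1L)) <
               -system$beta * (prop$W1 - cur$W1)) {
      cur <- prop
      accept_window <- accept_window + 1L
      if (sweep > burn_in) n_acc_total <- n_acc_total + 1L
    }
    n_window <- n_window + 1L
    if (sweep > burn_in) n_prop_total <- n_prop_total + 1L
    if (sweep <= burn_in && n_window >= 50L) {
      rate <- accept_window / n_window
      if (rate > 0.5) step <- step * 1.25
      if (rate < 0.3) step <- step * 0.8
      accept_window <- 0L; n_window <- 0L
    }
    if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      xs[kept] <- cur$xc
      effs[[kept]] <- cur
    }
  }
  pc <- stats::rnorm(n, 0, sqrt(mass / system$beta))
  lw <- vapply(seq_len(n), function(i) {
    centroid_log_weight(xs[i], pc[i], effs[[i]]$W1, system)
  }, numeric(1))
  structure(list(
    xc = xs, pc = pc, eff = effs, log_weight = lw,
    acceptance = if (n_prop_total > 0) n_acc_total / n_prop_total else NA_real_,
    step = step, n_eff_failures = n_fail, seed = seed
  ), class = "fklpi_centroids")
}

#' @export
print.fklpi_centroids <- function(x, ...) {
  cat(sprintf("<fklpi_centroids> %d samples, acceptance %.2f, step %.3g\n",
              length(x$xc), x$acceptance, x$step))
  invisible(x)
}

# Lightweight centroid-sample accessor
centroid_sample <- function(centroids, i) {
  list(xc = centroids$xc[i], pc = centroids$pc[i], eff = centroids$eff[[i]])
}

#' Sample quantum fluctuations around a centroid
#'
#' Draws independent Gaussian phase-space points per mode:
#' \eqn{q \sim N(x_c, \hbar\alpha/2M\Omega)},
#' \eqn{p \sim N(p_c, M\Omega\alpha\hbar/2)} — the widths of the analytic
#' quasi-density-operator Wigner transform.  At high temperature
#' \eqn{\alpha \to 0} and the cloud collapses onto the centroid.
#'
#' @param centroid Centroid sample (list with \code{xc}, \code{pc},
#'   \code{eff}); all modes must have \eqn{\Omega^2 > 0}.
#' @param n Number of fluctuation points.
#' @param system A \code{\link{thermal_system}}.
#' @param seed Optional seed.
#' @return List with matrices/vectors \code{q} and \code{p} (\code{n} rows).
#' @export
sample_qdo_fluctuations <- function(centroid, n, system, seed = NULL) {
  eff <- centroid$eff
  if (any(eff$omega2 <= 0)) {
    stop("barrier mode (omega2 <= 0): use sample_barrier_marginal",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  omega <- sqrt(eff$omega2)
  var_q <- system$hbar * eff$alpha / (2 * eff$mass * omega)
  var_p <- eff$mass * omega * eff$alpha * system$hbar / 2
  d <- length(eff$omega2)
  if (d == 1L) {
    list(q = stats::rnorm(n, centroid$xc, sqrt(var_q)),
         p = stats::rnorm(n, centroid$pc, sqrt(var_p)))
  } else {
    q <- sweep(matrix(stats::rnorm(n * d), n, d), 2L, sqrt(var_q), `*`)
    p <- sweep(matrix(stats::rnorm(n * d), n, d), 2L, sqrt(var_p), `*`)
    list(q = sweep(q, 2L, centroid$xc, `+`),
         p = sweep(p, 2L, centroid$pc, `+`))
  }
}

#' Combined momentum variance of the barrier branch
#'
#' After integrating the centroid momentum out of the sampling function,
#' the remaining Gaussian in \eqn{p} has variance
#' \eqn{M/\beta + M\Omega\alpha\hbar/2} analytically continued to
#' \eqn{\Omega^2 < 0}, i.e. \eqn{M/\beta - \hbar M|\Omega|\alpha_b/2} with
#' \eqn{\alpha_b = 1/v - \cot v}, \eqn{v = \hbar|\Omega|\beta/2}.  It is
#' positive exactly when \eqn{\hbar|\Omega|\beta < \pi}.
#'
#' @param omega2 Negative squared frequency (vectorized).
#' @param system A \code{\link{thermal_system}}.
#' @param mass Mode mass.
#' @return Combined momentum variance (may be negative beyond the bound;
#'   callers guard on positivity).
#' @export
barrier_momentum_variance <- function(omega2, system,
                                      mass = system$masses[1]) {
  if (any(omega2 >= 0)) stop("omega2 must be negative", call. = FALSE)
  ab <- barrier_alpha(omega2, system)
  mass / system$beta - system$hbar * mass * sqrt(-omega2) * ab / 2
}

#' Phase-space sampling at a barrier centroid
#'
#' For a single barrier mode (\eqn{\Omega^2 < 0}) the direct momentum
#' sampling is ill-defined; instead the centroid momentum is integrated out
#' analytically.  Positions come from the continued position Gaussian
#' \eqn{N(x_c, \hbar\alpha_b/2M|\Omega|)} and momenta from the combined
#' Gaussian of \code{\link{barrier_momentum_variance}}, which is real and
#' positive as long as \eqn{\hbar|\Omega|\beta < \pi}.
#'
#' @param centroid Centroid sample whose \code{eff} has \eqn{\Omega^2 < 0}.
#' @param system A \code{\link{thermal_system}}.
#' @param n Number of samples.
#' @param seed Optional seed.
#' @return List with vectors \code{q}, \code{p}.
#' @export
sample_barrier_marginal <- function(centroid, system, n, seed = NULL) {
  eff <- centroid$eff
  if (eff$omega2 >= 0) {
    stop("sample_barrier_marginal requires omega2 < 0", call. = FALSE)
  }
  absO <- sqrt(-eff$omega2)
  if (system$hbar * absO * system$beta >= pi) {
    stop(sprintf(
      "barrier sampling invalid: hbar*|Omega|*beta = %.4g >= pi",
      system$hbar * absO * system$beta), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ab <- barrier_alpha(eff$omega2, system)
  var_q <- system$hbar * ab / (2 * eff$mass * absO)
  var_p <- barrier_momentum_variance(eff$omega2, system, eff$mass)
  list(q = stats::rnorm(n, centroid$xc, sqrt(var_q)),
       p = stats::rnorm(n, 0, sqrt(var_p)))
}

#' Phase-space estimators for Boltzmann-operator products
#'
#' Builds the per-sample estimator of \eqn{(e^{-\beta\hat H}\hat A)_W /
#' (e^{-\beta\hat H})_W} used on the A side of the classical Wigner
#' correlation formula.  For the standard flavor the Moyal product of the
#' Gaussian quasi-density operator with \eqn{\hat x} or \eqn{\hat p} gives
#' complex linear estimators; for the Kubo flavor the centroid variables
#' themselves are the estimators (the convention adopted from the FK-LPI
#' literature, validated against harmonic closed forms in the test suite).
#'
#' @param kind \code{"identity"}, \code{"position"}, \code{"momentum"} or
#'   \code{"velocity"}.
#' @param flavor \code{"standard"} or \code{"kubo"}.
#' @return A function \code{f(q, p, xc, pc, omega2, alpha, mass)} returning
#'   a complex vector (vectorized over samples).
#' @export
operator_estimator <- function(kind = c("position", "momentum", "velocity",
                                        "identity"),
                               flavor = c("standard", "kubo")) {
  kind <- match.arg(kind)
  flavor <- match.arg(flavor)
  if (flavor == "kubo") {
    switch(kind,
      identity = function(q, p, xc, pc, omega2, alpha, mass)
        rep(1 + 0i, length(q)),
      position = function(q, p, xc, pc, omega2, alpha, mass)
        as.complex(xc),
      momentum = function(q, p, xc, pc, omega2, alpha, mass)
        as.complex(pc),
      velocity = function(q, p, xc, pc, omega2, alpha, mass)
        as.complex(pc / mass))
  } else {
    switch(kind,
      identity = function(q, p, xc, pc, omega2, alpha, mass)
        rep(1 + 0i, length(q)),
      position = function(q, p, xc, pc, omega2, alpha, mass) {
        omega <- sqrt(omega2)
        q + 1i * (p - pc) / (mass * omega * alpha)
      },
      momentum = function(q, p, xc, pc, omega2, alpha, mass) {
        omega <- sqrt(omega2)
        p - 1i * (mass * omega / alpha) * (q - xc)
      },
      velocity = function(q, p, xc, pc, omega2, alpha, mass) {
        omega <- sqrt(omega2)
        (p - 1i * (mass * omega / alpha) * (q - xc)) / mass
      })
  }
}

#' Centroid-integrated FK Boltzmann-Wigner density
#'
#' Numerically integrates the centroid representation of the
#' Boltzmann-Wigner function,
#' \eqn{(e^{-\beta\hat H})_W(q,p) \approx \int dx_c\, dp_c\,
#' \rho_{FK}(x_c,p_c)\,(\hat\delta_{FK})_W(q,p)}, over a centroid-position
#' grid (the centroid-momentum integral is done analytically since both
#' factors are Gaussian in \eqn{p_c}).  With \code{estimator = "position"}
#' it returns the operator product \eqn{(e^{-\beta\hat H}\hat x)_W} instead.
#' Used for validation against the exact grid oracle; 1D only.
#'
#' @param model 1D model potential.
#' @param system A \code{\link{thermal_system}}.
#' @param q,p Numeric vectors defining the phase grid (outer product).
#' @param xc_grid Centroid integration grid (should cover the thermal
#'   support).
#' @param estimator \code{"identity"} (density) or \code{"position"}.
#' @param ... Options for \code{\link{solve_effective_frequency}}.
#' @return Matrix of dimension \code{length(q) x length(p)} (complex when
#'   \code{estimator = "position"}).
#' @export
fk_wigner_density <- function(model, system, q, p, xc_grid,
                              estimator = c("identity", "position"), ...) {
  estimator <- match.arg(estimator)
  mass <- system$masses[1]
  hb <- system$hbar
  effs <- lapply(xc_grid, function(x)
    solve_effective_frequency(model, x, system, ...))
  omega2 <- vapply(effs, `[[`, numeric(1), "omega2")
  if (any(omega2 <= 0)) {
    stop("fk_wigner_density currently requires omega2 > 0 on the grid",
         call. = FALSE)
  }
  alpha <- vapply(effs, `[[`, numeric(1), "alpha")
  W1 <- vapply(effs, `[[`, numeric(1), "W1")
  omega <- sqrt(omega2)
  dxc <- diff(xc_grid)
  wq <- c(dxc / 2, 0) + c(0, dxc / 2)       # trapezoid weights
  Vc <- mass / system$beta                  # centroid momentum variance
  Vq <- mass * omega * alpha * hb / 2       # QDO momentum width
  Aq <- mass * omega / (hb * alpha)         # QDO position exponent
  wfac <- exp(-system$beta * (W1 - min(W1))) * wq *
    (2 / alpha) * sqrt(2 * pi * Vc * Vq / (Vc + Vq)) / (2 * pi * hb)
  out <- matrix(if (estimator == "identity") 0 else 0i,
                length(q), length(p))
  for (j in seq_along(p)) {
    pj <- p[j]
    pterm <- exp(-pj^2 / (2 * (Vc + Vq)))
    for (i in seq_along(q)) {
      qi <- q[i]
      g <- wfac * exp(-Aq * (qi - xc_grid)^2) * pterm
      if (estimator == "identity") {
        out[i, j] <- sum(g)
      } else {
        est <- qi + 1i * pj * Vq / ((Vc + Vq) * mass * omega * alpha)
        out[i, j] <- sum(g * est)
      }
    }
  }
  out
}
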