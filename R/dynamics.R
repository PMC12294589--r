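#' Spline cache of the centroid potential and effective frequency (1D)
#'
#' Solves the effective-frequency equations on a position grid once per
#' (model, temperature) and exposes cubic-spline interpolants for
#' \eqn{W_1(x_c)}, its negative derivative (the centroid force) and
#' \eqn{\Omega^2(x_c)}.  Queries outside the grid transparently extend the
#' grid and refit.  The grid should cover the sampled centroid range plus
#' several thermal widths; the companion sampler and propagators do this by
#' construction when given the field.
#'
#' @param model 1D model potential.
#' @param system A \code{\link{thermal_system}}.
#' @param x_range Length-2 numeric range to cover.
#' @param n_grid Number of grid nodes (default 201).
#' @param ... Options passed to \code{\link{solve_effective_frequency}}.
#' @return Object of class \code{"fklpi_field"} with closures \code{W1},
#'   \code{force}, \code{omega2}, and the node tables in \code{$table}.
#' @export
centroid_field <- function(model, system, x_range, n_grid = 201L, ...) {
  env <- new.env(parent = emptyenv())
  env$model <- model; env$system <- system
  env$opts <- list(...)
  build <- function(lo, hi) {
    xs <- seq(lo, hi, length.out = env$n_nodes %||% n_grid)
    effs <- lapply(xs, function(x)
      do.call(solve_effective_frequency,
              c(list(model = env$model, xc = x, system = env$system),
                env$opts)))
    conv <- vapply(effs, `[[`, logical(1), "converged")
    if (!all(conv)) {
      stop(sprintf("effective-frequency solve failed at %d grid node(s)",
                   sum(!conv)), call. = FALSE)
    }
    env$xs <- xs
    env$W1v <- vapply(effs, `[[`, numeric(1), "W1")
    env$om2v <- vapply(effs, `[[`, numeric(1), "omega2")
    env$a2v <- vapply(effs, `[[`, numeric(1), "a2")
    env$sW1 <- stats::splinefun(xs, env$W1v, method = "fmm")
    env$som2 <- stats::splinefun(xs, env$om2v, method = "fmm")
    env$lo <- lo; env$hi <- hi
    pos <- env$om2v[env$om2v > 0]
    env$om2_floor <- if (length(pos)) min(pos) else 1e-12
    invisible(NULL)
  }
  env$n_nodes <- n_grid
  build(x_range[1], x_range[2])
  ensure <- function(x) {
    r <- range(x)
    if (r[1] < env$lo || r[2] > env$hi) {
      pad <- 0.25 * (env$hi - env$lo)
      lo <- min(env$lo, r[1] - pad); hi <- max(env$hi, r[2] + pad)
      env$n_nodes <- max(env$n_nodes,
                         ceiling(env$n_nodes * (hi - lo) /
                                   (env$hi - env$lo)))
      build(lo, hi)
    }
  }
  structure(list(
    W1 = function(x) { ensure(x); env$sW1(x) },
    force = function(x) { ensure(x); -env$sW1(x, deriv = 1L) },
    omega2 = function(x) { ensure(x); env$som2(x) },
    env = env
  ), class = "fklpi_field")
}

#' @export
print.fklpi_field <- function(x, ...) {
  cat(sprintf("<fklpi_field> %d nodes on [%g, %g]\n",
              length(x$env$xs), x$env$lo, x$env$hi))
  invisible(x)
}

# Effective-frequency data interpolated from a field (fast sampling path).
field_eff <- function(field, xc) {
  om2 <- field$omega2(xc)
  sys <- field$env$system
  mass <- sys$masses[1]
  structure(list(
    xc = xc, omega2 = om2,
    a2 = smearing_width(om2, sys, mass),
    alpha = if (om2 > 0) alpha_parameter(om2, sys) else NA_real_,
    W1 = field$W1(xc), smeared_V = NA_real_,
    iterations = 0L, converged = TRUE, mass = mass
  ), class = "fklpi_eff")
}

#' Centroid force
#'
#' \eqn{-dW_1/dx_c}.  In 1D the force comes from the field's spline; in
#' multi-D it is computed by central differences of \eqn{W_1} with one
#' effective-frequency solve per displacement.
#'
#' @param field_or_model A \code{\link{centroid_field}} (1D) or a model
#'   potential (multi-D).
#' @param xc Centroid coordinate(s).
#' @param system Required for the multi-D path.
#' @param h Central-difference step for the multi-D path.
#' @return Force vector (or vectorized 1D forces).
#' @export
centroid_force <- function(field_or_model, xc, system = NULL, h = 1e-4) {
  if (inherits(field_or_model, "fklpi_field")) {
    return(field_or_model$force(xc))
  }
  model <- field_or_model
  if (is.null(system)) stop("multi-D centroid force needs the system", call. = FALSE)
  d <- model$dimension
  f <- numeric(d)
  for (i in seq_len(d)) {
    xp <- xc; xp[i] <- xp[i] + h
    xm <- xc; xm[i] <- xm[i] - h
    wp <- effective_frequency_matrix(model, xp, system)$W1
    wm <- effective_frequency_matrix(model, xm, system)$W1
    f[i] <- -(wp - wm) / (2 * h)
  }
  f
}

# ---- classical propagation ------------------------------------------------

# Vectorized velocity-Verlet for an ensemble of independent 1D phase points.
# record(k, q, p) is called with k = 0 for the initial state and after each
# step; gradient_fn must be vectorized over positions.
verlet_ensemble_1d <- function(gradient_fn, q, p, mass, dt, nsteps, record) {
  record(0L, q, p)
  F <- -gradient_fn(q)
  for (k in seq_len(nsteps)) {
    p_half <- p + 0.5 * dt * F
    q <- q + dt * p_half / mass
    F <- -gradient_fn(q)
    p <- p_half + 0.5 * dt * F
    record(k, q, p)
  }
  list(q = q, p = p)
}

#' Classical trajectory by velocity Verlet
#'
#' @param model Model potential (any dimension).
#' @param q0,p0 Initial coordinates and momenta (vectors of the model
#'   dimension).
#' @param dt Time step (positive; a warning is issued when
#'   \eqn{dt\,\omega_{max} > 0.1} estimated from the initial Hessian).
#' @param nsteps Number of steps.
#' @param system A \code{\link{thermal_system}} (for masses).
#' @return Object of class \code{"fklpi_traj"}: \code{times}, matrices
#'   \code{q}, \code{p} (\code{nsteps+1} rows) and \code{energy}.
#' @export
classical_trajectory <- function(model, q0, p0, dt, nsteps, system) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  d <- model$dimension
  q0 <- as.numeric(q0); p0 <- as.numeric(p0)
  m <- system_masses(system, d)
  if (model$provides_hessian) {
    H <- potential_hessian(model, q0)
    wmax2 <- max(abs(eigen(H / sqrt(tcrossprod(m)), symmetric = TRUE,
                           only.values = TRUE)$values))
    if (dt * sqrt(wmax2) > 0.1) {
      warning(sprintf("dt * omega_max = %.3g > 0.1; integration may be inaccurate",
                      dt * sqrt(wmax2)), call. = FALSE)
    }
  }
  Q <- matrix(NA_real_, nsteps + 1L, d)
  P <- matrix(NA_real_, nsteps + 1L, d)
  E <- numeric(nsteps + 1L)
  q <- q0; p <- p0
  store <- function(k) {
    Q[k + 1L, ] <<- q; P[k + 1L, ] <<- p
    E[k + 1L] <<- as.numeric(model$value(q)) + sum(p^2 / (2 * m))
  }
  store(0L)
  F <- -as.numeric(model$gradient(q))
  for (k in seq_len(nsteps)) {
    p <- p + 0.5 * dt * F
    q <- q + dt * p / m
    F <- -as.numeric(model$gradient(q))
    if (any(!is.finite(F))) stop("non-finite force encountered", call. = FALSE)
    p <- p + 0.5 * dt * F
    store(k)
  }
  structure(list(times = dt * (0:nsteps), q = Q, p = P, energy = E,
                 dt = dt, kind = "classical"),
            class = "fklpi_traj")
}

#' @export
print.fklpi_traj <- function(x, ...) {
  cat(sprintf("<fklpi_traj> %s, %d steps of dt = %g, %d DOF\n",
              x$kind, length(x$times) - 1L, x$dt, ncol(x$q)))
  invisible(x)
}

# ---- planetary propagation ------------------------------------------------

# Convert physical planet coordinates to dimensionless ones at centroid xc.
planet_to_dimensionless <- function(q, p, xc, pc, omega2, system, mass) {
  omega <- sqrt(omega2)
  alpha <- alpha_parameter(omega2, system)
  s <- sqrt(mass * omega / (system$hbar * alpha))
  list(qt = s * (q - xc), pt = (p - pc) / (system$hbar * alpha * s))
}

planet_to_physical <- function(qt, pt, xc, pc, omega2, system, mass) {
  omega <- sqrt(omega2)
  alpha <- alpha_parameter(omega2, system)
  s <- sqrt(mass * omega / (system$hbar * alpha))
  list(q = xc + qt / s, p = pc + system$hbar * alpha * s * pt)
}

# Vectorized planetary step ensemble: centroids on W1 by velocity Verlet,
# planets rotated through Omega(xc_mid)*dt in dimensionless coordinates.
# record(k, q, p, xc, pc) receives physical planet coordinates.
planetary_ensemble <- function(field, xc, pc, q0, p0, dt, nsteps, system,
                               record,
                               barrier_policy = c("clamp", "error")) {
  barrier_policy <- match.arg(barrier_policy)
  mass <- system$masses[1]
  floor_om2 <- field$env$om2_floor
  omega2_at <- function(x) {
    om2 <- field$omega2(x)
    bad <- om2 <= 0
    if (any(bad)) {
      if (barrier_policy == "error") {
        stop("planetary trajectory entered a barrier region (omega2 <= 0)",
             call. = FALSE)
      }
      om2[bad] <- floor_om2
    }
    om2
  }
  om2 <- omega2_at(xc)
  dl <- planet_to_dimensionless(q0, p0, xc, pc, om2, system, mass)
  qt <- dl$qt; pt <- dl$pt
  emit <- function(k, xc, pc, om2) {
    ph <- planet_to_physical(qt, pt, xc, pc, om2, system, mass)
    record(k, ph$q, ph$p, xc, pc)
  }
  emit(0L, xc, pc, om2)
  F <- field$force(xc)
  for (k in seq_len(nsteps)) {
    pc_half <- pc + 0.5 * dt * F
    xc_new <- xc + dt * pc_half / mass
    F <- field$force(xc_new)
    pc <- pc_half + 0.5 * dt * F
    om2_mid <- omega2_at(0.5 * (xc + xc_new))
    th <- sqrt(om2_mid) * dt
    ct <- cos(th); st <- sin(th)
    qt_new <- ct * qt + st * pt
    pt <- -st * qt + ct * pt
    qt <- qt_new
    xc <- xc_new
    om2 <- omega2_at(xc)
    emit(k, xc, pc, om2)
  }
  invisible(list(xc = xc, pc = pc, qt = qt, pt = pt))
}

#' Planetary trajectory
#'
#' Ensemble-conserving propagation: the centroid moves classically on the
#' centroid potential \eqn{W_1} (velocity Verlet) while the fluctuation
#' ("planet") phase point rotates about it at the local effective frequency
#' in dimensionless coordinates — an exact 2x2 rotation through
#' \eqn{\Omega(x_c)\,dt} per substep with \eqn{\Omega} frozen at the substep
#' midpoint, which conserves \eqn{\tilde q^2 + \tilde p^2} to round-off.
#' Physical coordinates are recovered with \eqn{\Omega} and \eqn{\alpha}
#' evaluated at the instantaneous centroid position.
#'
#' @param field A \code{\link{centroid_field}} for the model and
#'   temperature.
#' @param centroid List with \code{xc}, \code{pc} (scalars, 1D).
#' @param planet List with initial physical \code{q}, \code{p}.
#' @param dt Time step.
#' @param nsteps Number of steps.
#' @param system A \code{\link{thermal_system}}.
#' @param barrier_policy What to do if the centroid path reaches
#'   \eqn{\Omega^2 \le 0}: \code{"clamp"} to the smallest positive grid
#'   frequency (default, logged on the result) or \code{"error"}.
#' @return A \code{"fklpi_traj"} with additional columns \code{xc},
#'   \code{pc}, the dimensionless invariant \code{planet_norm2}
#'   (\eqn{\tilde q^2+\tilde p^2}) and centroid \code{energy}.
#' @export
planetary_trajectory <- function(field, centroid, planet, dt, nsteps, system,
                                 barrier_policy = c("clamp", "error")) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n <- nsteps + 1L
  Q <- numeric(n); P <- numeric(n); XC <- numeric(n); PC <- numeric(n)
  mass <- system$masses[1]
  rec <- function(k, q, p, xc, pc) {
    Q[k + 1L] <<- q; P[k + 1L] <<- p; XC[k + 1L] <<- xc; PC[k + 1L] <<- pc
  }
  fin <- planetary_ensemble(field, centroid$xc, centroid$pc,
                            planet$q, planet$p, dt, nsteps, system, rec,
                            barrier_policy)
  energy <- PC^2 / (2 * mass) + field$W1(XC)
  structure(list(times = dt * (0:nsteps), q = matrix(Q), p = matrix(P),
                 xc = XC, pc = PC, energy = energy,
                 planet_norm2 = fin$qt^2 + fin$pt^2,
                 dt = dt, kind = "planetary"),
            class = "fklpi_traj")
}
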