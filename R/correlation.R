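#' Correlation-series container
#'
#' @param times Uniform, increasing time grid.
#' @param values Complex correlation values.
#' @param kind \code{"standard"} or \code{"kubo"}.
#' @param n_samples Number of Monte Carlo samples behind the estimate
#'   (\code{NA} for exact results).
#' @param stderr Optional per-time Monte Carlo standard errors (combined
#'   real/imaginary, from block averaging).
#' @return Object of class \code{"fklpi_cf"}.
#' @export
correlation_series <- function(times, values, kind = "standard",
                               n_samples = NA_integer_, stderr = NULL) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) > 1L) {
    dts <- diff(times)
    if (max(abs(dts - dts[1])) > 1e-9 * max(abs(dts))) {
      stop("time grid must be uniform", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), values = as.complex(values),
                 kind = kind, n_samples = n_samples, stderr = stderr),
            class = "fklpi_cf")
}

#' @export
print.fklpi_cf <- function(x, ...) {
  cat(sprintf("<fklpi_cf> %s, %d times in [%g, %g], C(0) = %.6g%+.3gi\n",
              x$kind, length(x$times), min(x$times), max(x$times),
              Re(x$values[1]), Im(x$values[1])))
  invisible(x)
}

# Bare Wigner symbol of the B-side operator at propagated phase points.
.b_symbol <- function(kind, q, p, mass) {
  switch(kind,
    position = q,
    momentum = p,
    velocity = p / mass,
    position2 = q^2,   # with A = "identity": tracks the ensemble <x^2>(t)
    identity = rep(1, length(q)),
    stop(sprintf("unsupported B operator '%s'", kind), call. = FALSE))
}

#' Classical-Wigner / planetary correlation functions (1D)
#'
#' Assembles \eqn{C_{AB}(t) = \langle A_{est}(q,p;x_c,p_c)\,
#' B_W(q_t,p_t)\rangle} over a sampled centroid ensemble with \code{n_planets}
#' fluctuation points per centroid.  The A side carries the full
#' Boltzmann-product estimator (\code{\link{operator_estimator}}); the B
#' side is the bare Wigner symbol of the operator evaluated along the
#' trajectory.  Error bars come from block averaging over consecutive
#' centroid-chain blocks.  The partition function never appears: averages
#' are ratios of Monte Carlo sums.
#'
#' Propagators: \code{"classical"} (standard FK-LPI; velocity Verlet on the
#' bare potential), \code{"planetary"} (ensemble-conserving; centroids on
#' \eqn{W_1}, planets rotating at \eqn{\Omega(x_c)}), or \code{"fk_cmd"}
#' (centroid-only dynamics on \eqn{W_1}; Kubo flavor only, no planets).
#'
#' @param model 1D model potential.
#' @param system A \code{\link{thermal_system}}.
#' @param ensemble A \code{\link{sample_centroid_ensemble}} result.
#' @param A,B Operator kinds: \code{"position"}, \code{"momentum"},
#'   \code{"velocity"}, \code{"identity"}.
#' @param flavor \code{"standard"} or \code{"kubo"} (applies to the A-side
#'   estimator and the meaning of the result).
#' @param propagator \code{"classical"}, \code{"planetary"} or
#'   \code{"fk_cmd"}.
#' @param n_planets Fluctuation points per centroid (ignored for
#'   \code{fk_cmd}).
#' @param dt,nsteps Trajectory grid; the series is reported on
#'   \code{t = (0:nsteps) * dt}.
#' @param seed Seed for the fluctuation draws.
#' @param field Optional \code{\link{centroid_field}}; required for the
#'   planetary and fk_cmd propagators (built automatically over the sampled
#'   centroid range plus six thermal widths when omitted).
#' @param n_blocks Block count for error bars (default 10).
#' @param barrier_policy Passed to the planetary propagator.
#' @return A \code{\link{correlation_series}} with Monte Carlo
#'   \code{stderr}.
#' @export
correlation_function <- function(model, system, ensemble,
                                 A = "position", B = A,
                                 flavor = c("standard", "kubo"),
                                 propagator = c("classical", "planetary",
                                                "fk_cmd"),
                                 n_planets = 10L, dt, nsteps, seed = 1L,
                                 field = NULL, n_blocks = 10L,
                                 barrier_policy = "clamp") {
  flavor <- match.arg(flavor)
  propagator <- match.arg(propagator)
  n_c <- length(ensemble$xc)
  if (n_c < 1L) stop("empty ensemble", call. = FALSE)
  mass <- system$masses[1]
  om2_c <- vapply(ensemble$eff, `[[`, numeric(1), "omega2")
  alpha_c <- vapply(ensemble$eff, `[[`, numeric(1), "alpha")
  has_barrier <- any(om2_c <= 0)
  if (has_barrier && flavor == "standard") {
    stop("barrier centroids present: the standard-flavor Moyal estimator ",
         "requires omega2 > 0 (use the kubo flavor or restrict sampling)",
         call. = FALSE)
  }
  if (propagator == "fk_cmd" && flavor != "kubo") {
    stop("fk_cmd is centroid-only dynamics: use the kubo flavor",
         call. = FALSE)
  }
  if (propagator %in% c("planetary", "fk_cmd") && is.null(field)) {
    a2_c <- vapply(ensemble$eff, `[[`, numeric(1), "a2")
    pad <- 6 * max(sqrt(mean(a2_c)), stats::sd(ensemble$xc),
                   1 / sqrt(system$beta * mass))
    field <- centroid_field(model, system,
                            range(ensemble$xc) + c(-pad, pad))
  }
  set.seed(seed)
  if (propagator == "fk_cmd") {
    q0 <- ensemble$xc; p0 <- ensemble$pc
    xc_r <- ensemble$xc; pc_r <- ensemble$pc
    om2_r <- om2_c; alpha_r <- alpha_c
    cidx <- seq_len(n_c)
  } else {
    q0 <- numeric(n_c * n_planets); p0 <- numeric(n_c * n_planets)
    for (i in seq_len(n_c)) {
      cs <- centroid_sample(ensemble, i)
      fl <- if (om2_c[i] > 0) {
        sample_qdo_fluctuations(cs, n_planets, system)
      } else {
        sample_barrier_marginal(cs, system, n_planets)
      }
      idx <- ((i - 1L) * n_planets + 1L):(i * n_planets)
      q0[idx] <- fl$q; p0[idx] <- fl$p
    }
    cidx <- rep(seq_len(n_c), each = n_planets)
    xc_r <- ensemble$xc[cidx]; pc_r <- ensemble$pc[cidx]
    om2_r <- om2_c[cidx]; alpha_r <- alpha_c[cidx]
  }
  est <- operator_estimator(A, flavor)
  A_val <- est(q0, p0, xc_r, pc_r, om2_r, alpha_r, mass)
  n_tot <- length(q0)
  n_blocks <- min(n_blocks, n_c)
  block_of_c <- ceiling(seq_len(n_c) / (n_c / n_blocks))
  block_idx <- split(seq_len(n_tot), block_of_c[cidx])
  n_blocks <- length(block_idx)
  block_n <- lengths(block_idx)
  bm <- matrix(0i, nsteps + 1L, n_blocks)
  record <- function(k, q, p, ...) {
    v <- A_val * .b_symbol(B, q, p, mass)
    for (b in seq_len(n_blocks)) {
      bm[k + 1L, b] <<- sum(v[block_idx[[b]]]) / block_n[b]
    }
  }
  if (propagator == "classical") {
    gfun <- function(x) gradient_1d(model, x)
    verlet_ensemble_1d(gfun, q0, p0, mass, dt, nsteps, record)
  } else if (propagator == "planetary") {
    planetary_ensemble(field, xc_r, pc_r, q0, p0, dt, nsteps, system,
                       function(k, q, p, xc, pc) record(k, q, p),
                       barrier_policy)
  } else {
    gfun <- function(x) -field$force(x)
    verlet_ensemble_1d(gfun, q0, p0, mass, dt, nsteps, record)
  }
  w <- block_n / n_tot
  vals <- as.complex(bm %*% w)
  ctr <- sweep(bm, 1L, vals)
  se <- sqrt((rowSums(Re(ctr)^2) + rowSums(Im(ctr)^2)) /
               (n_blocks * (n_blocks - 1L)))
  out <- correlation_series(dt * (0:nsteps), vals, kind = flavor,
                            n_samples = n_tot, stderr = se)
  out$blocks <- bm          # per-block means: drift/uncertainty analyses
  out$block_weights <- w
  out
}

#' @rdname correlation_function
#' @param ... Passed on to \code{correlation_function}.
#' @export
classical_wigner_correlation <- function(model, system, ensemble, ...) {
  correlation_function(model, system, ensemble, propagator = "classical", ...)
}

#' @rdname correlation_function
#' @export
planetary_correlation <- function(model, system, ensemble, ...) {
  correlation_function(model, system, ensemble, propagator = "planetary", ...)
}

#' @rdname correlation_function
#' @export
kubo_correlation <- function(model, system, ensemble, ...) {
  correlation_function(model, system, ensemble, flavor = "kubo", ...)
}

#' Drift of an ensemble average relative to its initial value
#'
#' For a stationarity diagnostic (e.g. \eqn{\langle x^2\rangle(t)} computed
#' with \code{A = "identity"}, \code{B = "position2"}): the drift
#' \eqn{d(t) = C(t) - C(0)} is formed per Monte Carlo block, so its
#' standard error reflects the uncertainty of the \emph{difference} (the
#' common sampling noise at \eqn{t = 0} cancels within each block).  An
#' ensemble-conserving propagator keeps \eqn{|d(t)|} within a few standard
#' errors at all times; ordinary classical propagation of a quantum initial
#' ensemble does not.
#'
#' @param cf A \code{\link{correlation_function}} result (must carry block
#'   means).
#' @return Data frame with \code{t}, \code{drift} (real part) and
#'   \code{stderr}.
#' @export
ensemble_drift <- function(cf) {
  if (is.null(cf$blocks)) stop("cf carries no block means", call. = FALSE)
  db <- sweep(Re(cf$blocks), 2L, Re(cf$blocks[1L, ]))
  nb <- ncol(db)
  d <- as.numeric(db %*% cf$block_weights)
  ctr <- sweep(db, 1L, d)
  se <- sqrt(rowSums(ctr^2) / (nb * (nb - 1L)))
  data.frame(t = cf$times, drift = d, stderr = se)
}

#' Spectrum of a correlation function
#'
#' Discrete Fourier transform \eqn{I(\omega) = \Delta t \sum_t C(t)
#' e^{-i\omega t}} of the two-sided extension \eqn{C(-t) = C^*(t)}, with an
#' optional Hann window and zero padding.  With this sign convention the
#' positive-frequency side of a standard CF carries the absorption weight,
#' so \code{spectrum(standard) / spectrum(kubo)} recovers the harmonic
#' quantum correction factor at resolved peaks.
#'
#' @param cf A \code{\link{correlation_series}} on a uniform grid.
#' @param window \code{"hann"} (default) or \code{"none"}.
#' @param zero_pad Padding factor (integer >= 1, default 4).
#' @return Object of class \code{"fklpi_spectrum"}: \code{omega} (symmetric
#'   about 0), complex \code{intensity}, \code{window}.
#' @export
spectrum_from_cf <- function(cf, window = c("hann", "none"), zero_pad = 4L) {
  window <- match.arg(window)
  n <- length(cf$times)
  dt <- if (n > 1L) cf$times[2] - cf$times[1] else
    stop("need at least two times", call. = FALSE)
  v <- cf$values
  Tmax <- cf$times[n]
  full_t <- c(cf$times, -rev(cf$times[-1]))      # wrap-around order
  full_v <- c(v, Conj(rev(v[-1])))
  if (window == "hann") {
    full_v <- full_v * 0.5 * (1 + cos(pi * full_t / Tmax))
  }
  N0 <- length(full_v)
  N <- as.integer(zero_pad) * N0
  arr <- complex(N)
  arr[seq_len(n)] <- full_v[seq_len(n)]                 # t >= 0
  arr[(N - n + 2L):N] <- full_v[(n + 1L):N0]            # t < 0
  z <- stats::fft(arr) * dt
  k <- seq_len(N) - 1L
  k[k >= N / 2] <- k[k >= N / 2] - N
  omega <- 2 * pi * k / (N * dt)
  ord <- order(omega)
  structure(list(omega = omega[ord], intensity = z[ord], window = window,
                 dt = dt), class = "fklpi_spectrum")
}

#' @export
print.fklpi_spectrum <- function(x, ...) {
  cat(sprintf("<fklpi_spectrum> %d frequencies in [%g, %g], window %s\n",
              length(x$omega), min(x$omega), max(x$omega), x$window))
  invisible(x)
}

#' Harmonic quantum correction factor
#'
#' \eqn{Q_H(\omega) = \beta\hbar\omega / (1 - e^{-\beta\hbar\omega})},
#' continuous at \eqn{\omega = 0} where it equals 1.  Multiplying a
#' classical (or Kubo) spectrum by \eqn{Q_H} estimates the corresponding
#' quantum spectrum under a harmonic-bath assumption.
#'
#' @param omega Frequency grid.
#' @param system A \code{\link{thermal_system}}.
#' @return A \code{"fklpi_spectrum"} with real intensity \eqn{Q_H(\omega)}.
#' @export
harmonic_qcf <- function(omega, system) {
  x <- system$beta * system$hbar * omega
  qh <- ifelse(abs(x) < 1e-8, 1 + x / 2 + x^2 / 12, x / (1 - exp(-x)))
  structure(list(omega = omega, intensity = qh, window = "none"),
            class = "fklpi_spectrum")
}

#' Pointwise spectral ratio with a noise floor
#'
#' Ratio of two spectra on a common grid, e.g. an FK-LPI spectrum over its
#' classical counterpart to form an empirical quantum correction factor.
#' Denominator magnitudes below \code{floor * max(|denominator|)} are
#' floored to avoid noise blow-up; the affected indices are recorded in the
#' \code{flagged} element.
#'
#' @param quantum_spec,classical_spec \code{"fklpi_spectrum"} objects on the
#'   same frequency grid.
#' @param floor Relative denominator floor (default 1e-3).
#' @return A \code{"fklpi_spectrum"} whose intensity is the ratio, with
#'   elements \code{flagged} (integer indices).
#' @export
qcf_ratio <- function(quantum_spec, classical_spec, floor = 1e-3) {
  if (length(quantum_spec$omega) != length(classical_spec$omega) ||
      max(abs(quantum_spec$omega - classical_spec$omega)) >
        1e-9 * max(1, max(abs(quantum_spec$omega)))) {
    stop("spectra are not on a common frequency grid", call. = FALSE)
  }
  den <- classical_spec$intensity
  lim <- floor * max(Mod(den))
  flagged <- which(Mod(den) < lim)
  den[flagged] <- lim * ifelse(Mod(den[flagged]) > 0,
                               den[flagged] / Mod(den[flagged]), 1)
  out <- structure(list(omega = quantum_spec$omega,
                        intensity = quantum_spec$intensity / den,
                        window = quantum_spec$window,
                        flagged = flagged),
                   class = "fklpi_spectrum")
  out
}

#' Intermediate scattering function of a periodic liquid
#'
#' \eqn{F(Q,t) = \langle \sum_{j,j'} e^{-iQ r_j(0)} e^{iQ r_{j'}(t)}\rangle}
#' over an ensemble of trajectories, with the self (\eqn{j = j'}) and
#' distinct parts available separately.  \eqn{Q} must be commensurate with
#' the box (\eqn{2\pi n/L}).
#'
#' @param positions Array \code{[n_samples, n_particles, n_times]} of
#'   particle positions.
#' @param Q Scalar wavevector.
#' @param box Box length \eqn{L}.
#' @param dt Time step of the stored frames.
#' @param component \code{"total"}, \code{"self"} or \code{"distinct"}.
#' @return A \code{\link{correlation_series}} (standard kind).
#' @export
intermediate_scattering <- function(positions, Q, box, dt,
                                    component = c("total", "self",
                                                  "distinct")) {
  component <- match.arg(component)
  stopifnot_scalar(box, "box", positive = TRUE)
  nQ <- Q * box / (2 * pi)
  if (abs(nQ - round(nQ)) > 1e-8) {
    stop(sprintf(
      "Q = %g is not commensurate with the box: allowed Q = 2*pi*n/%g",
      Q, box), call. = FALSE)
  }
  dims <- dim(positions)
  if (length(dims) != 3L) {
    stop("positions must be an [n_samples, n_particles, n_times] array",
         call. = FALSE)
  }
  n_s <- dims[1]; n_t <- dims[3]
  ph <- exp(1i * Q * positions)               # same shape
  rho <- apply(ph, c(1L, 3L), sum)            # [n_samples, n_times]
  vals <- switch(component,
    total = colMeans(Conj(rho[, 1L]) * rho),
    self = {
      selfsum <- apply(Conj(ph[, , 1L, drop = FALSE])[, , 1L] *
                         array(ph, dims), c(1L, 3L), sum)
      colMeans(selfsum)
    },
    distinct = {
      tot <- colMeans(Conj(rho[, 1L]) * rho)
      selfsum <- apply(Conj(ph[, , 1L, drop = FALSE])[, , 1L] *
                         array(ph, dims), c(1L, 3L), sum)
      tot - colMeans(selfsum)
    })
  correlation_series(dt * (seq_len(n_t) - 1L), vals, kind = "standard",
                     n_samples = n_s)
}

#' Diffusion coefficient from a velocity autocorrelation function
#'
#' Green-Kubo integral \eqn{D = \frac{1}{d}\int_0^T \mathrm{Re}\,
#' C_{vv}(t)\,dt} by the trapezoidal rule, with a plateau check over the
#' tail of the running integral and a decay check on the VACF tail
#' (warnings when either fails).
#'
#' @param vacf A \code{\link{correlation_series}} of velocities.
#' @param dimension Spatial dimensionality (divides the trace).
#' @return List with \code{D}, \code{stderr} (propagated from the VACF
#'   error bars where available, treating times as independent — a lower
#'   bound for correlated noise), and \code{plateau} diagnostics.
#' @export
diffusion_from_vacf <- function(vacf, dimension = 1L) {
  t <- vacf$times; v <- Re(vacf$values)
  n <- length(t)
  dt <- t[2] - t[1]
  w <- rep(dt, n); w[c(1L, n)] <- dt / 2
  running <- cumsum(w * v) / dimension
  D <- running[n]
  tail_idx <- seq(max(2L, floor(0.8 * n)), n)
  plateau <- list(mean = mean(running[tail_idx]),
                  sd = stats::sd(running[tail_idx]))
  se <- if (!is.null(vacf$stderr)) {
    sqrt(sum((w * vacf$stderr)^2)) / dimension
  } else {
    NA_real_
  }
  tail_mag <- mean(abs(v[tail_idx]))
  decayed <- if (!is.null(vacf$stderr)) {
    tail_mag <= 3 * mean(vacf$stderr[tail_idx]) + 1e-12
  } else {
    tail_mag <= 0.05 * max(abs(v))
  }
  if (!decayed) {
    warning("VACF has not decayed to noise within the window; ",
            "D estimate may be biased", call. = FALSE)
  }
  if (plateau$sd > 0.1 * max(abs(D), .Machine$double.eps)) {
    warning("running Green-Kubo integral has not plateaued", call. = FALSE)
  }
  list(D = D, stderr = se, plateau = plateau)
}

#' Radial distribution function of a 1D periodic liquid
#'
#' Standard pair-histogram estimator with minimum-image distances: with
#' number density \eqn{\rho = N/L} the normalization satisfies the counting
#' sum rule \eqn{\int \rho\, g(r)\, dV \approx N - 1} (1D shell volume
#' \eqn{dV = 2\,dr}).
#'
#' @param configs Matrix \code{[n_configs, n_particles]} of positions.
#' @param bins Number of histogram bins over \eqn{(0, L/2]}.
#' @param box Box length.
#' @return Data frame with bin centers \code{r} and \code{g}.
#' @export
radial_distribution <- function(configs, bins = 50L, box) {
  if (is.null(dim(configs))) configs <- matrix(configs, nrow = 1L)
  n_cfg <- nrow(configs); N <- ncol(configs)
  if (n_cfg < 1L) stop("zero configurations", call. = FALSE)
  if (N < 2L) stop("need at least two particles", call. = FALSE)
  r_max <- box / 2
  edges <- seq(0, r_max, length.out = bins + 1L)
  counts <- numeric(bins)
  ij <- utils::combn(N, 2L)
  for (c0 in seq_len(n_cfg)) {
    d <- abs(min_image(configs[c0, ij[1L, ]] - configs[c0, ij[2L, ]], box))
    h <- findInterval(d, edges, rightmost.closed = TRUE)
    h <- h[h >= 1L & h <= bins]
    if (length(h)) {
      tb <- tabulate(h, nbins = bins)
      counts <- counts + 2 * tb     # ordered pairs
    }
  }
  dr <- diff(edges)
  rho <- N / box
  g <- counts / (n_cfg * N * rho * 2 * dr)
  data.frame(r = (edges[-1L] + edges[-(bins + 1L)]) / 2, g = g)
}
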