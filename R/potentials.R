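#' Model potential-energy surfaces
#'
#' Constructs an energy/gradient/Hessian provider for the built-in one
#' dimensional model potentials, for a periodic one-dimensional pair liquid,
#' or for a user-supplied force routine.  All coordinates are plain numeric
#' vectors; a 1D system is a dimension-1 vector (no scalar special case).
#'
#' Built-in models and their parameters:
#' \describe{
#'   \item{\code{harmonic}}{\eqn{V = \sum_i \frac{1}{2} M_i \omega_i^2 x_i^2};
#'     params \code{M}, \code{omega} (vectors give uncoupled N-D modes).}
#'   \item{\code{double_well}}{\eqn{V = -a x^2/2 + b x^4/4}; params \code{a},
#'     \code{b} (both positive; minima at \eqn{\pm\sqrt{a/b}}).}
#'   \item{\code{quartic}}{\eqn{V = c\, x^4/4}; param \code{c}.}
#'   \item{\code{morse}}{\eqn{V = D_e (1 - e^{-a(x-x_0)})^2}; params
#'     \code{De}, \code{a}, \code{x0}.}
#'   \item{\code{parabolic_barrier}}{\eqn{V = -\frac{1}{2} M \omega_b^2 x^2};
#'     params \code{M}, \code{omega_b}.}
#'   \item{\code{pair_liquid}}{\code{n_particles} atoms on a periodic line of
#'     length \code{box_length} interacting through a pair potential
#'     (\code{pair = list(type = "lennard_jones", epsilon, sigma)}), with the
#'     minimum-image convention, truncation at half the box length and the
#'     energy shifted to zero at the cutoff.}
#'   \item{\code{external}}{user force routine: params \code{dimension},
#'     \code{value_fn(x)}, \code{gradient_fn(x)}, optional \code{hessian_fn}.}
#' }
#'
#' @param name One of \code{"harmonic"}, \code{"double_well"},
#'   \code{"quartic"}, \code{"morse"}, \code{"parabolic_barrier"},
#'   \code{"pair_liquid"}, \code{"external"}.
#' @param params Named list of model parameters (see Details).
#'
#' @return An object of class \code{"fklpi_potential"} with elements
#'   \code{name}, \code{dimension}, \code{params}, \code{box_length} (or
#'   \code{NULL}), \code{provides_hessian}, and closures \code{value},
#'   \code{gradient}, \code{hessian}.  For 1D analytic models the closures
#'   are vectorized over a vector of scalar positions.
#' @examples
#' m <- make_model_potential("double_well", list(a = 1, b = 1))
#' m$value(sqrt(1))   # potential at the right-hand minimum
#' @export
make_model_potential <- function(name, params = list()) {
  name <- match.arg(name, c("harmonic", "double_well", "quartic", "morse",
                            "parabolic_barrier", "pair_liquid", "external"))
  switch(name,
    harmonic = .pot_harmonic(params),
    double_well = .pot_double_well(params),
    quartic = .pot_quartic(params),
    morse = .pot_morse(params),
    parabolic_barrier = .pot_parabolic_barrier(params),
    pair_liquid = .pot_pair_liquid(params),
    external = .pot_external(params)
  )
}

.new_potential <- function(name, dimension, params, value, gradient,
                           hessian = NULL, box_length = NULL,
                           vectorized = (dimension == 1L)) {
  structure(list(
    name = name, dimension = as.integer(dimension), params = params,
    box_length = box_length, provides_hessian = !is.null(hessian),
    vectorized = vectorized,
    value = value, gradient = gradient, hessian = hessian
  ), class = "fklpi_potential")
}

#' @export
print.fklpi_potential <- function(x, ...) {
  cat(sprintf("<fklpi_potential> %s, dimension %d%s\n", x$name, x$dimension,
              if (!is.null(x$box_length)) sprintf(", box %g", x$box_length)
              else ""))
  invisible(x)
}

.req_params <- function(params, names, model) {
  for (nm in names) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || any(!is.finite(v))) {
      stop(sprintf("model '%s' requires finite numeric parameter '%s'",
                   model, nm), call. = FALSE)
    }
  }
}

.pot_harmonic <- function(params) {
  params$M <- params$M %||% 1
  params$omega <- params$omega %||% 1
  .req_params(params, c("M", "omega"), "harmonic")
  d <- max(length(params$M), length(params$omega))
  M <- rep_len(params$M, d); w <- rep_len(params$omega, d)
  k <- M * w^2
  if (d == 1L) {
    .new_potential("harmonic", 1L, params,
      value = function(x) 0.5 * k * x^2,
      gradient = function(x) k * x,
      hessian = function(x) rep_len(k, length(x)))
  } else {
    .new_potential("harmonic", d, params,
      value = function(x) sum(0.5 * k * x^2),
      gradient = function(x) k * x,
      hessian = function(x) diag(k, d, d))
  }
}

.pot_double_well <- function(params) {
  .req_params(params, c("a", "b"), "double_well")
  a <- params$a; b <- params$b
  if (a <= 0 || b <= 0) stop("double_well requires a > 0, b > 0", call. = FALSE)
  .new_potential("double_well", 1L, params,
    value = function(x) -0.5 * a * x^2 + 0.25 * b * x^4,
    gradient = function(x) -a * x + b * x^3,
    hessian = function(x) -a + 3 * b * x^2)
}

.pot_quartic <- function(params) {
  params$c <- params$c %||% 1
  .req_params(params, "c", "quartic")
  cc <- params$c
  .new_potential("quartic", 1L, params,
    value = function(x) 0.25 * cc * x^4,
    gradient = function(x) cc * x^3,
    hessian = function(x) 3 * cc * x^2)
}

.pot_morse <- function(params) {
  params$x0 <- params$x0 %||% 0
  .req_params(params, c("De", "a", "x0"), "morse")
  De <- params$De; a <- params$a; x0 <- params$x0
  .new_potential("morse", 1L, params,
    value = function(x) { e <- exp(-a * (x - x0)); De * (1 - e)^2 },
    gradient = function(x) { e <- exp(-a * (x - x0)); 2 * De * a * e * (1 - e) },
    hessian = function(x) { e <- exp(-a * (x - x0)); 2 * De * a^2 * e * (2 * e - 1) })
}

.pot_parabolic_barrier <- function(params) {
  params$M <- params$M %||% 1
  .req_params(params, c("M", "omega_b"), "parabolic_barrier")
  k <- params$M * params$omega_b^2
  .new_potential("parabolic_barrier", 1L, params,
    value = function(x) -0.5 * k * x^2,
    gradient = function(x) -k * x,
    hessian = function(x) rep_len(-k, length(x)))
}

# Minimum-image signed separation on a periodic line of length L.
min_image <- function(dx, L) dx - L * round(dx / L)

.pair_fns <- function(pair) {
  type <- pair$type %||% "lennard_jones"
  if (type == "lennard_jones") {
    eps <- pair$epsilon %||% 1; sig <- pair$sigma %||% 1
    list(
      phi = function(r) { s6 <- (sig / r)^6; 4 * eps * (s6^2 - s6) },
      dphi = function(r) { s6 <- (sig / r)^6; -24 * eps * (2 * s6^2 - s6) / r },
      d2phi = function(r) { s6 <- (sig / r)^6; 24 * eps * (26 * s6^2 - 7 * s6) / r^2 },
      r_min = 2^(1 / 6) * sig
    )
  } else if (type == "morse") {
    De <- pair$De %||% 1; a <- pair$a %||% 1; r0 <- pair$r0 %||% 1
    list(
      phi = function(r) { e <- exp(-a * (r - r0)); De * ((1 - e)^2 - 1) },
      dphi = function(r) { e <- exp(-a * (r - r0)); 2 * De * a * e * (1 - e) },
      d2phi = function(r) { e <- exp(-a * (r - r0)); 2 * De * a^2 * e * (2 * e - 1) },
      r_min = r0
    )
  } else {
    stop(sprintf("unknown pair potential type '%s'", type), call. = FALSE)
  }
}

.pot_pair_liquid <- function(params) {
  .req_params(params, c("n_particles", "box_length"), "pair_liquid")
  N <- as.integer(params$n_particles); L <- params$box_length
  if (N < 2L) stop("pair_liquid requires at least 2 particles", call. = FALSE)
  if (L <= 0) stop("pair_liquid requires positive box_length", call. = FALSE)
  pf <- .pair_fns(params$pair %||% list())
  rc <- L / 2
  phi_rc <- pf$phi(rc)
  pair_terms <- function(x, fn) {
    # signed minimum-image separations for all ordered pairs j < k
    ij <- utils::combn(N, 2L)
    dx <- min_image(x[ij[1L, ]] - x[ij[2L, ]], L)
    r <- abs(dx)
    inside <- r < rc
    list(ij = ij, dx = dx, r = r, inside = inside)
  }
  value <- function(x) {
    pt <- pair_terms(x)
    r <- pt$r[pt$inside]
    if (any(r < 1e-12)) {
      stop("singular configuration: overlapping particles", call. = FALSE)
    }
    e <- sum(pf$phi(r) - phi_rc)
    if (!is.finite(e)) {
      stop("singular configuration: non-finite pair energy", call. = FALSE)
    }
    e
  }
  gradient <- function(x) {
    pt <- pair_terms(x)
    g <- numeric(N)
    sel <- which(pt$inside)
    if (length(sel)) {
      r <- pt$r[sel]
      if (any(r < 1e-12)) {
        stop("singular configuration: overlapping particles", call. = FALSE)
      }
      f <- pf$dphi(r) * sign(pt$dx[sel])  # dV/dx_j for pair (j,k)
      j <- pt$ij[1L, sel]; k <- pt$ij[2L, sel]
      for (i in seq_along(sel)) {
        g[j[i]] <- g[j[i]] + f[i]
        g[k[i]] <- g[k[i]] - f[i]
      }
    }
    g
  }
  hessian <- function(x) {
    pt <- pair_terms(x)
    H <- matrix(0, N, N)
    sel <- which(pt$inside)
    if (length(sel)) {
      h <- pf$d2phi(pt$r[sel])
      j <- pt$ij[1L, sel]; k <- pt$ij[2L, sel]
      for (i in seq_along(sel)) {
        H[j[i], j[i]] <- H[j[i], j[i]] + h[i]
        H[k[i], k[i]] <- H[k[i], k[i]] + h[i]
        H[j[i], k[i]] <- H[j[i], k[i]] - h[i]
        H[k[i], j[i]] <- H[k[i], j[i]] - h[i]
      }
    }
    H
  }
  out <- .new_potential("pair_liquid", N, params, value, gradient, hessian,
                        box_length = L, vectorized = FALSE)
  out$pair <- pf
  out
}

.pot_external <- function(params) {
  d <- params$dimension
  if (is.null(d) || d < 1) {
    stop("external model requires 'dimension'", call. = FALSE)
  }
  if (!is.function(params$value_fn) || !is.function(params$gradient_fn)) {
    stop("external model requires 'value_fn' and 'gradient_fn'", call. = FALSE)
  }
  .new_potential("external", as.integer(d), params,
                 value = params$value_fn, gradient = params$gradient_fn,
                 hessian = params$hessian_fn,
                 vectorized = isTRUE(params$vectorized))
}

#' Evaluate potential energy and gradient at a configuration
#'
#' @param model A \code{\link{make_model_potential}} object.
#' @param coords Numeric coordinate vector, length equal to the model
#'   dimension.
#' @return List with \code{energy} (finite scalar) and \code{gradient}
#'   (vector of the model dimension).
#' @examples
#' m <- make_model_potential("harmonic", list(M = 1, omega = 1))
#' potential_value_gradient(m, 1)
#' @export
potential_value_gradient <- function(model, coords) {
  coords <- as.numeric(coords)
  if (length(coords) != model$dimension) {
    stop(sprintf("coordinate length %d does not match model dimension %d",
                 length(coords), model$dimension), call. = FALSE)
  }
  if (model$dimension == 1L && model$vectorized) {
    e <- model$value(coords); g <- model$gradient(coords)
  } else {
    e <- model$value(coords); g <- model$gradient(coords)
  }
  if (!is.finite(e)) {
    stop("singular configuration: non-finite energy", call. = FALSE)
  }
  list(energy = as.numeric(e), gradient = as.numeric(g))
}

#' Hessian of a model potential
#'
#' Returns the (symmetric) second-derivative matrix, using the analytic
#' Hessian when the model provides one and otherwise central finite
#' differences of the gradient with step \code{1e-5 * max(1, |x_i|)}.
#'
#' @inheritParams potential_value_gradient
#' @param finite_diff Allow the finite-difference fallback when no analytic
#'   Hessian is available (default \code{TRUE}).
#' @return A symmetric \code{dimension x dimension} matrix.
#' @export
potential_hessian <- function(model, coords, finite_diff = TRUE) {
  coords <- as.numeric(coords)
  if (length(coords) != model$dimension) {
    stop("coordinate length does not match model dimension", call. = FALSE)
  }
  d <- model$dimension
  if (model$provides_hessian) {
    H <- model$hessian(coords)
    H <- matrix(as.numeric(H), d, d)
  } else {
    if (!finite_diff) {
      stop("model has no analytic Hessian and finite differencing is disabled",
           call. = FALSE)
    }
    H <- matrix(0, d, d)
    for (i in seq_len(d)) {
      h <- 1e-5 * max(1, abs(coords[i]))
      xp <- coords; xp[i] <- xp[i] + h
      xm <- coords; xm[i] <- xm[i] - h
      H[, i] <- (as.numeric(model$gradient(xp)) -
                 as.numeric(model$gradient(xm))) / (2 * h)
    }
  }
  (H + t(H)) / 2
}

# Fast scalar second derivative for 1D models, vectorized over positions.
hessian_1d <- function(model, x) {
  if (model$provides_hessian && model$vectorized) {
    as.numeric(model$hessian(x))
  } else if (model$provides_hessian) {
    vapply(x, function(xi) as.numeric(model$hessian(xi))[1L], numeric(1))
  } else {
    h <- 1e-5 * pmax(1, abs(x))
    (vapply(x + h, function(xi) as.numeric(model$gradient(xi)), numeric(1)) -
     vapply(x - h, function(xi) as.numeric(model$gradient(xi)), numeric(1))) /
      (2 * h)
  }
}

# Vectorized 1D value/gradient wrappers (fall back to vapply for closures
# that are not natively vectorized, e.g. external routines).
value_1d <- function(model, x) {
  if (model$vectorized) as.numeric(model$value(x))
  else vapply(x, function(xi) as.numeric(model$value(xi)), numeric(1))
}

gradient_1d <- function(model, x) {
  if (model$vectorized) as.numeric(model$gradient(x))
  else vapply(x, function(xi) as.numeric(model$gradient(xi)), numeric(1))
}
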