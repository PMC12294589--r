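# Internal numerical helpers shared across the package.

# u*coth(u), analytically continued to negative u2 = u^2 (u = i*v gives v*cot(v)).
# Accepts the *squared* argument so callers never take sqrt of a negative number.
# Series near u2 = 0 avoids cancellation: u coth u = 1 + u2/3 - u2^2/45 + ...
ucoth_sq <- function(u2) {
  out <- numeric(length(u2))
  small <- abs(u2) < 1e-6
  out[small] <- 1 + u2[small] / 3 - u2[small]^2 / 45
  pos <- !small & u2 > 0
  if (any(pos)) {
    u <- sqrt(u2[pos])
    out[pos] <- u / tanh(u)
  }
  neg <- !small & u2 < 0
  if (any(neg)) {
    v <- sqrt(-u2[neg])
    if (any(v >= pi)) {
      stop("analytic continuation out of range: hbar*|Omega|*beta >= 2*pi",
           call. = FALSE)
    }
    out[neg] <- v / tan(v)
  }
  out
}

# log(sinh(u)/u) continued to u2 < 0 as log(sin(v)/v); stable for large u.
lsinhc_sq <- function(u2) {
  out <- numeric(length(u2))
  small <- abs(u2) < 1e-8
  out[small] <- u2[small] / 6 - u2[small]^2 / 180
  pos <- !small & u2 > 0
  if (any(pos)) {
    u <- sqrt(u2[pos])
    out[pos] <- u + log1p(-exp(-2 * u)) - log(2 * u)
  }
  neg <- !small & u2 < 0
  if (any(neg)) {
    v <- sqrt(-u2[neg])
    if (any(v >= pi)) {
      stop("analytic continuation out of range: hbar*|Omega|*beta >= 2*pi",
           call. = FALSE)
    }
    out[neg] <- log(sin(v) / v)
  }
  out
}

# Cached Gauss-Hermite rules (physicists' convention: integral e^{-t^2} f(t) dt).
.gh_cache <- new.env(parent = emptyenv())

gauss_hermite_rule <- function(order) {
  key <- as.character(order)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(order)
  }
  .gh_cache[[key]]
}

# E[f(y)] for y ~ Normal(mu, sd^2) by Gauss-Hermite quadrature; f vectorized.
gauss_expectation <- function(f, mu, sd, order = 40L) {
  gh <- gauss_hermite_rule(order)
  y <- mu + sqrt(2) * sd * gh$x
  vals <- f(y)
  if (any(!is.finite(vals))) {
    stop("non-finite integrand in Gaussian smearing quadrature", call. = FALSE)
  }
  sum(gh$w * vals) / sqrt(pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
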