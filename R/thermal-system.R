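#' Thermal ensemble context
#'
#' Bundles the inverse temperature, per-degree-of-freedom masses and the
#' value of the reduced Planck constant that every other computation in the
#' package refers to.  All quantities are in one consistent unit system
#' (by default natural units with \code{hbar = 1}); units are never mixed.
#'
#' @param beta Inverse temperature \eqn{1/k_B T} (inverse energy), positive.
#' @param masses Positive mass, one per degree of freedom (recycled to the
#'   model dimension where needed).
#' @param hbar Reduced Planck constant in the chosen units (default 1).
#'
#' @return An object of class \code{"fklpi_system"}: a list with elements
#'   \code{beta}, \code{masses}, \code{hbar}.
#' @examples
#' sys <- thermal_system(beta = 8, masses = 1)
#' @export
thermal_system <- function(beta, masses = 1, hbar = 1) {
  stopifnot_scalar(beta, "beta", positive = TRUE)
  stopifnot_scalar(hbar, "hbar", positive = TRUE)
  if (!is.numeric(masses) || any(!is.finite(masses)) || any(masses <= 0)) {
    stop("'masses' must be positive and finite", call. = FALSE)
  }
  structure(list(beta = beta, masses = as.numeric(masses), hbar = hbar),
            class = "fklpi_system")
}

#' @export
print.fklpi_system <- function(x, ...) {
  cat(sprintf("<fklpi_system> beta = %g, hbar = %g, masses = %s\n",
              x$beta, x$hbar, paste(signif(x$masses, 4), collapse = ", ")))
  invisible(x)
}

# Mass vector of the right length for a model dimension.
system_masses <- function(system, dimension) {
  m <- rep_len(system$masses, dimension)
  m
}
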