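---
title: "Quantum correlation functions by Feynman-Kleinert linearized path integrals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum correlation functions by Feynman-Kleinert linearized path integrals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fklpi)
```

## The problem

Classical molecular dynamics misses nuclear quantum effects — zero-point
motion, tunneling, detailed balance in spectra — that matter for light
nuclei and low temperatures, i.e. whenever $\hbar\omega/k_BT \gg 1$.
Quantum time-correlation functions
$C_{AB}(t) = Z^{-1}\,\mathrm{Tr}[e^{-\beta\hat H}\hat A\,\hat B(t)]$
carry transport coefficients, spectra and structure factors, but cannot be
evaluated exactly for many-body systems because of the sign problem of the
real-time propagator.

The classical Wigner (linearized path integral) approximation replaces the
quantum time evolution by classical trajectories whose *initial conditions*
are sampled from the Wigner transform of the Boltzmann operator.  It is
exact for harmonic potentials, at high temperature, and at $t = 0$; the
error it makes is a dynamical one (artificial dephasing in strongly
anharmonic systems).  This package implements the Feynman–Kleinert (FK)
route to that initial distribution and both ways of propagating it:
ordinary classical trajectories (standard FK-LPI) and the
ensemble-conserving *planetary* scheme.

## The FK Boltzmann–Wigner distribution

Sampling is split into a classical-like part and a quantum part.

**Centroids.**  Phase points $(x_c, p_c)$ are drawn from the FK centroid
density $\propto \exp(-\beta p_c^2/2M)\exp(-\beta W_1(x_c))$, where
$W_1$ is the FK variational approximation to the centroid potential.  One
printed rendering of the kinetic exponent omits the factor 2; we use the
Maxwell form $p_c^2/2M$, which is the choice that reproduces the barrier
validity bound $\hbar|\Omega|\beta < \pi$ quoted below — integrating
$p_c$ out with any other prefactor moves that bound.

**Effective frequency.**  At each centroid the local potential is replaced
by a variationally optimized harmonic one.  Its squared frequency solves
the fixed point of two equations: the smearing width
$$a^2(\Omega) = \frac{1}{M\Omega^2\beta}\Big\{\tfrac{\hbar\Omega\beta}{2}
\coth\tfrac{\hbar\Omega\beta}{2} - 1\Big\},$$
and the Gaussian-smeared Hessian
$\Omega^2(a^2) = \tfrac{1}{M}\,E[V''(x_c + y)]$, $y \sim N(0, a^2)$.
The width interpolates between $\hbar^2\beta/12M$ at high temperature and
the ground-state width $\hbar/2M\Omega$ at low temperature, and both it
and $W_1$ continue smoothly through $\Omega^2 = 0$ to barrier regions
(the $\coth$ becomes a $\cot$; validity requires
$\hbar|\Omega|\beta < 2\pi$ for the width and $< \pi$ for momentum
sampling).  `solve_effective_frequency()` iterates the pair from the bare
Hessian (or from the high-temperature width when the bare curvature is
non-positive), with a 0.5 damping factor applied only if the iteration
oscillates without contracting; typical anharmonic fixtures converge in
4–10 iterations at the default relative tolerance of $10^{-8}$ on
$\Omega^2$.

The smearing integral is evaluated by Gauss–Hermite quadrature (order 40,
automatically doubled when an order-80 self-check moves the result by more
than $10^{-8}$), or by the integration-by-parts "gradient sampling" form
$\Omega^2 = E[V'(x_c+y)\,y]/(M a^2)$, which needs only force calls and is
the black-box path for external potentials (2500 samples is the
liquid-scale default).  The two routes agree within Monte Carlo error;
the test suite checks this at $n = 10^5$ against the quadrature oracle.

**Fluctuations.**  Around each centroid, the quasi-density operator has an
*analytic* Gaussian Wigner transform with position variance
$\hbar\alpha/2M\Omega$ and momentum variance $M\Omega\alpha\hbar/2$, where
$\alpha = \coth(\hbar\Omega\beta/2) - 2/\hbar\Omega\beta \in (0,1)$.
For the harmonic oscillator, centroid variance plus fluctuation variance
add up exactly to the quantum $\langle x^2\rangle =
(\hbar/2M\omega)\coth(\beta\hbar\omega/2)$ — one of the package's
acceptance identities.

**Barriers.**  Where $\Omega^2 < 0$ the direct momentum sampling is
ill-defined; integrating the centroid momentum out analytically leaves a
Gaussian in $p$ with variance $M/\beta + M\Omega\alpha\hbar/2$ (continued),
positive exactly while $\hbar|\Omega|\beta < \pi$.  Note that this
variance closes *to zero* at the bound — sampling near the bound succeeds
but produces nearly zero-momentum points.  Beyond the bound
`sample_barrier_marginal()` raises an error naming the bound, and the
Metropolis sampler counts and rejects proposals whose effective-frequency
solve fails.

## Estimators and sign conventions

The A side of the correlation formula carries the full
Boltzmann-operator product: for the standard flavor the Moyal product of
the QDO Gaussian with $\hat x$ or $\hat p$ gives complex linear
estimators, e.g. $q + i(p-p_c)/M\Omega\alpha$ for position.  For the Kubo
flavor the centroid variables themselves are the estimators — a convention
taken from the FK-LPI literature and validated here against harmonic
closed forms.  The B side is always the bare Wigner symbol along the
trajectory.

The relative sign between the time-evolution phase and the Wigner
transform is not something we assume: the literature renders the
Heisenberg propagator both ways.  We fixed every sign against a numeric
oracle — the Wigner transform of the kernel
$\langle x|e^{-\beta\hat H}\hat x|x'\rangle$ computed on the exact grid
solution — which forces the estimator above, the spectral phases
$e^{+i(E_n - E_m)t/\hbar}$ in `exact_correlation()`, and the
$e^{-i\omega t}$ Fourier convention in `spectrum_from_cf()`.  With that
set, the harmonic position CF is
$(\hbar/2M\omega)[\coth(\beta\hbar\omega/2)\cos\omega t + i\sin\omega t]$
and the ratio of standard to Kubo spectra equals the harmonic quantum
correction factor $Q_H(\omega) = \beta\hbar\omega/(1 - e^{-\beta\hbar\omega})$
at positive frequencies.

## Propagation: standard and planetary

Standard FK-LPI propagates the sampled $(q, p)$ by velocity Verlet on the
bare potential.  This does not preserve the quantum ensemble: for the
low-temperature double well the ensemble average
$\langle x^2\rangle(t)$ rises visibly within a few vibrational periods
(zero-point energy leaking into the classical motion).

The planetary scheme repairs this.  Centroids move classically on
$W_1(x_c)$ — in 1D from a cubic-spline cache of $W_1$ and $\Omega^2$ built
once per (model, temperature), extended transparently if a trajectory
leaves the grid.  Planets are carried in *dimensionless* coordinates
$\tilde q = \sqrt{M\Omega/\hbar\alpha}\,(q - x_c)$,
$\tilde p = (p - p_c)/\sqrt{\hbar\alpha M\Omega}$ and advanced by an exact
$2\times2$ rotation through $\Omega(x_{c,\mathrm{mid}})\,dt$ per substep,
with $\Omega$ frozen at the substep midpoint — this conserves
$\tilde q^2 + \tilde p^2$ to round-off, which is the property that makes
the scheme ensemble-conserving.  Physical coordinates are recovered with
$\Omega$ and $\alpha$ evaluated at the instantaneous centroid position
(the adopted reading of the time-subscripted width).  Restricting the
output to the centroid alone gives FK-CMD (centroid molecular dynamics on
the FK centroid potential), available as `propagator = "fk_cmd"`.

If a planetary centroid wanders into a barrier region mid-trajectory the
method has no prescription; both policies are implemented
(`barrier_policy = "clamp"` to the smallest positive grid frequency, the
default, or `"error"`) and the choice is recorded on the trajectory.

## The study conditions and what the tests show

The fixture set (`fixture_ensembles()`) defines the conditions under which
every claim is tested: harmonic oscillators at $\beta \in \{0.1, 1, 8\}$,
the quartic oscillator at $\beta = 1$, a double well at $\beta = 8$, a
parabolic barrier at $0.9\pi$ of the validity bound, and a 16-particle 1D
Lennard-Jones liquid.

The double well is the model problem for comparing propagators at a
temperature where essentially only the lowest doublet is occupied.  The
literature source for that comparison does not print its parameters, so
the package fixes its own convention once: $V = -x^2/2 + x^4/4$ with
$M = \hbar = 1$ at $\beta = 8$ (well depth $1/4$, minima at $\pm 1$,
thermal doublet weight $> 99.5\%$).  The parameters were chosen so that
the smeared effective frequency stays real across the entire centroid
range at this temperature — a precondition for running the planetary
propagator at all, since deeper wells push the barrier region past the
$2\pi$ continuation bound where the FK centroid density itself is
undefined.  They remain ordinary config inputs for users who want other
regimes.

Under these conditions (1000 Metropolis centroids, 10 planets each, ten
effective-well periods at $dt = 0.02$): planetary
$\langle x^2\rangle(t)$ is stationary within Monte Carlo error (mean
$|d(t)|/\sigma \approx 0.8$, with $d(t)$ the per-block drift relative to
$t = 0$), standard FK-LPI drifts by $\sim\!20\sigma$, and the planetary
position CF tracks the exact grid-oracle CF more closely than the
standard one (time-averaged deviation ratio $\approx 0.8$).  What these
tests do *not* show: the generator has no force-field error, no
finite-size effects beyond the 1D box, and no deep-tunneling regime —
passing here demonstrates correctness of the machinery and the
qualitative planetary advantage, not quantitative accuracy for real
liquids.

## Numerical choices

* **Oracles.**  The exact 1D reference uses a Colbert–Miller
  (Fourier-grid) kinetic matrix, whose spectra converge exponentially —
  needed for the $10^{-8}$ eigenvalue checks; second-order finite
  differences would not reach that.  Spectral sums truncate at Boltzmann
  weight $10^{-10}$ and refuse to run if the last computed state still
  carries weight above $10^{-8}$.  Oracles are exercised only from the
  test suite and validation helpers, never from sampling or propagation.
* **Quadrature and series.**  $u\coth u$, $\alpha$ and
  $\ln(\sinh u/u)$ switch to Taylor branches near $u = 0$ to avoid
  cancellation; all three continue analytically to barrier frequencies.
* **Metropolis.**  Isotropic Gaussian proposals, step auto-tuned during
  burn-in to 30–50% acceptance and then frozen; momenta are drawn exactly.
  With a centroid field the chain evaluates spline $W_1$; effective
  frequencies attached to samples are then spline-interpolated.
* **Error bars** come from block averaging over 10 consecutive centroid
  blocks; stationarity is judged on per-block *drift* so that the common
  $t = 0$ sampling noise cancels.  The Monte Carlo averages are ratios of
  weighted sums — the partition function is never computed.
* **Multi-dimensional solver.**  Mass-weighted smeared Hessian →
  diagonalize → per-mode widths, iterated to stable mode frequencies;
  tensor-product Gauss–Hermite for dimension ≤ 2, common-random-number
  Monte Carlo above.  Zero modes get the free-particle width
  $\hbar^2\beta/12$; invalid imaginary modes are flagged per mode.  The
  exact normal-mode smearing loop is this package's documented convention
  (the multi-dimensional equations are only sketched in the method
  literature).
* **Configs** are YAML rather than TOML — equally diff-able and
  language-neutral, with a parser available to R — hashed (minus the
  output directory) into every output file so mixed bundles can be
  detected.

## Problem sizes

The default test and acceptance runs use: $10^5$ phase-space samples for
harmonic CF checks (2000 centroids × 50 planets, 200 steps), $10^4$
samples for the double-well comparison (1000 × 10, ~2800 steps), $10^5$
gradient-sampling draws, and grid oracles at 400–960 points.  These sizes
give 3σ margins comfortably below the asserted bounds while keeping the
whole suite under a minute on one CPU; all of them scale up linearly if
sharper error bars are wanted.

## Known limitations

* Dynamical anharmonic effects (tunneling splittings, interference) are
  outside the classical Wigner approximation by construction; the double
  well at $\beta = 8$ shows the expected dephasing in *both* propagators.
* The barrier branch samples a single imaginary mode only, and the
  planetary propagator needs $\Omega^2 > 0$ along centroid paths (clamping
  otherwise).
* The multi-dimensional solver is exercised at liquid-dimer scale;
  condensed-phase production runs (hundreds of DOF with Ewald sums,
  literature pair potentials) are out of scope here.
* Spectral estimates inherit the usual windowing bias; both raw and
  Hann-windowed spectra are available, and no instrumental resolution
  convolution is applied.
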