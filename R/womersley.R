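# Closed-form Womersley pulsatile flow: harmonic-wise relations between
# centerline velocity, volumetric flow and radial velocity profiles, for the
# circular tube (used to convert duplex centerline velocities, as the
# measurements are made in circular vessels) and for the planar channel
# (used by the 2D solver inlet).

#' Blood fluid properties
#'
#' Density and dynamic viscosity of blood treated as a Newtonian fluid. If a
#' hematocrit is supplied, viscosity is derived from it through
#' [viscosity_from_hematocrit()]; otherwise `mu` defaults to 3.5e-3 Pa s.
#'
#' @param rho density kg/m^3.
#' @param mu dynamic viscosity Pa s (ignored when `hematocrit` is given).
#' @param hematocrit optional volume fraction in (0,1).
#' @return object of class `fluid_properties` with `rho`, `mu`, `nu`,
#'   `hematocrit`.
#' @export
fluid_properties <- function(rho = 1060, mu = NULL, hematocrit = NULL) {
  assert_that(is_scalar_number(rho) && rho > 0, "domain_error", "rho must be > 0")
  if (!is.null(hematocrit)) {
    mu <- viscosity_from_hematocrit(hematocrit)
  } else if (is.null(mu)) {
    mu <- 3.5e-3
  }
  assert_that(is_scalar_number(mu) && mu > 0, "domain_error", "mu must be > 0")
  structure(list(rho = rho, mu = mu, nu = mu / rho, hematocrit = hematocrit),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> rho=%g kg/m^3  mu=%.4g Pa s  nu=%.4g m^2/s%s\n",
              x$rho, x$mu, x$nu,
              if (is.null(x$hematocrit)) "" else sprintf("  (from hematocrit %.2f)", x$hematocrit)))
  invisible(x)
}

#' Whole-blood viscosity from hematocrit
#'
#' Quadratic hematocrit-viscosity relation
#' `mu = mu_plasma * (1 + 2.5 H + 7.35 H^2)`, monotone increasing on (0,1),
#' returning plasma viscosity in the `H -> 0` limit. The exact mapping used
#' for patient simulations is not standardized, so the coefficients and
#' plasma viscosity are configurable.
#'
#' @param H hematocrit, volume fraction in (0,1).
#' @param mu_plasma plasma viscosity Pa s (default 1.2e-3).
#' @param c1,c2 linear and quadratic coefficients.
#' @return dynamic viscosity Pa s.
#' @export
viscosity_from_hematocrit <- function(H, mu_plasma = 1.2e-3, c1 = 2.5, c2 = 7.35) {
  assert_that(is_scalar_number(H) && H > 0 && H < 1, "domain_error",
              "hematocrit must lie strictly in (0, 1)")
  mu_plasma * (1 + c1 * H + c2 * H^2)
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega / nu)`: the dimensionless frequency parameter
#' governing the shape of pulsatile velocity profiles.
#'
#' @param R tube radius (or channel half-height) m, > 0.
#' @param omega angular frequency rad/s, >= 0.
#' @param nu kinematic viscosity m^2/s, > 0.
#' @export
womersley_number <- function(R, omega, nu) {
  assert_that(is_scalar_number(R) && R > 0, "domain_error", "R must be > 0")
  assert_that(is_scalar_number(nu) && nu > 0, "domain_error", "nu must be > 0")
  assert_that(is.numeric(omega) && all(omega >= 0), "domain_error", "omega must be >= 0")
  R * sqrt(omega / nu)
}

#' Bessel function of the first kind for complex argument
#'
#' `J_n(z)` for integer order `n >= 0` and complex `z`, via the periodic
#' trapezoid rule on the integral representation
#' `J_n(z) = (1/2pi) int_0^{2pi} cos(n t - z sin t) dt`, which converges
#' spectrally for analytic integrands. Accurate to near machine precision
#' for the moderate `|z|` (Womersley numbers up to a few tens) arising in
#' arterial flow.
#'
#' @param n integer order >= 0.
#' @param z complex (or real) argument, may be vectorized.
#' @param nquad number of quadrature nodes (even; default scales with |z|).
#' @export
besselJ_complex <- function(n, z, nquad = NULL) {
  assert_that(length(n) == 1L && n >= 0 && n == round(n), "domain_error",
              "order n must be a non-negative integer")
  z <- as.complex(z)
  if (is.null(nquad)) nquad <- max(64L, 2L * (4L * ceiling(max(Mod(z), 1)) + 40L))
  theta <- 2 * pi * (seq_len(nquad) - 1L) / nquad
  st <- sin(theta)
  vapply(z, function(zz) {
    mean(cos(n * theta - zz * st))
  }, complex(1))
}

# Lambda = i^{3/2} alpha, the complex Womersley argument.
womersley_lambda <- function(alpha) alpha * exp(3i * pi / 4)

#' Harmonic flow / centerline-velocity ratio in a tube
#'
#' For harmonic `n` with Womersley number `alpha`, the fully developed
#' oscillatory tube flow satisfies
#' `Q_n / u_{c,n} = pi R^2 * (1 - 2 J1(L)/(L J0(L))) / (1 - 1/J0(L))` with
#' `L = i^{3/2} alpha`; the steady harmonic uses the Poiseuille ratio
#' `pi R^2 / 2` (centerline velocity is twice the mean).
#'
#' @param R tube radius m.
#' @param alpha Womersley number (>= 0; 0 selects the steady ratio).
#' @return complex ratio, units m^2.
#' @export
womersley_tube_ratio <- function(R, alpha) {
  assert_that(is_scalar_number(R) && R > 0, "domain_error", "R must be > 0")
  if (alpha == 0) return(complex(real = pi * R^2 / 2))
  L <- womersley_lambda(alpha)
  J0 <- besselJ_complex(0L, L)
  J1 <- besselJ_complex(1L, L)
  if (Mod(J0) < 1e-14)
    stop_graftflow("numeric_error", "J0(Lambda) vanished; non-physical Womersley number")
  pi * R^2 * (1 - 2 * J1 / (L * J0)) / (1 - 1 / J0)
}

#' Harmonic flow / centerline-velocity ratio in a planar channel
#'
#' Planar analogue of [womersley_tube_ratio()] for a channel of half-height
#' `a`, per unit out-of-plane depth. The oscillatory solution is
#' `u(y) = A (1 - cosh(l y)/cosh(l a))` with `l = sqrt(i omega / nu)`, giving
#' `q_n / u_{c,n} = (2a - 2 tanh(l a)/l) / (1 - sech(l a))`; the steady
#' ratio is `4a/3` (centerline = 1.5 x mean velocity).
#'
#' @param a channel half-height m.
#' @param alpha Womersley number `a sqrt(omega/nu)`.
#' @return complex ratio, units m (flow is per unit depth).
#' @export
womersley_channel_ratio <- function(a, alpha) {
  assert_that(is_scalar_number(a) && a > 0, "domain_error", "a must be > 0")
  if (alpha == 0) return(complex(real = 4 * a / 3))
  la <- alpha * exp(1i * pi / 4)  # l * a = sqrt(i) alpha
  (2 * a - 2 * a * tanh(la) / la) / (1 - 1 / cosh(la))
}

#' Convert a centerline-velocity waveform to volumetric flow
#'
#' Applies the harmonic-wise Womersley tube relation: each harmonic of the
#' centerline velocity is multiplied by the complex ratio
#' [womersley_tube_ratio()] evaluated at that harmonic's Womersley number,
#' and the result is resynthesized as a real flow waveform. This is the
#' standard way of deriving time-varying flow rates from duplex centerline
#' velocities under a fully developed Womersley profile assumption.
#'
#' @param u a [velocity_waveform()].
#' @param R vessel radius m.
#' @param fluid a [fluid_properties()].
#' @param N harmonics retained (default 10).
#' @return a [flow_waveform()] sampled at the same times.
#' @export
flow_from_centerline <- function(u, R, fluid, N = 10L) {
  assert_that(inherits(u, "velocity_waveform"), "validation_error",
              "u must be a velocity_waveform")
  assert_that(is_scalar_number(R) && R > 0, "domain_error", "R must be > 0")
  hs <- fourier_decompose(u, N = N)
  qc <- hs$coeffs
  for (n in 0:hs$N) {
    alpha <- womersley_number(R, n * hs$omega0, fluid$nu)
    qc[n + 1L] <- qc[n + 1L] * womersley_tube_ratio(R, alpha)
  }
  hsQ <- structure(list(omega0 = hs$omega0, coeffs = qc, T = hs$T, N = hs$N),
                   class = "harmonic_series")
  flow_waveform(u$t, harmonic_eval(hsQ, u$t), u$T, site = u$site)
}

# Harmonic amplitudes of the radial tube profile for a given flow harmonic.
# Returns function(r) giving the complex profile amplitude at radius r.
tube_profile_harmonic <- function(Qn, R, alpha) {
  if (alpha == 0) {
    force(Qn)
    return(function(r) 2 * Qn / (pi * R^2) * (1 - (r / R)^2))
  }
  L <- womersley_lambda(alpha)
  J0L <- besselJ_complex(0L, L)
  J1L <- besselJ_complex(1L, L)
  B <- Qn / (pi * R^2 * (1 - 2 * J1L / (L * J0L)))
  function(r) B * (1 - besselJ_complex(0L, L * r / R) / J0L)
}

# Channel analogue: complex profile amplitude at transverse position y for a
# per-depth flow harmonic qn in a channel of half-height a.
channel_profile_harmonic <- function(qn, a, alpha) {
  if (alpha == 0) {
    return(function(y) 3 * qn / (4 * a) * (1 - (y / a)^2))
  }
  la <- alpha * exp(1i * pi / 4)
  l <- la / a
  A <- qn / (2 * a - 2 * tanh(la) / l)
  function(y) A * (1 - cosh(l * y) / cosh(la))
}

#' Womersley inlet velocity profile (tube)
#'
#' Radial velocity profile reproducing a given volumetric flow waveform
#' under the fully developed Womersley assumption. Satisfies no-slip
#' (`u(R, t) = 0` exactly), integrates back to `Q(t)` over the cross-section
#' for band-limited waveforms, reduces to the parabolic profile as
#' `alpha -> 0`, and flattens toward plug flow with annular phase lead at
#' large `alpha`.
#'
#' @param Q a [flow_waveform()].
#' @param R tube radius m.
#' @param fluid a [fluid_properties()].
#' @param t evaluation times s (vector).
#' @param r radii m in `[-R, R]` (negative values mirror the profile).
#' @param N harmonics retained.
#' @return matrix `length(r) x length(t)` of axial velocity m/s.
#' @export
inlet_profile <- function(Q, R, fluid, t, r, N = 10L) {
  assert_that(inherits(Q, "flow_waveform"), "validation_error", "Q must be a flow_waveform")
  if (any(abs(r) > R * (1 + 1e-12)))
    stop_graftflow("range_error", "radii r must satisfy |r| <= R")
  hs <- fourier_decompose(Q, N = N)
  profs <- lapply(0:hs$N, function(n) {
    alpha <- womersley_number(R, n * hs$omega0, fluid$nu)
    tube_profile_harmonic(hs$coeffs[n + 1L], R, alpha)(abs(r))
  })
  out <- matrix(0, length(r), length(t))
  for (n in 0:hs$N) {
    ph <- exp(1i * n * hs$omega0 * t)
    out <- out + Re(outer(profs[[n + 1L]], ph))
  }
  # exact no-slip at the wall regardless of truncation round-off
  out[abs(abs(r) - R) < 1e-14, ] <- 0
  out
}

#' Womersley inlet velocity profile (planar channel)
#'
#' Planar-channel analogue of [inlet_profile()] used by the 2D solver inlet:
#' given a per-unit-depth flow waveform `q` (m^2/s) and half-height `a`,
#' returns the transverse profile reproducing `q(t)`.
#'
#' @param q a [flow_waveform()] whose `Q` field holds per-depth flow m^2/s.
#' @param a channel half-height m.
#' @param fluid a [fluid_properties()].
#' @param t evaluation times s.
#' @param y transverse positions m in `[-a, a]`.
#' @param N harmonics retained.
#' @return matrix `length(y) x length(t)`.
#' @export
inlet_profile_channel <- function(q, a, fluid, t, y, N = 10L) {
  assert_that(inherits(q, "flow_waveform"), "validation_error", "q must be a flow_waveform")
  if (any(abs(y) > a * (1 + 1e-12)))
    stop_graftflow("range_error", "positions y must satisfy |y| <= a")
  hs <- fourier_decompose(q, N = N)
  profs <- lapply(0:hs$N, function(n) {
    alpha <- womersley_number(a, n * hs$omega0, fluid$nu)
    channel_profile_harmonic(hs$coeffs[n + 1L], a, alpha)(y)
  })
  out <- matrix(0, length(y), length(t))
  for (n in 0:hs$N) {
    ph <- exp(1i * n * hs$omega0 * t)
    out <- out + Re(outer(profs[[n + 1L]], ph))
  }
  out[abs(abs(y) - a) < 1e-14, ] <- 0
  out
}
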