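# Stochastic integrators for the overdamped Langevin dynamics of the free
# head.  These are the plain-R reference implementations (vectorised, using
# R's RNG); the long production simulations use the identical laws in
# src/kernel.c.

#' Stokes friction coefficient of a sphere
#'
#' @param a Sphere radius, nm.
#' @param eta Viscosity, g/(nm s).
#' @return Drag coefficient `6 pi eta a` in g/s.
#' @examples
#' friction_coefficient(3, 1e-9)  # 5.655e-8 g/s
#' @export
friction_coefficient <- function(a, eta = 1e-9) {
  stopifnot(a > 0, eta > 0)
  6 * pi * eta * a
}

#' Einstein diffusion constant
#'
#' @param kBT Thermal energy, pN nm (1 pN nm = 1 g nm^2/s^2).
#' @param xi Drag coefficient, g/s.
#' @return Diffusion constant `kBT/xi` in nm^2/s.
#' @examples
#' diffusion_constant(4.11, friction_coefficient(3))  # ~7.27e7 nm^2/s
#' @export
diffusion_constant <- function(kBT, xi) {
  stopifnot(xi > 0, kBT >= 0)
  kBT / xi
}

#' Diffusion parameters for a time-stepped simulation
#'
#' Bundles drag, diffusion constant and time step derived from
#' [physics_constants()].
#'
#' @param constants A [physics_constants()].
#' @param dt Integrator time step, s.
#' @return An object of class `diffusion_params` with fields `xi`, `D`,
#'   `dt`, `kBT`.
#' @export
diffusion_params <- function(constants = physics_constants(), dt = 1e-9) {
  stopifnot(inherits(constants, "physics_constants"), dt > 0)
  xi <- friction_coefficient(constants$head_radius, constants$eta)
  structure(list(xi = xi, D = diffusion_constant(constants$kBT, xi),
                 dt = dt, kBT = constants$kBT),
            class = "diffusion_params")
}

#' Euler-Maruyama step
#'
#' One explicit Euler step of the overdamped Langevin equation:
#' `x' = x + f(x) dt/xi + z`, with `z ~ Normal(0, 2 D dt)` drawn from R's
#' RNG.  Vectorised over `x`/`force` for ensemble use.
#'
#' @param x Current position(s), nm.
#' @param force Tether force evaluated at `x`, pN.
#' @param params A [diffusion_params()].
#' @return Updated position(s), nm.
#' @export
euler_step <- function(x, force, params) {
  stopifnot(inherits(params, "diffusion_params"))
  if (any(!is.finite(force))) stop("non-finite force")
  x + force * params$dt / params$xi +
    stats::rnorm(length(x), 0, sqrt(2 * params$D * params$dt))
}

#' Exact Ornstein-Uhlenbeck transition step
#'
#' For the Hookean tether the Langevin equation is linear, so the
#' transition over a step of length `dt` is Gaussian and can be sampled
#' exactly:
#' mean `c + (x - c) exp(-kappa dt/xi)`,
#' variance `(kBT/kappa) (1 - exp(-2 kappa dt/xi))`.
#'
#' @param x Current position(s), nm.
#' @param center Potential centre, nm.
#' @param kappa Spring stiffness, pN/nm; must be positive.
#' @param params A [diffusion_params()].
#' @return Updated position(s), nm.
#' @export
ou_exact_step <- function(x, center, kappa, params) {
  stopifnot(inherits(params, "diffusion_params"), kappa > 0)
  m <- exp(-kappa * params$dt / params$xi)
  sd <- sqrt(params$kBT / kappa * (1 - m^2))
  center + (x - center) * m + stats::rnorm(length(x), 0, sd)
}

#' Reflected Euler step (Lepingle scheme)
#'
#' One Euler step of a diffusion reflected at `barriers = c(lo, hi)`.
#' Simple clamping would pile probability mass onto the boundary; instead
#' the scheme samples the extremum of the underlying Brownian path over the
#' step via the Brownian-bridge formula and applies the Skorokhod
#' reflection map at the nearer barrier:
#' `m = (x + y - sqrt((y - x)^2 - 2 sigma^2 log U)) / 2`,
#' `x' = y + max(0, lo - m)` (lower barrier; mirrored for the upper).
#' The two barriers are far apart relative to one step, so only the nearer
#' one receives the bridge correction; in the negligible event that the
#' corrected value crosses the far barrier it is mirrored back.
#'
#' @param x Current position(s), inside `[lo, hi]`.
#' @param force Tether force at `x`, pN.
#' @param barriers Numeric `c(lo, hi)`, nm.
#' @param params A [diffusion_params()].
#' @return Updated position(s) in `[lo, hi]`.
#' @export
reflected_step <- function(x, force, barriers, params) {
  stopifnot(inherits(params, "diffusion_params"), length(barriers) == 2,
            barriers[1] < barriers[2])
  if (any(x < barriers[1] | x > barriers[2]))
    stop("x outside the reflecting barriers")
  s2 <- 2 * params$D * params$dt
  y <- x + force * params$dt / params$xi +
    stats::rnorm(length(x), 0, sqrt(s2))
  u <- stats::runif(length(x))
  lo_near <- (x - barriers[1]) <= (barriers[2] - x)
  disc <- (y - x)^2 - 2 * s2 * log(u)
  out <- y
  if (any(lo_near)) {
    m <- 0.5 * (x + y - sqrt(disc))
    corr <- pmax(0, barriers[1] - m)
    out <- ifelse(lo_near, y + corr, out)
  }
  if (any(!lo_near)) {
    M <- 0.5 * (x + y + sqrt(disc))
    corr <- pmax(0, M - barriers[2])
    out <- ifelse(!lo_near, y - corr, out)
  }
  # far-barrier safety net (probability ~0 at sensible dt)
  out <- ifelse(out > barriers[2], 2 * barriers[2] - out, out)
  out <- ifelse(out < barriers[1], 2 * barriers[1] - out, out)
  pmin(pmax(out, barriers[1]), barriers[2])
}

# Draw standard normals from the compiled ziggurat generator (exposed for
# statistical validation of the C RNG against R's).
ziggurat_normal <- function(n, seed) {
  .Call(C_znorm, as.numeric(n), as.numeric(seed))
}
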