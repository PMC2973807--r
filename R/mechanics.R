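# Force-extension laws and potential energies for the neck-linker tether,
# plus a Boltzmann quadrature oracle for stationary head-position densities.
# Units throughout: lengths nm, forces pN, energies pN nm, rates 1/s.

#' Physical constants for the Brownian dynamics
#'
#' Thermal energy, solvent viscosity and motor-head radius used to derive the
#' Stokes drag and diffusion constant of the diffusing head.
#'
#' @param kBT Thermal energy in pN nm. The default 4.11 corresponds to ~298 K.
#' @param eta Viscosity in g/(nm s); water is 1e-9.
#' @param head_radius Radius of the spherical motor head in nm.
#' @return An object of class `physics_constants`.
#' @examples
#' physics_constants()
#' @export
physics_constants <- function(kBT = 4.11, eta = 1e-9, head_radius = 3) {
  stopifnot(kBT > 0, eta > 0, head_radius > 0)
  structure(list(kBT = kBT, eta = eta, head_radius = head_radius),
            class = "physics_constants")
}

#' Mechanical model of the neck-linker tether
#'
#' The tether restraining the free motor head is described by one of three
#' force laws:
#' \describe{
#'   \item{`"wlc"`}{increasing stiffness: a worm-like chain whose restoring
#'     force diverges as the extension approaches the contour length
#'     (`n_residues * lc_per_residue`).}
#'   \item{`"hookean"`}{constant stiffness: a linear spring of stiffness
#'     `kappa`.}
#'   \item{`"reflecting"`}{a very soft spring (`kappa`, default 0.01 pN/nm)
#'     between hard reflecting barriers placed `barrier_half_width` nm either
#'     side of the potential centre.}
#' }
#'
#' Defaults follow the Kinesin-1 parameterisation: 14 residues per linker at
#' 0.364 nm/residue, persistence length 0.7 nm, Hookean stiffness 1 pN/nm and
#' a reflecting barrier at 5.3 nm.  The neck-linker-extended mutant
#' (`kinesin1_DAL`) has 17 residues, Hookean stiffness 0.8 pN/nm and a
#' barrier scaled by 17/14.
#'
#' @param kind One of `"wlc"`, `"hookean"`, `"reflecting"`.
#' @param motor `"kinesin1"` or `"kinesin1_DAL"`; sets the per-motor
#'   defaults; individual arguments override.
#' @param n_residues Residues per neck linker (14 wild type, 17 mutant).
#' @param lc_per_residue Contour length per residue, nm.
#' @param Lp Persistence length, nm (WLC only).
#' @param kappa Spring stiffness, pN/nm (Hookean and Reflecting).
#' @param barrier_half_width Distance from the potential centre to each
#'   reflecting barrier for a single-linker tether, nm.  The printed value
#'   5.3 nm (close to 14 x 0.38) is retained for the wild type and scaled by
#'   residue count for the mutant.
#' @return An object of class `neck_linker_model`.
#' @examples
#' neck_linker_model("wlc")
#' neck_linker_model("reflecting", motor = "kinesin1_DAL")
#' @export
neck_linker_model <- function(kind = c("wlc", "hookean", "reflecting"),
                              motor = c("kinesin1", "kinesin1_DAL"),
                              n_residues = NULL, lc_per_residue = 0.364,
                              Lp = 0.7, kappa = NULL,
                              barrier_half_width = NULL) {
  kind <- match.arg(kind)
  motor <- match.arg(motor)
  dal <- motor == "kinesin1_DAL"
  if (is.null(n_residues)) n_residues <- if (dal) 17L else 14L
  if (is.null(kappa)) {
    kappa <- switch(kind,
                    wlc = 0,
                    hookean = if (dal) 0.8 else 1.0,
                    reflecting = 0.01)
  }
  if (is.null(barrier_half_width)) {
    barrier_half_width <- 5.3 * n_residues / 14
  }
  stopifnot(n_residues >= 1, lc_per_residue > 0, Lp > 0, kappa >= 0,
            barrier_half_width > 0)
  structure(list(kind = kind, motor = motor, n_residues = n_residues,
                 lc_per_residue = lc_per_residue, Lp = Lp, kappa = kappa,
                 barrier_half_width = barrier_half_width),
            class = "neck_linker_model")
}

#' @export
print.neck_linker_model <- function(x, ...) {
  cat("Neck linker model:", x$kind, "(", x$motor, ")\n")
  cat("  residues/linker:", x$n_residues, " contour:",
      format(x$n_residues * x$lc_per_residue, digits = 4), "nm\n")
  if (x$kind == "wlc")
    cat("  persistence length:", x$Lp, "nm\n")
  if (x$kind != "wlc")
    cat("  stiffness:", x$kappa, "pN/nm\n")
  if (x$kind == "reflecting")
    cat("  barrier half-width:", format(x$barrier_half_width, digits = 4),
        "nm (single linker)\n")
  invisible(x)
}

#' Tether configuration for a chemical state
#'
#' Resolves a neck-linker model into the effective tether acting on the free
#' head in a given chemical state: in the pre-docking state the head is held
#' by both neck linkers (contour length doubles, Hookean springs act in
#' series so the stiffness halves, reflecting barriers move out to twice the
#' single-linker half-width); after ATP binding and docking a single linker
#' remains.
#'
#' @param model A [neck_linker_model()].
#' @param center Centre of the tether potential, nm.
#' @param n_linkers 1 (docked states) or 2 (both linkers disordered).
#' @return An object of class `tether_configuration` with fields `center`,
#'   `n_linkers`, `Lc` (effective contour length), `kappa` (effective
#'   stiffness) and `barriers` (reflecting only).
#' @examples
#' m <- neck_linker_model("wlc")
#' tether_configuration(m, center = 4.1, n_linkers = 1)
#' @export
tether_configuration <- function(model, center, n_linkers = 1) {
  stopifnot(inherits(model, "neck_linker_model"),
            n_linkers %in% c(1, 2), is.finite(center))
  Lc <- n_linkers * model$n_residues * model$lc_per_residue
  kappa <- if (model$kind == "hookean") model$kappa / n_linkers else model$kappa
  barriers <- NULL
  if (model$kind == "reflecting") {
    half <- n_linkers * model$barrier_half_width
    barriers <- c(center - half, center + half)
  }
  structure(list(center = center, n_linkers = n_linkers, Lc = Lc,
                 kappa = kappa, barriers = barriers, kind = model$kind,
                 Lp = model$Lp),
            class = "tether_configuration")
}

#' Worm-like chain force-extension law
#'
#' Entropic restoring force required to hold a chain of contour length `Lc`
#' and persistence length `Lp` at end-to-end extension `x`:
#' `(kBT/Lp) * (1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc)`.
#'
#' @param x Extension, nm; must satisfy `0 <= x < Lc`.
#' @param Lp Persistence length, nm.
#' @param Lc Contour length, nm.
#' @param kBT Thermal energy, pN nm.
#' @return Force in pN (vectorised over `x`).
#' @examples
#' wlc_force(2.548, Lp = 0.7, Lc = 5.096)  # half extension, ~7.34 pN
#' @export
wlc_force <- function(x, Lp, Lc, kBT = 4.11) {
  stopifnot(Lp > 0, Lc > 0, kBT > 0)
  if (any(x < 0 | x >= Lc))
    stop("extension must lie in [0, Lc); cap extensions before calling")
  s <- x / Lc
  (kBT / Lp) * (0.25 / (1 - s)^2 - 0.25 + s)
}

# closed-form WLC stretching energy (antiderivative of the force law)
wlc_energy <- function(x, Lp, Lc, kBT = 4.11) {
  s <- x / Lc
  (kBT / Lp) * Lc * (s^2 / 2 - s / 4 + 0.25 / (1 - s) - 0.25)
}

#' Signed tether force on the free head
#'
#' Restoring force exerted by the tether at head position `x`.  All three
#' laws are symmetric about the potential centre, so the magnitude is the
#' extension law evaluated at `|x - center|` and the sign always points back
#' toward the centre.
#'
#' @param x Head position(s), nm.
#' @param tether A [tether_configuration()].
#' @param model A [neck_linker_model()].
#' @return Signed force in pN.
#' @examples
#' m <- neck_linker_model("hookean")
#' tc <- tether_configuration(m, center = 4.1)
#' tether_force(6.1, tc, m)  # 2 nm extension of a 1 pN/nm spring: -2 pN
#' @export
tether_force <- function(x, tether, model) {
  stopifnot(inherits(tether, "tether_configuration"))
  d <- x - tether$center
  mag <- switch(model$kind,
    wlc = wlc_force(abs(d), model$Lp, tether$Lc),
    hookean = tether$kappa * abs(d),
    reflecting = tether$kappa * abs(d))
  -sign(d) * mag
}

#' Tether potential energy
#'
#' Potential whose negative gradient is [tether_force()], anchored at
#' `U(center) = 0`.  Hookean and Reflecting use the quadratic closed form;
#' the WLC uses the integrated force-extension law.
#'
#' @inheritParams tether_force
#' @return Energy in pN nm.
#' @export
potential_energy <- function(x, tether, model) {
  stopifnot(inherits(tether, "tether_configuration"))
  d <- abs(x - tether$center)
  switch(model$kind,
    wlc = wlc_energy(d, model$Lp, tether$Lc),
    hookean = 0.5 * tether$kappa * d^2,
    reflecting = 0.5 * tether$kappa * d^2)
}

#' Boltzmann stationary density of the tethered head
#'
#' Normalised equilibrium density `exp(-U(x)/kBT)` of the head position on a
#' grid.  This is the analytic oracle for the long-run histograms produced
#' by the stochastic integrators: a Gaussian for the Hookean spring, a
#' truncated exp-quadratic between the barriers for the Reflecting model and
#' the exponentiated worm-like-chain potential (support `|x - c| < Lc`) for
#' the WLC.
#'
#' @inheritParams tether_force
#' @param constants A [physics_constants()].
#' @param grid Increasing numeric vector of positions, nm.  Must lie inside
#'   the WLC support; for the Reflecting model, density outside the barriers
#'   is zero.
#' @return Numeric vector of densities (1/nm) integrating to 1 over `grid`
#'   by the trapezoid rule.
#' @examples
#' m <- neck_linker_model("hookean")
#' tc <- tether_configuration(m, center = 4.1)
#' g <- seq(-6, 14, length.out = 2001)
#' d <- boltzmann_density(tc, m, physics_constants(), g)
#' sum((d[-1] + d[-length(d)]) / 2 * diff(g))  # 1
#' @export
boltzmann_density <- function(tether, model, constants = physics_constants(),
                              grid) {
  stopifnot(inherits(constants, "physics_constants"),
            length(grid) > 2, all(diff(grid) > 0))
  if (model$kind == "wlc" &&
      any(abs(grid - tether$center) >= tether$Lc))
    stop("grid exceeds the worm-like chain support (center +/- Lc)")
  u <- potential_energy(grid, tether, model)
  dens <- exp(-u / constants$kBT)
  if (model$kind == "reflecting") {
    eps <- 1e-9
    dens[grid < tether$barriers[1] - eps |
         grid > tether$barriers[2] + eps] <- 0
  }
  z <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  dens / z
}

#' Mass of a density on an interval
#'
#' Trapezoid-rule integral of a gridded density over `[lo, hi]`, used to
#' turn [boltzmann_density()] into a binding-zone occupancy.
#'
#' @param grid,dens Grid and density as returned by [boltzmann_density()].
#' @param lo,hi Interval bounds, nm.
#' @return Probability mass on the interval.
#' @export
density_mass <- function(grid, dens, lo, hi) {
  keep <- grid >= lo & grid <= hi
  g <- grid[keep]
  d <- dens[keep]
  if (length(g) < 2) return(0)
  sum((d[-1] + d[-length(d)]) / 2 * diff(g))
}
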