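# The five-state chemomechanical cycle coupled to the diffusing head.
#
# States: 1 both heads bound; 2 one head tethered, no nucleotide; 3 ATP
# bound, neck linker docked; 4 post-hydrolysis (the vulnerable state where
# tethered-head attachment races bound-head release); 5 detached
# (absorbing).  State 1 is simulated with a Gillespie exponential hold;
# states 2-4 advance the head one SDE step per dt and then apply ordered
# Bernoulli thresholds for the chemical channels.

#' Rate constants of the chemomechanical cycle
#'
#' Default values are the Kinesin-1 parameterisation; `k_attach` depends on
#' the neck-linker model because it is calibrated so that the effective
#' attachment rate (k_attach times the binding-zone occupancy) exceeds the
#' overall ~100/s stepping rate.
#'
#' @param model Neck-linker model kind, sets the `k_attach` default:
#'   75000/s (wlc, Lp = 0.7 nm), 12000/s (wlc, Lp = 2 nm), 10000/s
#'   (hookean), 3500/s (reflecting).
#' @param Lp Persistence length, used only to pick the WLC `k_attach`.
#' @param k_attach Attachment rate inside the binding zone, 1/s.
#' @param atp_conc ATP concentration, uM (1 mM default).
#' @param k_detach,k_detach_rev State 1 exit rates, 1/s.
#' @param k_ATP_on ATP on-rate, 1/uM/s.
#' @param k_ATP_off,k_hydrolysis,k_hydrolysis_rev Chemical rates, 1/s.
#' @param k_attach_rev Reverse attachment rate, 1/s.  Listed in the rate
#'   table but used by no transition of the simulated cycle; carried for
#'   completeness.
#' @param k_unbind Bound-head release rate from state 4, 1/s.
#' @return An object of class `rate_constants`.
#' @export
rate_constants <- function(model = c("wlc", "hookean", "reflecting"),
                           Lp = 0.7, k_attach = NULL, atp_conc = 1000,
                           k_detach = 250, k_detach_rev = 0.25,
                           k_ATP_on = 3, k_ATP_off = 200,
                           k_hydrolysis = 300, k_hydrolysis_rev = 8,
                           k_attach_rev = 0.45, k_unbind = 3) {
  model <- match.arg(model)
  if (is.null(k_attach)) {
    k_attach <- switch(model,
      wlc = if (Lp >= 2) 12000 else 75000,
      hookean = 10000,
      reflecting = 3500)
  }
  r <- list(k_detach = k_detach, k_detach_rev = k_detach_rev,
            k_ATP_on = k_ATP_on, k_ATP_off = k_ATP_off,
            k_hydrolysis = k_hydrolysis,
            k_hydrolysis_rev = k_hydrolysis_rev,
            k_attach = k_attach, k_attach_rev = k_attach_rev,
            k_unbind = k_unbind, atp_conc = atp_conc)
  if (any(unlist(r) < 0)) stop("rate constants must be non-negative")
  structure(r, class = "rate_constants")
}

#' Track geometry
#'
#' @param site_spacing Tubulin-dimer spacing along a protofilament, nm.
#' @param zone_half_width Half-width of the binding zone around each site,
#'   nm (binding allowed when the head is within this distance of a site).
#' @param docking_bias Forward displacement of the tether centre caused by
#'   neck-linker docking, nm.
#' @return An object of class `track_geometry`.
#' @export
track_geometry <- function(site_spacing = 8.2, zone_half_width = 1,
                           docking_bias = 4.1) {
  stopifnot(zone_half_width < site_spacing / 2, docking_bias > 0)
  structure(list(site_spacing = site_spacing,
                 zone_half_width = zone_half_width,
                 docking_bias = docking_bias),
            class = "track_geometry")
}

#' Full simulation configuration
#'
#' Assembles the neck-linker model, rate constants, geometry, physics and
#' integrator settings for one motor.  The integrator time step defaults to
#' 1 ns for the WLC (whose force law is stiff near full extension) and
#' 10 ns for the Hookean (exact transitions) and Reflecting models, and is
#' validated against the fastest chemical channel so that every Bernoulli
#' threshold sum stays below 0.1 per step.
#'
#' `center_convention` selects where the tether potential sits in states 2
#' and 3 (state 4 is always centred at `docking_bias`):
#' `"results"` places the two-linker state-2 potential at the bound head
#' (centre 0) and docks the centre at 4.1 nm for both ATP states, matching
#' the stationary-distribution figures; `"methods"` centres state 2 between
#' the binding sites (-4.1 nm) and state 3 at 0.  See the vignette for why
#' `"results"` is the default.
#'
#' @param motor `"kinesin1"` or `"kinesin1_DAL"`.
#' @param model Neck-linker model kind (`"wlc"`, `"hookean"`,
#'   `"reflecting"`) or a [neck_linker_model()] object.
#' @param Lp WLC persistence length, nm.
#' @param atp_conc ATP concentration, uM.
#' @param k_attach Optional override of the model-specific attachment rate.
#' @param rates,geometry,physics Component objects; built from the other
#'   arguments when `NULL`.
#' @param dt Integrator time step, s.
#' @param center_convention `"results"` or `"methods"` (see Details).
#' @param max_time Wall-clock cap on simulated time per run, s.
#' @param cap_fraction WLC extensions are capped at this fraction of the
#'   contour length when evaluating the (diverging) force.
#' @param allow_rear_s4 Permit binding to the rearward site from state 4
#'   (the algorithm restricts state-4 binding to the forward site; this
#'   flag exists for sensitivity analysis).
#' @param n_runs,base_seed Default ensemble size and seed carried with the
#'   configuration (used by [simulate_ensemble()] and [run_experiment()]).
#' @return An object of class `engine_config`.
#' @examples
#' cfg <- engine_config("kinesin1", "reflecting")
#' cfg
#' @export
engine_config <- function(motor = c("kinesin1", "kinesin1_DAL"),
                          model = c("wlc", "hookean", "reflecting"),
                          Lp = 0.7, atp_conc = 1000, k_attach = NULL,
                          rates = NULL, geometry = track_geometry(),
                          physics = physics_constants(), dt = NULL,
                          center_convention = c("results", "methods"),
                          max_time = 120, cap_fraction = 0.995,
                          allow_rear_s4 = FALSE, n_runs = 50,
                          base_seed = 1) {
  motor <- match.arg(motor)
  if (is.character(model)) {
    model <- neck_linker_model(match.arg(model), motor = motor, Lp = Lp)
  }
  stopifnot(inherits(model, "neck_linker_model"))
  center_convention <- match.arg(center_convention)
  if (is.null(rates)) {
    rates <- rate_constants(model$kind, Lp = model$Lp,
                            k_attach = k_attach, atp_conc = atp_conc)
  } else if (!is.null(k_attach)) {
    rates$k_attach <- k_attach
  }
  if (is.null(dt)) dt <- if (model$kind == "wlc") 1e-9 else 1e-8
  max_exit <- max(
    rates$k_attach + rates$k_ATP_on * rates$atp_conc,          # state 2
    rates$k_ATP_off + rates$k_hydrolysis,                      # state 3
    rates$k_hydrolysis_rev + rates$k_unbind + rates$k_attach)  # state 4
  if (max_exit * dt > 0.1) {
    stop(sprintf(
      "dt too large: max exit rate %.3g/s gives per-step probability %.3g > 0.1",
      max_exit, max_exit * dt))
  }
  structure(list(motor = motor, model = model, rates = rates,
                 geometry = geometry, physics = physics, dt = dt,
                 center_convention = center_convention,
                 max_time = max_time, cap_fraction = cap_fraction,
                 allow_rear_s4 = allow_rear_s4,
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed)),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat("Engine config:", x$motor, "/", x$model$kind, "\n")
  cat("  k_attach:", x$rates$k_attach, "/s  ATP:", x$rates$atp_conc,
      "uM  dt:", format(x$dt * 1e9, digits = 3), "ns\n")
  cat("  tether centers (S2,S3,S4):",
      paste(format(state_centers(x), digits = 3), collapse = ", "),
      "nm (", x$center_convention, "convention )\n")
  invisible(x)
}

# tether potential centres for states 2, 3, 4 under the chosen convention
state_centers <- function(config) {
  b <- config$geometry$docking_bias
  if (config$center_convention == "results") c(0, b, b) else c(-b, 0, b)
}

# tether_configuration objects for the three diffusive states
state_tethers <- function(config) {
  cen <- state_centers(config)
  list(s2 = tether_configuration(config$model, cen[1], n_linkers = 2),
       s3 = tether_configuration(config$model, cen[2], n_linkers = 1),
       s4 = tether_configuration(config$model, cen[3], n_linkers = 1))
}

#' Gillespie draw for the both-heads-bound state
#'
#' State 1 has no diffusing head, so its dwell is an exponential hold with
#' rate `k_detach + k_detach_rev`; the exit goes to state 2 (rear head
#' releases) with probability `k_detach/(k_detach + k_detach_rev)` and
#' otherwise reverses the last attachment (front head releases, state 4).
#'
#' @param rates A [rate_constants()].
#' @return `list(dwell = <s>, next_state = 2L or 4L)`.
#' @export
gillespie_state1 <- function(rates) {
  total <- rates$k_detach + rates$k_detach_rev
  list(dwell = stats::rexp(1, total),
       next_state = if (stats::runif(1) < rates$k_detach / total) 2L else 4L)
}

#' Position-dependent binding rate
#'
#' `k_attach` when the head is within the zone half-width of an allowed
#' site (closed interval), zero otherwise.
#'
#' @param x Head position(s), nm, relative to the bound head.
#' @param sites Allowed target sites, nm (state 2: `c(-8.2, 8.2)`; state 4:
#'   `8.2`).
#' @param geometry A [track_geometry()].
#' @param k_attach Attachment rate, 1/s.
#' @return Rate(s), 1/s.
#' @export
binding_rate <- function(x, sites, geometry, k_attach) {
  near <- vapply(x, function(xx) any(abs(xx - sites) <= geometry$zone_half_width),
                 logical(1))
  ifelse(near, k_attach, 0)
}

# allowed binding sites by state
state_sites <- function(state, config) {
  s <- config$geometry$site_spacing
  if (state == 2L) c(-s, s)
  else if (state == 4L) {
    if (config$allow_rear_s4) c(-s, s) else s
  } else numeric(0)
}

# Ordered Bernoulli thresholds of the per-dt chemical channels, given the
# uniform draw u.  Returns the next state (possibly unchanged).  Binding
# targets the site whose zone contains the head.
chem_transition <- function(state, x, config, u) {
  r <- config$rates
  dt <- config$dt
  kx <- binding_rate(x, state_sites(state, config), config$geometry,
                     r$k_attach)
  if (state == 2L) {
    atp <- r$k_ATP_on * r$atp_conc
    if (u <= kx * dt) 1L
    else if (u <= (kx + atp) * dt) 3L
    else 2L
  } else if (state == 3L) {
    if (u <= r$k_ATP_off * dt) 2L
    else if (u <= (r$k_ATP_off + r$k_hydrolysis) * dt) 4L
    else 3L
  } else if (state == 4L) {
    hr <- r$k_hydrolysis_rev
    if (u <= hr * dt) 3L
    else if (u <= (hr + r$k_unbind) * dt) 5L
    else if (u <= (hr + r$k_unbind + kx) * dt) 1L
    else 4L
  } else stop("not a diffusive state")
}

#' One coupled step of a diffusive state
#'
#' Reference implementation of the per-dt update for states 2-4: advance
#' the head one SDE step under the state's tether (integrator chosen by the
#' model kind), then draw one uniform variate and apply the ordered
#' Bernoulli thresholds of the chemical channels.  The production ensembles
#' run the identical update in compiled code.
#'
#' @param state Current chemical state, 2, 3 or 4.
#' @param head Current head position, nm.
#' @param config An [engine_config()].
#' @return `list(head = <nm>, state = <next state>)`; the head position
#'   carries over unchanged across a chemical transition.
#' @export
diffusive_state_step <- function(state, head, config) {
  tc <- state_tethers(config)[[state - 1L]]
  params <- diffusion_params(config$physics, config$dt)
  x <- if (config$model$kind == "hookean") {
    ou_exact_step(head, tc$center, tc$kappa, params)
  } else if (config$model$kind == "reflecting") {
    reflected_step(min(max(head, tc$barriers[1]), tc$barriers[2]),
                   tether_force(head, tc, config$model), tc$barriers, params)
  } else {
    ext <- abs(head - tc$center)
    capped <- min(ext, config$cap_fraction * tc$Lc)
    f <- -sign(head - tc$center) * wlc_force(capped, config$model$Lp, tc$Lc)
    drift <- min(abs(f) * params$dt / params$xi, ext)
    xn <- head - sign(head - tc$center) * drift +
      stats::rnorm(1, 0, sqrt(2 * params$D * params$dt))
    lim <- 0.999 * tc$Lc
    min(max(xn, tc$center - lim), tc$center + lim)
  }
  list(head = x, state = chem_transition(state, x, config, stats::runif(1)))
}

#' Apply a binding event to a motor assembly
#'
#' Bookkeeping for the moment the free head captures a site `8.2 n` nm
#' from the bound head: the head snaps to the site centre, the pair
#' becomes both-bound, and the coordinate frame re-centres on the front
#' head.  Binding the forward site (`site_n = +1`) advances the motor one
#' site; binding the rearward site from the tethered state re-creates the
#' previous both-bound configuration, so it adds no net displacement (a
#' futile rebind).  Negative displacements arise only when an attachment
#' is reversed (front-head release), which the run simulator logs as a
#' backward step.
#'
#' @param assembly List with `bound_position` (absolute nm of the bound
#'   head), `displacement` (cumulative signed nm) and `steps` (signed step
#'   record); see [run_single_motor()] for where these live in a full run.
#' @param site_n Target site index relative to the bound head (+1 forward,
#'   -1 rearward).
#' @param geometry A [track_geometry()].
#' @return The updated assembly, with `head` snapped to the new frame
#'   origin.
#' @export
complete_step_on_binding <- function(assembly, site_n,
                                     geometry = track_geometry()) {
  stopifnot(site_n %in% c(-1, 1))
  s <- geometry$site_spacing
  if (site_n > 0) {
    assembly$bound_position <- assembly$bound_position + s
    assembly$displacement <- assembly$displacement + s
    assembly$steps <- c(assembly$steps, s)
  }
  assembly$head <- 0
  assembly
}

# pack an engine_config into the flat parameter vector read by C_run_motor
pack_engine_par <- function(config, record_events = TRUE) {
  m <- config$model
  r <- config$rates
  g <- config$geometry
  xi <- friction_coefficient(config$physics$head_radius, config$physics$eta)
  cen <- state_centers(config)
  kind <- match(m$kind, c("wlc", "hookean", "reflecting")) - 1
  Lc1 <- m$n_residues * m$lc_per_residue
  kap1 <- if (m$kind == "hookean") m$kappa else m$kappa
  c(kind, config$dt, xi, config$physics$kBT, config$cap_fraction,
    cen[1], cen[2], cen[3],
    Lc1, 2 * Lc1, m$Lp,
    kap1, if (m$kind == "hookean") m$kappa / 2 else m$kappa,
    m$barrier_half_width, 2 * m$barrier_half_width,
    r$k_detach, r$k_detach_rev, r$k_ATP_on * r$atp_conc, r$k_ATP_off,
    r$k_hydrolysis, r$k_hydrolysis_rev, r$k_attach, r$k_unbind,
    g$site_spacing, g$zone_half_width, as.numeric(config$allow_rear_s4),
    config$max_time, as.numeric(record_events))
}

#' Simulate one processive run
#'
#' Runs the full chemomechanical cycle from the initial condition (state 2,
#' free head at the rear site) until detachment (state 5) or `max_time`.
#' Every chemical transition is logged with its time and the head position
#' at the firing step; completed mechanical steps are signed multiples of
#' the site spacing.
#'
#' @param config An [engine_config()].
#' @param seed Integer seed; runs are reproducible given (config, seed).
#' @param record_events Keep the full event log (default) or only the
#'   summary counters.
#' @return An object of class `motor_run`: fields `run_length` (nm, signed
#'   cumulative displacement), `total_time` (s), `termination`
#'   (`"detached"` or `"max_time"`), step counters, `events` data frame.
#' @export
run_single_motor <- function(config, seed, record_events = TRUE) {
  stopifnot(inherits(config, "engine_config"))
  res <- .Call(C_run_motor, pack_engine_par(config, record_events),
               as.numeric(seed))
  res$termination <- if (res$termination == 0) "detached" else "max_time"
  res$events <- as.data.frame(res$events)
  res$seed <- seed
  class(res) <- "motor_run"
  res
}

#' @export
print.motor_run <- function(x, ...) {
  cat("Motor run:", format(x$run_length, digits = 4), "nm in",
      format(x$total_time, digits = 4), "s (", x$termination, ")\n")
  cat("  steps: +", x$n_steps_forward, " / -", x$n_steps_backward,
      "; futile rebinds:", x$n_futile_rebinds, "\n", sep = "")
  invisible(x)
}

#' Simulate an ensemble of independent runs
#'
#' Runs are seeded as `base_seed + run index`, making the ensemble
#' reproducible and embarrassingly parallel in principle (executed
#' serially here).
#'
#' @param config An [engine_config()].
#' @param n_runs Number of independent runs.
#' @param base_seed Integer base seed.
#' @param record_events Keep per-run event logs (turn off to save memory
#'   in large ensembles).
#' @return An object of class `motor_ensemble` (list of `motor_run`s with
#'   the config attached).
#' @export
simulate_ensemble <- function(config, n_runs = config$n_runs,
                              base_seed = config$base_seed,
                              record_events = FALSE) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    run_single_motor(config, seed = base_seed + i, record_events)
  })
  structure(list(runs = runs, config = config, base_seed = base_seed),
            class = "motor_ensemble")
}

#' @export
print.motor_ensemble <- function(x, ...) {
  print(ensemble_summary(x))
  invisible(x)
}
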