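# Statistics over trajectories and ensembles: stationary histograms, zone
# occupancy, recurrence times, velocity/run-length summaries, and small
# analytic utilities.

#' Stationary distribution of the tethered head
#'
#' Long single-state simulation of the diffusing head with attachment
#' switched off (`k_attach = 0`), as used for the stationary
#' position-distribution profiles: either the pre-docking state
#' (`"two_linker"`, both neck linkers disordered) or the docked state
#' (`"one_linker"`, centre displaced forward by the docking bias).
#' Occupancy of the forward binding zone and completed-excursion
#' recurrence statistics are accumulated on the fly.
#'
#' @param config An [engine_config()].
#' @param state `"one_linker"` (docked, default) or `"two_linker"`.
#' @param sim_time Simulated time, s (default 10 ms).
#' @param seed Integer seed.
#' @param nbins Number of histogram bins spanning the support.
#' @param dt Optional override of the configured time step.
#' @param burn_in Steps discarded before accumulating (the tether relaxes
#'   within tens of ns; the default discards 10 us at dt = 1 ns).
#' @return An object of class `stationary_distribution`: `bin_edges`,
#'   `probability` (sums to 1), `density`, `total_time`, `zone_occupancy`,
#'   `recurrence_time` (s; `NA` until at least one completed excursion),
#'   `n_excursions`, `mean`, `sd`, `warning` (set when the trajectory is
#'   too short for a stable zone estimate).
#' @examples
#' cfg <- engine_config("kinesin1", "reflecting")
#' sd1 <- stationary_distribution(cfg, sim_time = 1e-4, seed = 1)
#' sd1$zone_occupancy
#' @export
stationary_distribution <- function(config, state = c("one_linker",
                                                      "two_linker"),
                                    sim_time = 0.01, seed = 1, nbins = 400,
                                    dt = NULL, burn_in = 1e4) {
  stopifnot(inherits(config, "engine_config"))
  state <- match.arg(state)
  if (is.null(dt)) dt <- config$dt
  tc <- if (state == "one_linker") state_tethers(config)$s4
        else state_tethers(config)$s2
  m <- config$model
  xi <- friction_coefficient(config$physics$head_radius, config$physics$eta)
  supp <- support_interval(tc, m, config$physics)
  kind <- match(m$kind, c("wlc", "hookean", "reflecting")) - 1
  par <- c(kind, tc$center, tc$Lc, m$Lp, tc$kappa,
           if (is.null(tc$barriers)) c(0, 0) else tc$barriers,
           config$physics$kBT, xi, dt, config$cap_fraction)
  n_steps <- ceiling(sim_time / dt)
  zone <- config$geometry$site_spacing +
    c(-1, 1) * config$geometry$zone_half_width
  res <- .Call(C_stationary, par, as.numeric(n_steps), as.numeric(burn_in),
               as.numeric(seed), c(supp[1], supp[2], nbins), zone)
  edges <- seq(supp[1], supp[2], length.out = nbins + 1)
  prob <- res$counts / res$n_steps
  p_zone <- res$n_in_zone / res$n_steps
  rec <- if (res$n_excursions > 0) {
    res$excursion_steps * dt / res$n_excursions
  } else NA_real_
  warn <- if (res$n_in_zone < 1e3)
    "fewer than 1000 in-zone samples; zone occupancy is noisy" else NULL
  structure(list(bin_edges = edges, probability = prob,
                 density = prob / diff(edges),
                 total_time = n_steps * dt, dt = dt,
                 zone = zone, zone_occupancy = p_zone,
                 recurrence_time = rec, n_excursions = res$n_excursions,
                 mean = res$sum_x / res$n_steps,
                 sd = sqrt(res$sum_x2 / res$n_steps -
                           (res$sum_x / res$n_steps)^2),
                 cap_hits = res$cap_hits, state = state,
                 tether = tc, model = m, warning = warn),
            class = "stationary_distribution")
}

# simulation/plotting support of a tether: WLC support, reflecting
# barriers, or +/- 6 sd for the unbounded Hookean spring
support_interval <- function(tether, model, physics) {
  switch(model$kind,
    wlc = tether$center + c(-1, 1) * tether$Lc,
    reflecting = tether$barriers,
    hookean = tether$center +
      c(-6.5, 6.5) * sqrt(physics$kBT / tether$kappa))
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("Stationary distribution (", x$state, ", ", x$model$kind, "): ",
      format(x$total_time * 1e3, digits = 4), " ms at dt = ",
      format(x$dt * 1e9, digits = 3), " ns\n", sep = "")
  cat("  mean ", format(x$mean, digits = 4), " nm, sd ",
      format(x$sd, digits = 4), " nm\n", sep = "")
  cat("  zone [", x$zone[1], ", ", x$zone[2], "] occupancy: ",
      format(x$zone_occupancy, digits = 3), "\n", sep = "")
  cat("  recurrence time: ",
      if (is.na(x$recurrence_time)) "NA" else
        paste0(format(x$recurrence_time * 1e9, digits = 4), " ns"),
      " (", x$n_excursions, " excursions)\n", sep = "")
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

#' @export
plot.stationary_distribution <- function(x, ...) {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mid, x$density, type = "l", xlab = "position (nm)",
                 ylab = "density (1/nm)", ...)
  graphics::abline(v = x$zone, lty = 3)
  invisible(x)
}

#' Mean recurrence time of a sampled trajectory
#'
#' Mean time, over all completed excursions, from leaving the zone to next
#' re-entering it, for a trajectory sampled at interval `dt`.  Excursions
#' truncated by the end of the trajectory are discarded.
#'
#' @param x Numeric vector of sampled positions, nm.
#' @param zone `c(lo, hi)`, nm.
#' @param dt Sampling interval, s.
#' @param min_excursions Error when fewer completed excursions are found.
#' @return Mean recurrence time, s.
#' @export
recurrence_time <- function(x, zone, dt, min_excursions = 100) {
  stopifnot(length(zone) == 2, zone[1] < zone[2], dt > 0)
  inz <- x >= zone[1] & x <= zone[2]
  if (!any(inz) || all(inz))
    stop("trajectory must both visit and leave the zone")
  r <- rle(inz)
  out_lens <- r$lengths[!r$values]
  # drop excursions truncated by either end of the trajectory
  if (!r$values[1]) out_lens <- out_lens[-1]
  if (length(r$values) && !r$values[length(r$values)] && length(out_lens))
    out_lens <- out_lens[-length(out_lens)]
  if (length(out_lens) < min_excursions)
    stop(sprintf("only %d completed excursions (need >= %d)",
                 length(out_lens), min_excursions))
  mean(out_lens) * dt
}

#' Velocity and run-length summary of an ensemble
#'
#' Per-run velocity is the signed cumulative displacement divided by the
#' run's elapsed time; the ensemble summary is the arithmetic mean with
#' standard error across runs (not a pooled distance/time ratio, matching
#' how motor assays are reported).
#'
#' @param ensemble A [simulate_ensemble()] result or list of `motor_run` objects.
#' @return An object of class `ensemble_summary` with `n_runs`,
#'   `velocity_mean`, `velocity_sem` (nm/s), `runlength_mean`,
#'   `runlength_sem` (nm), `detach_per_step` (completed runs per forward
#'   step), `backward_fraction` and `mean_steps`.
#' @export
ensemble_summary <- function(ensemble) {
  runs <- if (inherits(ensemble, "motor_ensemble")) ensemble$runs
          else ensemble
  runs <- Filter(function(r) inherits(r, "motor_run"), runs)
  done <- Filter(function(r) r$termination == "detached", runs)
  if (length(done) < 2)
    stop("need at least 2 completed (detached) runs")
  rl <- vapply(done, function(r) r$run_length, numeric(1))
  tt <- vapply(done, function(r) r$total_time, numeric(1))
  v <- rl / tt
  nf <- vapply(done, function(r) r$n_steps_forward, numeric(1))
  nb <- vapply(done, function(r) r$n_steps_backward, numeric(1))
  n <- length(done)
  structure(list(n_runs = n,
                 velocity_mean = mean(v),
                 velocity_sem = stats::sd(v) / sqrt(n),
                 runlength_mean = mean(rl),
                 runlength_sem = stats::sd(rl) / sqrt(n),
                 detach_per_step = n / sum(nf + nb),
                 backward_fraction = sum(nb) / max(1, sum(nf + nb)),
                 mean_steps = mean(nf + nb),
                 n_incomplete = length(runs) - n),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble of", x$n_runs, "completed runs\n")
  cat(sprintf("  velocity:   %.0f +/- %.0f nm/s (mean +/- SEM)\n",
              x$velocity_mean, x$velocity_sem))
  cat(sprintf("  run length: %.0f +/- %.0f nm\n",
              x$runlength_mean, x$runlength_sem))
  cat(sprintf("  detach/step: %.4f  backward fraction: %.4f\n",
              x$detach_per_step, x$backward_fraction))
  invisible(x)
}

#' Effective concentration of a tethered motor head
#'
#' Concentration equivalent of confining one molecule to a hemispheric
#' volume of the given radius around its binding site; used to convert the
#' first-order attachment rate into an equivalent bimolecular on-rate.
#'
#' @param radius Hemisphere radius, nm.
#' @return Molar concentration (mol/L).
#' @examples
#' effective_concentration(1)  # ~0.79 M
#' @export
effective_concentration <- function(radius) {
  stopifnot(radius > 0)
  avogadro <- 6.02214076e23
  vol_nm3 <- (2 / 3) * pi * radius^3
  vol_l <- vol_nm3 * 1e-24
  1 / (vol_l * avogadro)
}

#' Processivity estimate from the kinetic race
#'
#' The number of steps per processive run is approximately the ratio of
#' the effective attachment rate (`k_attach` times the binding-zone
#' occupancy) to the bound-head release rate `k_unbind` -- the two
#' channels competing in the vulnerable post-hydrolysis state.
#'
#' @param rates A [rate_constants()].
#' @param zone_occupancy Stationary probability that the head is in the
#'   binding zone.
#' @return Expected steps per run.
#' @export
processivity_estimate <- function(rates, zone_occupancy) {
  stopifnot(rates$k_unbind > 0, zone_occupancy >= 0, zone_occupancy <= 1)
  rates$k_attach * zone_occupancy / rates$k_unbind
}
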