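# Shared oracles and cached simulations for the test suite.

# physical constants used throughout
KBT <- 4.11
XI <- 6 * pi * 1e-9 * 3

# Boltzmann zone occupancy by direct quadrature over the package's
# potential (used as the stationarity oracle for the integrators)
quad_zone <- function(config, state = "one_linker", lo = 7.2, hi = 9.2,
                      n = 200001) {
  tc <- if (state == "one_linker") neckstep:::state_tethers(config)$s4
        else neckstep:::state_tethers(config)$s2
  supp <- neckstep:::support_interval(tc, config$model, config$physics)
  if (config$model$kind == "wlc")
    supp <- tc$center + c(-1, 1) * 0.999999 * tc$Lc
  g <- seq(supp[1], supp[2], length.out = n)
  d <- boltzmann_density(tc, config$model, config$physics, g)
  density_mass(g, d, lo, hi)
}

# Ensemble summaries are expensive; compute each (fixture, n, seed) once
# per test session.
.cache <- new.env(parent = emptyenv())

cached_summary <- function(name, n, seed = 42) {
  key <- sprintf("%s_%d_%d", name, n, seed)
  if (is.null(.cache[[key]])) {
    cfg <- fixture_config(name)
    .cache[[key]] <- ensemble_summary(simulate_ensemble(cfg, n, seed))
  }
  .cache[[key]]
}

cached_stationary <- function(name, sim_time = 0.01, seed = 11, ...) {
  key <- sprintf("st_%s_%g_%d", name, sim_time, seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- stationary_distribution(fixture_config(name),
                                             sim_time = sim_time,
                                             seed = seed, ...)
  }
  .cache[[key]]
}

# Monte-Carlo standard error of a zone-occupancy estimate from an
# autocorrelated trajectory, via batch means on the histogram-free
# re-simulation is overkill; use the effective-sample-size bound with the
# tether relaxation time as the correlation time.
occupancy_mc_sigma <- function(p, total_time, tau_corr) {
  n_eff <- total_time / (2 * tau_corr)
  sqrt(p * (1 - p) / n_eff)
}
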