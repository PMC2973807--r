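# Configuration serialisation, canned fixtures for the study conditions,
# and the reproducible experiment driver.  All physical quantities in the
# YAML dialect carry unit suffixes in their key names to keep unit errors
# visible.

fixture_table <- function() {
  data.frame(
    name = c("wlc07_kin1", "wlc07_dal", "wlc20_kin1", "wlc20_dal",
             "hookean_kin1", "hookean_dal", "reflecting_kin1",
             "reflecting_dal"),
    model = rep(c("wlc", "wlc", "hookean", "reflecting"), each = 2),
    Lp = c(0.7, 0.7, 2, 2, 0.7, 0.7, 0.7, 0.7),
    motor = rep(c("kinesin1", "kinesin1_DAL"), 4),
    stringsAsFactors = FALSE)
}

#' Names of the canned configurations
#'
#' Eight fixtures: the four neck-linker models (WLC with Lp 0.7 or 2 nm,
#' Hookean, Reflecting) crossed with the two motors (wild-type Kinesin-1
#' and the three-residue neck-linker-extended mutant).
#'
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() fixture_table()$name

#' Canned simulation configuration
#'
#' Returns the fully resolved [engine_config()] for one of the eight named
#' study conditions (see [fixture_names()]), at 1 mM ATP with the
#' model-specific attachment rate.
#'
#' @param name Fixture name.
#' @param ... Overrides passed on to [engine_config()].
#' @return An [engine_config()].
#' @examples
#' fixture_config("reflecting_kin1")
#' @export
fixture_config <- function(name, ...) {
  tab <- fixture_table()
  i <- match(name, tab$name)
  if (is.na(i))
    stop("unknown fixture '", name, "'; see fixture_names()")
  engine_config(motor = tab$motor[i], model = tab$model[i], Lp = tab$Lp[i],
                ...)
}

# engine_config -> plain nested list with unit-suffixed keys
config_to_list <- function(config) {
  m <- config$model
  r <- config$rates
  g <- config$geometry
  p <- config$physics
  list(
    motor = config$motor,
    model = list(kind = m$kind, n_residues = m$n_residues,
                 lc_per_residue_nm = m$lc_per_residue, Lp_nm = m$Lp,
                 kappa_pN_per_nm = m$kappa,
                 barrier_half_width_nm = m$barrier_half_width),
    rates = list(k_detach_per_s = r$k_detach,
                 k_detach_rev_per_s = r$k_detach_rev,
                 k_ATP_on_per_uM_s = r$k_ATP_on,
                 k_ATP_off_per_s = r$k_ATP_off,
                 k_hydrolysis_per_s = r$k_hydrolysis,
                 k_hydrolysis_rev_per_s = r$k_hydrolysis_rev,
                 k_attach_per_s = r$k_attach,
                 k_attach_rev_per_s = r$k_attach_rev,
                 k_unbind_per_s = r$k_unbind,
                 atp_conc_uM = r$atp_conc),
    geometry = list(site_spacing_nm = g$site_spacing,
                    zone_half_width_nm = g$zone_half_width,
                    docking_bias_nm = g$docking_bias),
    physics = list(kBT_pN_nm = p$kBT, eta_g_per_nm_s = p$eta,
                   head_radius_nm = p$head_radius),
    integrator = list(dt_ns = config$dt * 1e9,
                      max_time_s = config$max_time,
                      center_convention = config$center_convention,
                      cap_fraction = config$cap_fraction,
                      allow_rear_s4 = config$allow_rear_s4),
    ensemble = list(n_runs = config$n_runs, base_seed = config$base_seed))
}

config_from_list <- function(x) {
  m <- x$model
  model <- neck_linker_model(kind = m$kind, motor = x$motor,
                             n_residues = m$n_residues,
                             lc_per_residue = m$lc_per_residue_nm,
                             Lp = m$Lp_nm,
                             kappa = m$kappa_pN_per_nm,
                             barrier_half_width = m$barrier_half_width_nm)
  r <- x$rates
  rates <- rate_constants(model = m$kind, Lp = m$Lp_nm,
                          k_attach = r$k_attach_per_s,
                          atp_conc = r$atp_conc_uM,
                          k_detach = r$k_detach_per_s,
                          k_detach_rev = r$k_detach_rev_per_s,
                          k_ATP_on = r$k_ATP_on_per_uM_s,
                          k_ATP_off = r$k_ATP_off_per_s,
                          k_hydrolysis = r$k_hydrolysis_per_s,
                          k_hydrolysis_rev = r$k_hydrolysis_rev_per_s,
                          k_attach_rev = r$k_attach_rev_per_s,
                          k_unbind = r$k_unbind_per_s)
  engine_config(motor = x$motor, model = model, rates = rates,
                geometry = track_geometry(x$geometry$site_spacing_nm,
                                          x$geometry$zone_half_width_nm,
                                          x$geometry$docking_bias_nm),
                physics = physics_constants(x$physics$kBT_pN_nm,
                                            x$physics$eta_g_per_nm_s,
                                            x$physics$head_radius_nm),
                dt = x$integrator$dt_ns * 1e-9,
                center_convention = x$integrator$center_convention,
                max_time = x$integrator$max_time_s,
                cap_fraction = x$integrator$cap_fraction,
                allow_rear_s4 = x$integrator$allow_rear_s4,
                n_runs = x$ensemble$n_runs,
                base_seed = x$ensemble$base_seed)
}

# recursively check that `x` introduces no keys absent from `ref`
check_unknown_keys <- function(x, ref, path = "") {
  bad <- setdiff(names(x), names(ref))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "))
  for (k in names(x)) {
    if (is.list(ref[[k]]) && is.list(x[[k]]))
      check_unknown_keys(x[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Write a configuration to YAML
#'
#' @param config An [engine_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "engine_config"))
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' Load a configuration from YAML
#'
#' Reads a configuration written by [write_config()] (or hand-edited in
#' the same dialect), applies defaults for missing sub-keys, rejects
#' unknown keys, and validates the time step against the fastest chemical
#' channel.  `load_config(write_config(cfg))` reproduces `cfg`.
#'
#' @param path YAML file.
#' @return An [engine_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  x <- yaml::read_yaml(path)
  if (!is.list(x) || is.null(x$motor))
    stop("not a simulation config (missing 'motor'): ", path)
  template <- config_to_list(engine_config(
    motor = x$motor,
    model = if (!is.null(x$model$kind)) x$model$kind else "wlc"))
  check_unknown_keys(x, template)
  merged <- utils::modifyList(template, x)
  config_from_list(merged)
}

#' Run a reproducible ensemble experiment
#'
#' Simulates the configured ensemble and writes a self-contained results
#' directory: the resolved config snapshot (`config.yaml`), one TSV event
#' log per run (`run_###.tsv`: time_s, state, x_nm, step_nm), an ensemble
#' `summary.json`, and a plain-text `manifest.txt` with seeds, package
#' version and wall time.  Summaries are a deterministic function of
#' (config, seed): rerunning with the same inputs reproduces
#' `summary.json` byte for byte.
#'
#' @param config An [engine_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_runs,base_seed Optional overrides of the configured ensemble.
#' @param write_run_logs Write the per-run TSV event logs (default TRUE).
#' @return The manifest as a named list, invisibly.
#' @export
run_experiment <- function(config, out_dir, n_runs = config$n_runs,
                           base_seed = config$base_seed,
                           write_run_logs = TRUE) {
  stopifnot(inherits(config, "engine_config"), n_runs >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir)
  t0 <- proc.time()[["elapsed"]]
  config$n_runs <- as.integer(n_runs)
  config$base_seed <- as.integer(base_seed)
  write_config(config, file.path(out_dir, "config.yaml"))
  ens <- simulate_ensemble(config, n_runs, base_seed,
                           record_events = write_run_logs)
  if (write_run_logs) {
    for (i in seq_len(n_runs)) {
      ev <- ens$runs[[i]]$events
      names(ev) <- c("time_s", "state", "x_nm", "step_nm")
      utils::write.table(
        format(ev, digits = 10, trim = TRUE, scientific = FALSE),
        file.path(out_dir, sprintf("run_%03d.tsv", i)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  s <- ensemble_summary(ens)
  summ <- list(motor = config$motor, model = config$model$kind,
               n_runs = s$n_runs,
               velocity_mean = s$velocity_mean,
               velocity_sem = s$velocity_sem,
               runlength_mean = s$runlength_mean,
               runlength_sem = s$runlength_sem,
               detach_per_step = s$detach_per_step,
               backward_fraction = s$backward_fraction,
               base_seed = base_seed)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cap_hits <- sum(vapply(ens$runs, function(r) r$cap_hits, numeric(1)))
  manifest <- c(
    package = "neckstep",
    version = as.character(utils::packageVersion("neckstep")),
    motor = config$motor, model = config$model$kind,
    n_runs = n_runs, base_seed = base_seed,
    summary_md5 = unname(tools::md5sum(file.path(out_dir, "summary.json"))),
    cap_hits = cap_hits,
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 2))
  writeLines(paste(names(manifest), manifest, sep = ": "),
             file.path(out_dir, "manifest.txt"))
  invisible(as.list(manifest))
}
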