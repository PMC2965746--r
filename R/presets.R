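# Named scenario presets reproducing the package's reference simulations.
# Each preset is a full crisprdyn_config whose provenance notes flag which
# values define the scenario and which are shared defaults.

.preset_cache <- new.env(parent = emptyenv())

#' Names of the bundled scenario presets
#'
#' `fig4a`-`fig4d` and `fig5a`-`fig5b` are phage-model invasion scenarios
#' (no CRISPR; CRISPR invasion with no/strong/modest MOI effect; CRISPR plus
#' envelope resistance at modest/high cost). `fig6a1`-`fig6a3`, `fig6b`,
#' `fig6c`, `fig6d` are plasmid-model scenarios (plasmid invasion without
#' CRISPR at three transfer rates; plasmid invading a CRISPR resident;
#' immune-CRISPR invading a plasmid-bearing resident; a beneficial plasmid).
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() {
  c("fig4a", "fig4b", "fig4c", "fig4d", "fig5a", "fig5b",
    "fig6a1", "fig6a2", "fig6a3", "fig6b", "fig6c", "fig6d")
}

default_integration <- function(t_end) {
  list(t_end = t_end, report_dt = 0.5, rtol = 1e-8, atol = 1e-10,
       method = "lsoda")
}

# shared habitat of every scenario
preset_env <- function() list(A = 50, w = 0.2, k = 0.25, e = 5e-7,
                              refuge_density = 100,
                              phage_extinction_threshold = 0.1)

env_provenance <- c(
  "env.A" = "scenario value (shared across all presets)",
  "env.w" = "scenario value (shared across all presets)",
  "env.k" = "scenario value (shared across all presets)",
  "env.e" = "scenario value (shared across all presets)",
  "env.refuge_density" = "default (value not fixed by the scenarios)",
  "env.phage_extinction_threshold" = "scenario value (phage-loss rule)")

make_config <- function(model, params, initial, t_end, provenance) {
  structure(
    list(model = model, env = preset_env(),
         params = unclass(params), initial = as.list(initial),
         integration = default_integration(t_end),
         provenance = c(env_provenance, provenance)),
    class = "crisprdyn_config")
}

phage_preset <- function(param_overrides, initial, scenario_keys, t_end = 500) {
  params <- do.call(phage_params, param_overrides)
  prov <- c(
    stats::setNames(rep("scenario value", length(scenario_keys)),
                    paste0("params.", scenario_keys)),
    stats::setNames(rep("default (unprinted in the scenario)",
                        length(setdiff(names(unclass(params)), scenario_keys))),
                    paste0("params.",
                           setdiff(names(unclass(params)), scenario_keys))),
    stats::setNames(rep("default invasion initial condition",
                        length(initial)), paste0("initial.", names(initial))))
  make_config("phage", params, initial, t_end, prov)
}

plasmid_preset <- function(param_overrides, initial, scenario_keys, t_end = 2000) {
  params <- do.call(plasmid_params, param_overrides)
  prov <- c(
    stats::setNames(rep("scenario value", length(scenario_keys)),
                    paste0("params.", scenario_keys)),
    stats::setNames(rep("default (unprinted in the scenario)",
                        length(setdiff(names(unclass(params)), scenario_keys))),
                    paste0("params.",
                           setdiff(names(unclass(params)), scenario_keys))),
    stats::setNames(rep("default invasion initial condition",
                        length(initial)), paste0("initial.", names(initial))))
  make_config("plasmid", params, initial, t_end, prov)
}

# Resident N-N_P coexistence state for the immune-invasion scenario: no
# closed form, so it is obtained once by a deterministic burn-in of the
# plasmid model without CRISPR classes.
resident_plasmid_equilibrium <- function() {
  if (!is.null(.preset_cache$nnp_eq)) return(.preset_cache$nnp_eq)
  env <- do.call(chemostat_env, preset_env())
  params <- plasmid_params()  # deleterious plasmid, all gammas 1e-9
  init <- plasmid_state(N = bacterial_equilibrium(env, params$V_N),
                        N_P = 1e3,
                        R = resource_equilibrium(params$V_N, env$k, env$w))
  tr <- simulate_plasmid(params, env, init, t_end = 3000, report_dt = 5)
  .preset_cache$nnp_eq <- tr$state[nrow(tr$state), ]
  .preset_cache$nnp_eq
}

#' Retrieve a scenario preset as a configuration
#'
#' Builds the full configuration (habitat, parameters, initial state,
#' integration settings) for one named scenario; see [preset_names()]. The
#' provenance notes in the serialized form ([write_config()]) distinguish
#' scenario-defining values from defaults. Initial densities follow the
#' invasion convention: resident population(s) at their analytic chemostat
#' equilibrium, invaders at 1e3 cells/ml, phage (where present) at 1e4
#' particles/ml.
#'
#' @param name One of [preset_names()].
#' @return A `crisprdyn_config`.
#' @examples
#' preset("fig4a")
#' @export
preset <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% preset_names())
    stop(config_error(sprintf(
      "unknown preset '%s'; see preset_names()", paste(name, collapse = ","))))

  env <- do.call(chemostat_env, preset_env())
  Nstar <- bacterial_equilibrium(env, 1.0)
  Rstar <- resource_equilibrium(1.0, env$k, env$w)

  phage_inv <- function(...) {  # resident N + phage, listed invaders
    s <- phage_state(N = Nstar, P = 1e4, R = Rstar)
    extra <- c(...)
    s[names(extra)] <- extra
    s
  }

  switch(name,
    fig4a = phage_preset(
      list(V_N = 1.0, delta_N = 5e-9, mu = 0, m = 0),
      phage_inv(),
      c("V_N", "delta_N", "mu", "m")),
    fig4b = phage_preset(
      list(V_N = 1.0, V_C = 0.95, V_CR = 0.90, delta_N = 5e-9, delta_C = 5e-9,
           delta_MIN = 1e-14, delta_MAX = 5e-9, x = 0, mu = 0),
      phage_inv(C = 1e3),
      c("V_N", "V_C", "V_CR", "delta_N", "delta_C", "delta_MIN", "delta_MAX",
        "x", "mu")),
    fig4c = phage_preset(
      list(V_N = 1.0, V_C = 0.95, V_CR = 0.90, delta_N = 5e-9, delta_C = 5e-9,
           delta_MIN = 1e-14, delta_MAX = 5e-9, x = 0.5, n = 2, q = 1e2, mu = 0),
      phage_inv(C = 1e3),
      c("V_N", "V_C", "V_CR", "delta_N", "delta_C", "delta_MIN", "delta_MAX",
        "x", "n", "q", "mu")),
    fig4d = phage_preset(
      list(V_N = 1.0, V_C = 0.95, V_CR = 0.90, delta_N = 5e-9, delta_C = 5e-9,
           delta_MIN = 1e-14, delta_MAX = 5e-9, x = 0.2, n = 2, q = 1e2, mu = 0),
      phage_inv(C = 1e3),
      c("V_N", "V_C", "V_CR", "delta_N", "delta_C", "delta_MIN", "delta_MAX",
        "x", "n", "q", "mu")),
    fig5a = phage_preset(
      list(V_N = 1.0, V_NR = 0.85, V_C = 0.95, V_CR = 0.90,
           delta_N = 5e-9, delta_C = 5e-9, delta_MIN = 1e-14, delta_MAX = 5e-9,
           x = 0.2, n = 2, q = 1e2),
      phage_inv(C = 1e3, N_R = 1e3),
      c("V_N", "V_NR", "V_C", "V_CR", "delta_N", "delta_C", "delta_MIN",
        "delta_MAX", "x", "n", "q")),
    fig5b = phage_preset(
      list(V_N = 1.0, V_NR = 0.70, V_C = 0.95, V_CR = 0.90,
           delta_N = 5e-9, delta_C = 5e-9, delta_MIN = 1e-14, delta_MAX = 5e-9,
           x = 0.2, n = 2, q = 1e2),
      phage_inv(C = 1e3, N_R = 1e3),
      c("V_N", "V_NR", "V_C", "V_CR", "delta_N", "delta_C", "delta_MIN",
        "delta_MAX", "x", "n", "q")),
    fig6a1 = plasmid_preset(
      list(V_N = 1.0, V_NP = 0.95),
      plasmid_state(N = Nstar, N_P = 1e3, R = Rstar),
      c("V_N", "V_NP", "gamma_NN", "gamma_NC", "gamma_CN", "gamma_CC",
        "tau_N", "tau_C", "v", "m", "z")),
    fig6a2 = plasmid_preset(
      list(V_N = 1.0, V_NP = 1.2),
      plasmid_state(N = Nstar, N_P = 1e3, R = Rstar),
      c("V_N", "V_NP", "gamma_NN", "gamma_NC", "gamma_CN", "gamma_CC",
        "tau_N", "tau_C", "v", "m", "z")),
    fig6a3 = plasmid_preset(
      list(V_N = 1.0, V_NP = 0.95, gamma_NN = 1e-11),
      plasmid_state(N = Nstar, N_P = 1e3, R = Rstar),
      c("V_N", "V_NP", "gamma_NN", "gamma_NC", "gamma_CN", "gamma_CC",
        "tau_N", "tau_C", "v", "m", "z")),
    fig6b = plasmid_preset(
      list(V_N = 1.0, V_NP = 0.95, V_C = 0.97, V_CP = 0.88, V_X = 0.96),
      plasmid_state(C = bacterial_equilibrium(env, 0.97), N_P = 1e3,
                    R = resource_equilibrium(0.97, env$k, env$w)),
      c("V_N", "V_NP", "V_C", "V_CP", "V_X", "gamma_NN", "gamma_NC",
        "gamma_CN", "gamma_CC", "tau_N", "tau_C", "v", "m", "z")),
    fig6c = {
      eq <- resident_plasmid_equilibrium()
      plasmid_preset(
        list(V_N = 1.0, V_NP = 0.95, V_C = 0.97, V_CP = 0.88, V_X = 0.96),
        plasmid_state(N = eq[["N"]], N_P = eq[["N_P"]], C_X = 1e3,
                      R = eq[["R"]]),
        c("V_N", "V_NP", "V_C", "V_CP", "V_X", "gamma_NN", "gamma_NC",
          "gamma_CN", "gamma_CC", "tau_N", "tau_C", "v", "m", "z"))
    },
    fig6d = plasmid_preset(
      list(V_N = 1.0, V_NP = 1.2, V_C = 0.97, V_CP = 1.1, V_X = 0.96),
      plasmid_state(C = bacterial_equilibrium(env, 0.97), N_P = 1e3,
                    R = resource_equilibrium(0.97, env$k, env$w)),
      c("V_N", "V_NP", "V_C", "V_CP", "V_X", "gamma_NN", "gamma_NC",
        "gamma_CN", "gamma_CC", "tau_N", "tau_C", "v", "m", "z"))
  )
}

#' Run a scenario preset
#'
#' Builds the preset configuration, applies overrides, integrates the model,
#' classifies the ecological outcome, and (optionally) writes the run
#' artifacts to a directory: `config.txt` (configuration echo with
#' provenance), `timeseries.csv` (one row per reporting time), `summary.json`
#' (the [classify_outcome()] summary), and `run.log`.
#'
#' @param name One of [preset_names()].
#' @param overrides Named list of configuration overrides; keys may be bare
#'   (`delta_N`) when unambiguous or qualified (`params.delta_N`,
#'   `integration.t_end`).
#' @param out_dir Optional output directory (created if needed).
#' @param classify_settings Optional named list passed to
#'   [classify_outcome()] (`window_frac`, `persistence_floor`,
#'   `limitation_fraction`).
#' @return A list with `trajectory` (`crispr_trajectory`), `outcome`
#'   (`outcome_summary`), and `config` (`crisprdyn_config`).
#' @examples
#' \donttest{
#' res <- run_preset("fig4a", overrides = list(t_end = 100))
#' res$outcome
#' }
#' @export
run_preset <- function(name, overrides = list(), out_dir = NULL,
                       classify_settings = list()) {
  cfg <- apply_overrides(preset(name), overrides)
  obj <- config_objects(cfg)
  it <- obj$integration
  sim <- if (cfg$model == "phage") simulate_phage else simulate_plasmid
  traj <- sim(obj$params, obj$env, obj$initial, t_end = it$t_end,
              report_dt = it$report_dt, rtol = it$rtol, atol = it$atol,
              method = it$method)
  outcome <- do.call(classify_outcome, c(list(traj), classify_settings))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(cfg, file.path(out_dir, "config.txt"))
    write_trajectory(traj, file.path(out_dir, "timeseries.csv"))
    jsonlite::write_json(outcome_to_list(outcome),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("preset: %s (model: %s)", name, cfg$model),
      sprintf("solver: %s, rtol=%g, atol=%g, report_dt=%g hr",
              it$method, it$rtol, it$atol, it$report_dt),
      sprintf("integrated over [0, %g] hr; %d reported states",
              it$t_end, length(traj$time)),
      if (nrow(traj$events) > 0)
        sprintf("event: %s at t=%g hr", traj$events$event, traj$events$time)
      else "events: none",
      sprintf("outcome: regime=%s dominant=%s", outcome$regime,
              outcome$dominant)),
      file.path(out_dir, "run.log"))
  }
  list(trajectory = traj, outcome = outcome, config = cfg)
}
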