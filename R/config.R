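.config_defaults <- function() {
  list(
    # scheme: group-based twin-range, 0.8/1.4 nm, pairlist every 10 fs
    solute_rule = "group", solvent_rule = "group", center_rule = "cog",
    designated_atom = "OW", r_short = 0.8, r_long = 1.4, update_interval = 5L,
    # protocol
    timestep = 0.002, n_steps = 1000L,
    t_ref_solute = 298.15, t_ref_solvent = 298.15, tau_t = 0.1,
    thermostat = TRUE, p_ref = .atm_kj, tau_p = 0.5,
    compressibility = 4.575e-4, pressure_coupling = FALSE,
    eps_rf = 61, shake_tol = 1e-4,
    log_interval = 1L, output_interval = 0L, seed = 1L,
    # io
    output_prefix = "run")
}

#' Parse and write run configurations
#'
#' YAML run configuration with study-condition defaults: a group-based
#' twin-range scheme (0.8 / 1.4 nm, pairlist update every 5 steps = 10 fs at
#' 2 fs steps), weak coupling to 298.15 K (tau 0.1 ps) and 1 atm (tau 0.5 ps,
#' compressibility 4.575e-4 (kJ mol^-1 nm^-3)^-1), reaction-field dielectric
#' 61 and SHAKE tolerance 1e-4.  An empty file yields the full default
#' configuration; unknown keys and out-of-range values are rejected.
#' `parse_config(write_config(cfg, p))` is the identity.
#'
#' @param path Config file.
#' @return A validated named list of class `run_config`.
#' @export
parse_config <- function(path) {
  raw <- if (file.exists(path) && file.size(path) > 0) yaml::read_yaml(path)
         else list()
  if (is.null(raw)) raw <- list()
  defs <- .config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- defs
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

#' @rdname parse_config
#' @param config A `run_config` (or plain list of its fields).
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname parse_config
#' @export
validate_config <- function(config) {
  cfg <- unclass(config)
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$solute_rule %in% c("group", "atomistic"), "solute_rule must be 'group' or 'atomistic'")
  chk(cfg$solvent_rule %in% c("group", "atomistic"), "solvent_rule must be 'group' or 'atomistic'")
  chk(cfg$center_rule %in% c("cog", "atom"), "center_rule must be 'cog' or 'atom'")
  chk(cfg$r_short > 0, "r_short must be positive")
  chk(cfg$r_short <= cfg$r_long, "r_short must not exceed r_long")
  chk(cfg$update_interval >= 1, "update_interval must be >= 1")
  chk(cfg$timestep > 0, "timestep must be positive")
  chk(cfg$tau_t >= cfg$timestep, "tau_t must be at least one timestep")
  chk(cfg$shake_tol > 0, "shake_tol must be positive")
  chk(cfg$eps_rf >= 1, "eps_rf must be >= 1")
  chk(cfg$n_steps >= 1, "n_steps must be >= 1")
  cfg$update_interval <- as.integer(cfg$update_interval)
  cfg$n_steps <- as.integer(cfg$n_steps)
  cfg$log_interval <- as.integer(cfg$log_interval)
  cfg$output_interval <- as.integer(cfg$output_interval)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  single <- x$update_interval == 1L || x$r_short == x$r_long
  cat(sprintf("<run_config> %s/%s scheme (%s), R %g/%g nm, %s pairlist\n",
              x$solute_rule, x$solvent_rule, x$center_rule, x$r_short,
              x$r_long, if (single) "single-range" else "twin-range"))
  cat(sprintf("  dt %g ps x %d steps, T %g/%g K (tau %g ps), eps_rf %g, seed %d\n",
              x$timestep, x$n_steps, x$t_ref_solute, x$t_ref_solvent, x$tau_t,
              x$eps_rf, x$seed))
  invisible(x)
}

#' @rdname parse_config
#' @export
config_scheme <- function(config) {
  cutoff_scheme(config$solute_rule, config$solvent_rule, config$center_rule,
                config$designated_atom, config$r_short, config$r_long,
                config$update_interval)
}

#' @rdname parse_config
#' @export
config_protocol <- function(config) {
  md_protocol(timestep = config$timestep, n_steps = config$n_steps,
              t_ref_solute = config$t_ref_solute,
              t_ref_solvent = config$t_ref_solvent, tau_t = config$tau_t,
              thermostat = config$thermostat, p_ref = config$p_ref,
              tau_p = config$tau_p, compressibility = config$compressibility,
              pressure_coupling = config$pressure_coupling,
              eps_rf = config$eps_rf, shake_tol = config$shake_tol,
              log_interval = config$log_interval,
              output_interval = config$output_interval, seed = config$seed)
}
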