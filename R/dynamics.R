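#' Simulation protocol
#'
#' Integration and coupling settings.  Defaults mirror the study conditions:
#' 2 fs leapfrog steps, SHAKE relative tolerance 1e-4, separate solute and
#' solvent weak-coupling baths at 298.15 K with relaxation time 0.1 ps, and
#' (when enabled) weak-coupling pressure scaling to 1 atm with relaxation time
#' 0.5 ps and isothermal compressibility 4.575e-4 (kJ mol^-1 nm^-3)^-1
#' (7.51e-4 for pure water).
#'
#' @param timestep Integration step, ps.
#' @param n_steps Number of steps.
#' @param t_ref_solute,t_ref_solvent Bath reference temperatures, K.
#' @param tau_t Temperature relaxation time, ps (>= timestep).
#' @param thermostat Logical, couple to the baths?
#' @param p_ref Reference pressure, kJ mol^-1 nm^-3 (1 atm = 0.0610194).
#' @param tau_p Pressure relaxation time, ps.
#' @param compressibility Isothermal compressibility, (kJ mol^-1 nm^-3)^-1.
#' @param pressure_coupling Logical, isotropic weak-coupling barostat?
#' @param eps_rf Reaction-field dielectric constant.
#' @param shake_tol SHAKE relative tolerance on squared distances.
#' @param log_interval Energy-log cadence, steps.
#' @param output_interval Trajectory-frame cadence, steps (0 = no frames).
#' @param seed Integer seed recorded with the run.
#' @return Object of class `md_protocol`.
#' @export
md_protocol <- function(timestep = 0.002, n_steps = 1000L,
                        t_ref_solute = 298.15, t_ref_solvent = 298.15,
                        tau_t = 0.1, thermostat = TRUE,
                        p_ref = .atm_kj, tau_p = 0.5,
                        compressibility = 4.575e-4, pressure_coupling = FALSE,
                        eps_rf = 61, shake_tol = 1e-4,
                        log_interval = 1L, output_interval = 0L, seed = 1L) {
  stopifnot(timestep > 0, n_steps >= 1, tau_t >= timestep, shake_tol > 0,
            tau_p > 0, log_interval >= 1)
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 t_ref_solute = t_ref_solute, t_ref_solvent = t_ref_solvent,
                 tau_t = tau_t, thermostat = thermostat,
                 p_ref = p_ref, tau_p = tau_p,
                 compressibility = compressibility,
                 pressure_coupling = pressure_coupling,
                 eps_rf = eps_rf, shake_tol = shake_tol,
                 log_interval = as.integer(log_interval),
                 output_interval = as.integer(output_interval),
                 seed = as.integer(seed)),
            class = "md_protocol")
}

#' Leapfrog integration step
#'
#' `v(t + dt/2) = v(t - dt/2) + F/m dt`, then `r(t + dt) = r(t) + v dt`.
#' No constraint enforcement here (see [shake()]).
#'
#' @param positions,velocities N x 3 matrices.
#' @param forces N x 3, kJ mol^-1 nm^-1.
#' @param masses Length-N, u.
#' @param timestep ps.
#' @return List with updated `positions` and `velocities`.
#' @export
leapfrog_step <- function(positions, velocities, forces, masses, timestep) {
  velocities <- velocities + forces * (timestep / masses)
  positions <- positions + velocities * timestep
  list(positions = positions, velocities = velocities)
}

#' SHAKE constraint correction
#'
#' Iteratively displaces atoms along the reference bond directions until every
#' constraint satisfies `|d^2 - d0^2| / d0^2 <= tolerance`.
#'
#' @param positions_new Post-integration positions (to be corrected).
#' @param positions_ref Pre-integration reference positions.
#' @param constraints 3-column `(i, j, d0)` matrix (1-based).
#' @param tolerance Relative tolerance.
#' @param masses Atomic masses, u.
#' @param max_iter Iteration cap; exceeding it aborts with diagnostics.
#' @return List: corrected `positions`, `iterations`, `max_rel_dev`.
#' @export
shake <- function(positions_new, positions_ref, constraints, tolerance = 1e-4,
                  masses, max_iter = 500L) {
  if (nrow(constraints) == 0)
    return(list(positions = positions_new, iterations = 0L, max_rel_dev = 0))
  res <- cpp_shake(positions_new, positions_ref,
                   as.integer(constraints[, 1]) - 1L,
                   as.integer(constraints[, 2]) - 1L,
                   constraints[, 3], 1 / masses, tolerance, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("SHAKE failed to converge in %d iterations (max relative deviation %.3e)",
                 max_iter, res$max_rel_dev))
  list(positions = res$positions, iterations = res$iterations,
       max_rel_dev = res$max_rel_dev)
}

#' Instantaneous bath temperature
#'
#' `T = 2 E_kin / (dof k_B)`.
#'
#' @param kinetic_energy kJ/mol.
#' @param dof Degrees of freedom in the bath.
#' @return Temperature, K.
#' @export
bath_temperature <- function(kinetic_energy, dof) {
  if (any(dof <= 0)) stop("dof must be positive")
  2 * kinetic_energy / (dof * .k_boltz)
}

#' Weak-coupling temperature scaling factor
#'
#' `lambda = sqrt(1 + (dt / tau_T) (T_ref / T - 1))`, applied per bath to that
#' bath's velocities.  One application moves the temperature to
#' `T + (dt / tau_T)(T_ref - T)`.
#'
#' @param t_inst Instantaneous bath temperature, K (> 0; at exactly 0 no
#'   scaling is possible and 1 is returned).
#' @param t_ref Reference temperature, K.
#' @param timestep,tau_t ps.
#' @return Velocity scaling factor.
#' @export
weak_coupling_t_scale <- function(t_inst, t_ref, timestep, tau_t) {
  if (t_inst <= 0) return(1)
  sqrt(1 + (timestep / tau_t) * (t_ref / t_inst - 1))
}

#' Weak-coupling pressure scaling factor
#'
#' `mu = (1 - kappa_T (dt / tau_P) (P_ref - P))^(1/3)`; box edges and all
#' coordinates are scaled isotropically by `mu`.  Values outside [0.9, 1.1]
#' (a pathological pressure spike) are clamped with a warning.
#'
#' @param p_inst,p_ref kJ mol^-1 nm^-3.
#' @param timestep,tau_p ps.
#' @param kappa_t Isothermal compressibility, (kJ mol^-1 nm^-3)^-1.
#' @return Linear scaling factor for box and coordinates.
#' @export
weak_coupling_p_scale <- function(p_inst, p_ref, timestep, tau_p, kappa_t) {
  mu <- (1 - kappa_t * (timestep / tau_p) * (p_ref - p_inst))^(1 / 3)
  if (!is.finite(mu) || mu < 0.9 || mu > 1.1) {
    warning(sprintf("pathological pressure scaling factor %.4f clamped", mu))
    mu <- min(max(mu, 0.9), 1.1)
  }
  mu
}

#' Instantaneous pressure
#'
#' `P = (2/3) (E_kin - Xi) / V` with `Xi = -1/2 sum r_ij . F_ij` the
#' accumulated pair virial.  For an ideal gas (`Xi = 0`) this reduces to
#' `P V = (2/3) E_kin = N k_B T`.
#'
#' @param kinetic_energy kJ/mol.
#' @param virial Xi, kJ/mol.
#' @param volume nm^3.
#' @return Pressure, kJ mol^-1 nm^-3.
#' @export
compute_pressure <- function(kinetic_energy, virial, volume) {
  stopifnot(volume > 0)
  (2 / 3) * (kinetic_energy - virial) / volume
}

#' Degrees of freedom per temperature bath
#'
#' `3 N_atoms(bath) - N_constraints(bath)` for the solute and solvent baths.
#' Centre-of-mass motion removal is off (no roto-translational constraints at
#' desk scale), so no global reduction applies.
#'
#' @param system An [md_system()].
#' @return Named numeric vector with `solute` and `solvent` counts.
#' @export
bath_dof <- function(system) {
  sol <- system$subsystem == "solute"
  csol <- if (nrow(system$constraints)) sol[system$constraints[, 1]] else logical(0)
  c(solute = 3 * sum(sol) - sum(csol),
    solvent = 3 * sum(!sol) - sum(!csol))
}

.bath_kinetic <- function(velocities, masses, solute_mask) {
  ke <- 0.5 * masses * rowSums(velocities^2)
  c(solute = sum(ke[solute_mask]), solvent = sum(ke[!solute_mask]))
}

#' Run a molecular dynamics simulation
#'
#' The driver loop: pairlist update when due (recomputing the cached
#' intermediate-range contribution), short-range nonbonded forces plus frozen
#' cache, leapfrog, SHAKE (with velocity correction), per-bath weak-coupling
#' thermostat and optional isotropic barostat.  Energies are logged before
#' integration at time `t = step * dt` with the kinetic energy taken from the
#' on-step average `(v(t - dt/2) + v(t + dt/2)) / 2`; the thermostat uses the
#' post-SHAKE half-step velocities it actually rescales.  Fully reproducible
#' for a fixed starting state.
#'
#' @param system [md_system()] (velocities as prepared, e.g. by
#'   [assign_maxwell_velocities()]).
#' @param scheme [cutoff_scheme()].
#' @param protocol [md_protocol()].
#' @return Object of class `md_run`: final `system`, `energy` log data frame,
#'   `trajectory` (list of frames with `step`, `time`, `positions`, `box`),
#'   `scheme`, `protocol`, per-bath `dof`, and `max_constraint_dev`.
#' @export
run_simulation <- function(system, scheme, protocol) {
  dt <- protocol$timestep
  n <- protocol$n_steps
  params <- rf_params(protocol$eps_rf, scheme$r_long)
  ent <- make_entities(system, scheme)
  if (any(system$box < 2 * scheme$r_long))
    stop("box smaller than twice the long-range cutoff")
  pos <- system$positions
  vel <- system$velocities
  box <- system$box
  masses <- system$masses
  sol_mask <- system$subsystem == "solute"
  dof <- bath_dof(system)
  has_solute <- dof[["solute"]] > 0
  has_solvent <- dof[["solvent"]] > 0
  cons <- system$constraints
  plist <- NULL
  # packed per-atom arrays for the C++ kernels, built once
  ljt0 <- .lj_type_int(system)
  sub0 <- .subsys_int(system)
  excl0 <- system$exclusions - 1L
  # single-range limit: classification and evaluation fused in one kernel
  # call (bit-identical to building the canonical pairlist first); fully
  # atomistic entity sets take the flattened single-loop kernel
  fast_sr <- scheme$r_short == scheme$r_long && scheme$update_interval == 1L
  all_atomistic <- all(diff(ent$ptr) == 1L)
  nlog <- length(seq(0L, n - 1L, by = protocol$log_interval))
  log <- matrix(NA_real_, nlog, 18)
  colnames(log) <- c("step", "time", "e_el_ss", "e_el_sv", "e_el_vv",
                     "e_lj_ss", "e_lj_sv", "e_lj_vv", "e_pot",
                     "e_kin_solute", "e_kin_solvent", "t_solute", "t_solvent",
                     "virial", "pressure", "volume", "e_tot", "constraint_dev")
  frames <- list()
  ilog <- 0L
  max_dev <- 0
  for (s in seq_len(n)) {
    step0 <- s - 1L
    if (fast_sr) {
      raw <- if (all_atomistic)
        cpp_sr_nonbonded_atomistic(pos, system$charges, ljt0, system$lj$c6,
                                   system$lj$c12, sub0, system$molecule_id,
                                   box, scheme$r_long, params$c_rf,
                                   params$r_rf, .f_elec, excl0)
      else
        cpp_sr_nonbonded(pos, ent$ptr, ent$atoms, ent$center_atom,
                         system$charges, ljt0, system$lj$c6,
                         system$lj$c12, sub0, system$molecule_id, box,
                         scheme$r_long, params$c_rf, params$r_rf,
                         .f_elec, excl0)
      nb <- list(energy = .decomp(raw$e_el, raw$e_lj), forces = raw$forces,
                 virial = raw$virial)
    } else {
      if (is.null(plist) || pairlist_due_for_update(step0, scheme)) {
        plist <- build_pairlist(ent, pos, box, scheme)
        plist$cache <- NULL
      }
      sys_box <- system; sys_box$box <- box
      nb <- compute_nonbonded(sys_box, plist, scheme, params, step = step0,
                              entities = ent, positions = pos)
      plist <- nb$pairs
    }
    forces <- nb$forces
    epot <- nb$energy$total
    vold <- vel
    stepres <- leapfrog_step(pos, vel, forces, masses, dt)
    posnew <- stepres$positions
    vel <- stepres$velocities
    dev <- 0
    if (nrow(cons) > 0) {
      sh <- shake(posnew, pos, cons, protocol$shake_tol, masses)
      vel <- vel + (sh$positions - posnew) / dt
      posnew <- sh$positions
      dev <- sh$max_rel_dev
      max_dev <- max(max_dev, dev)
    }
    vavg <- 0.5 * (vold + vel)
    ek_avg <- .bath_kinetic(vavg, masses, sol_mask)
    ek_half <- .bath_kinetic(vel, masses, sol_mask)
    press <- compute_pressure(sum(ek_avg), nb$virial, prod(box))
    if (step0 %% protocol$log_interval == 0L) {
      ilog <- ilog + 1L
      log[ilog, ] <- c(step0, step0 * dt, nb$energy$electrostatic,
                       nb$energy$lj, epot, ek_avg["solute"], ek_avg["solvent"],
                       if (has_solute) bath_temperature(ek_avg[["solute"]], dof[["solute"]]) else NA,
                       if (has_solvent) bath_temperature(ek_avg[["solvent"]], dof[["solvent"]]) else NA,
                       nb$virial, press, prod(box), epot + sum(ek_avg), dev)
    }
    if (protocol$output_interval > 0 && step0 %% protocol$output_interval == 0L) {
      frames[[length(frames) + 1L]] <-
        list(step = step0, time = step0 * dt, positions = pos, box = box)
    }
    if (protocol$thermostat) {
      if (has_solute) {
        lam <- weak_coupling_t_scale(
          bath_temperature(ek_half[["solute"]], dof[["solute"]]),
          protocol$t_ref_solute, dt, protocol$tau_t)
        vel[sol_mask, ] <- vel[sol_mask, ] * lam
      }
      if (has_solvent) {
        lam <- weak_coupling_t_scale(
          bath_temperature(ek_half[["solvent"]], dof[["solvent"]]),
          protocol$t_ref_solvent, dt, protocol$tau_t)
        vel[!sol_mask, ] <- vel[!sol_mask, ] * lam
      }
    }
    if (protocol$pressure_coupling) {
      mu <- weak_coupling_p_scale(press, protocol$p_ref, dt, protocol$tau_p,
                                  protocol$compressibility)
      box <- box * mu
      posnew <- posnew * mu
      if (any(box < 2 * scheme$r_long))
        stop("pressure coupling shrank the box below twice the long-range cutoff")
    }
    pos <- posnew
  }
  system$positions <- pos
  system$velocities <- vel
  system$box <- box
  structure(list(system = system, energy = as.data.frame(log),
                 trajectory = frames, scheme = scheme, protocol = protocol,
                 dof = dof, max_constraint_dev = max_dev),
            class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  cat(sprintf("<md_run> %d steps of %.4g ps (%g ps), %d frames, %d log rows\n",
              x$protocol$n_steps, x$protocol$timestep,
              x$protocol$n_steps * x$protocol$timestep,
              length(x$trajectory), nrow(x$energy)))
  tl <- tail(x$energy, 1)
  cat(sprintf("  final: E_pot %.3f, T_solvent %.2f K, max constraint dev %.2e\n",
              tl$e_pot, tl$t_solvent, x$max_constraint_dev))
  invisible(x)
}
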