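#' Reaction-field constant
#'
#' For a homogeneous dielectric continuum of relative permittivity `eps_rf`
#' beyond the cutoff (zero ionic strength, unit dielectric inside),
#' `C_rf = 2 (eps_rf - 1) / (2 eps_rf + 1)`.  This is the choice that makes
#' the pair energy vanish exactly at the cutoff distance.
#'
#' @param eps_rf Relative dielectric constant of the reaction field (>= 1).
#' @return Dimensionless constant in `[0, 1)`.
#' @examples
#' rf_constant(61)  # 120/123
#' @export
rf_constant <- function(eps_rf) {
  if (any(eps_rf < 1)) stop("eps_rf must be >= 1")
  2 * (eps_rf - 1) / (2 * eps_rf + 1)
}

#' Reaction-field parameter set
#'
#' @param eps_rf Reaction-field dielectric constant (61 for the protein-type
#'   setting, 78 for pure water).
#' @param r_rf Reaction-field cutoff distance R_rf, nm (the long-range cutoff).
#' @return List with `eps_rf`, `c_rf` and `r_rf`, class `rf_params`.
#' @export
rf_params <- function(eps_rf = 61, r_rf = 1.4) {
  stopifnot(r_rf > 0)
  structure(list(eps_rf = eps_rf, c_rf = rf_constant(eps_rf), r_rf = r_rf),
            class = "rf_params")
}

#' Reaction-field pair energy and force
#'
#' The shifted Coulomb + reaction-field interaction between two point charges,
#' `V(r) = f q_i q_j [ 1/r - C_rf r^2 / (2 R_rf^3) - (1 - C_rf/2) / R_rf ]`
#' (kJ/mol), which is exactly zero at the cutoff distance `R_rf`.
#' `rf_pair_force()` returns
#' the analytic force on atom i (`-dV/dr` along the unit vector of
#' `r_vec = r_i - r_j`); the force on j is its negative.
#'
#' @param q_i,q_j Charges, e.
#' @param r_ij Distance, nm (vectorized).
#' @param params An [rf_params()].
#' @return Energy in kJ/mol; force in kJ mol^-1 nm^-1.
#' @examples
#' p <- rf_params(61, 1.4)
#' rf_pair_energy(1, 1, 0.7, p)   # ~135.55
#' rf_pair_energy(1, -1, 1.4, p)  # 0 at the cutoff
#' @export
rf_pair_energy <- function(q_i, q_j, r_ij, params) {
  if (any(r_ij <= 0)) stop("r_ij must be positive")
  crf <- params$c_rf; rrf <- params$r_rf
  # grouped so the value is exactly zero (in floating point) at r_ij = R_rf
  .f_elec * q_i * q_j *
    ((1 / r_ij - 1 / rrf) - 0.5 * crf * (r_ij^2 - rrf^2) / rrf^3)
}

#' @rdname rf_pair_energy
#' @param r_vec Separation vector `r_i - r_j`, nm.
#' @export
rf_pair_force <- function(q_i, q_j, r_vec, params) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("zero separation")
  mag <- .f_elec * q_i * q_j * (1 / r^2 + params$c_rf * r / params$r_rf^3)
  mag * r_vec / r
}

#' Lennard-Jones pair energy and force
#'
#' `V(r) = C12 / r^12 - C6 / r^6`, applied with the same entity cutoff as the
#' electrostatics and no shift or long-range correction.
#'
#' @param type_i,type_j LJ type labels.
#' @param r_vec Separation vector `r_i - r_j`, nm.
#' @param lj An [lj_table()].
#' @return List with `energy` (kJ/mol) and `force` (vector on atom i).
#' @export
lj_pair_energy_force <- function(type_i, type_j, r_vec, lj = default_lj_table()) {
  r2 <- sum(r_vec^2)
  if (r2 <= 0) stop("zero separation")
  c6 <- lj$c6[type_i, type_j]; c12 <- lj$c12[type_i, type_j]
  ir6 <- 1 / r2^3
  e <- c12 * ir6^2 - c6 * ir6
  fscal <- (12 * c12 * ir6^2 - 6 * c6 * ir6) / r2
  list(energy = e, force = fscal * r_vec)
}

.subsys_int <- function(system) ifelse(system$subsystem == "solute", 0L, 1L)

.lj_type_int <- function(system) match(system$lj_type, system$lj$types) - 1L

# Evaluate one entity-pair list at given positions; returns raw accumulators.
.eval_entity_pairs <- function(system, entities, pairs, positions, params) {
  if (nrow(pairs) == 0) {
    return(list(e_el = numeric(3), e_lj = numeric(3),
                forces = matrix(0, n_atoms(system), 3), virial = 0))
  }
  cpp_eval_pairs(positions, pairs - 1L, entities$ptr, entities$atoms,
                 system$charges, .lj_type_int(system),
                 system$lj$c6, system$lj$c12, .subsys_int(system),
                 system$molecule_id, system$box,
                 params$c_rf, params$r_rf, .f_elec, system$exclusions - 1L)
}

.decomp <- function(e_el, e_lj) {
  structure(list(
    electrostatic = setNames(e_el, c("solute-solute", "solute-solvent", "solvent-solvent")),
    lj = setNames(e_lj, c("solute-solute", "solute-solvent", "solvent-solvent")),
    total_electrostatic = sum(e_el), total_lj = sum(e_lj),
    total = sum(e_el) + sum(e_lj)), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  m <- rbind(electrostatic = x$electrostatic, `lennard-jones` = x$lj)
  print(round(cbind(m, total = rowSums(m)), 6))
  cat(sprintf("total potential: %.6f kJ/mol\n", x$total))
  invisible(x)
}

#' Nonbonded energies, forces and virial over a pair structure
#'
#' Short-range entity pairs are evaluated at the current positions on every
#' call.  Intermediate-range pairs are evaluated only when the pairlist is due
#' for an update at `step` (or when no cache exists yet); between updates the
#' cached intermediate-range forces, energy decomposition and virial are
#' re-added unchanged -- the twin-range approximation.  All atom pairs of two
#' listed entities interact at their atomic minimum-image distance; excluded
#' intramolecular pairs are skipped.
#'
#' @param system [md_system()].
#' @param pairs [build_pairlist()] result (returned updated, carrying the
#'   cache).
#' @param scheme [cutoff_scheme()].
#' @param params [rf_params()]; `params$r_rf` should equal `scheme$r_long`.
#' @param step Step counter (0-based) for the update cadence.
#' @param entities Matching [make_entities()] result.
#' @param positions Optional coordinates overriding `system$positions`.
#' @return List: `energy` (an `energy_decomposition`), `forces` (N x 3,
#'   kJ mol^-1 nm^-1), `virial` (kJ/mol), `pairs` (updated pair structure).
#' @export
compute_nonbonded <- function(system, pairs, scheme, params, step = 0L,
                              entities = make_entities(system, scheme),
                              positions = system$positions) {
  if (scheme$update_interval == 1L && nrow(pairs$intermediate_pairs) > 0) {
    # single-range limit: everything is current every step, so evaluate one
    # merged, canonically ordered list -- numerically identical to a run whose
    # single cutoff sits at r_long
    merged <- rbind(pairs$short_pairs, pairs$intermediate_pairs)
    merged <- merged[order(merged[, 1], merged[, 2]), , drop = FALSE]
    sr <- .eval_entity_pairs(system, entities, merged, positions, params)
    pairs$cache <- NULL
    return(list(energy = .decomp(sr$e_el, sr$e_lj), forces = sr$forces,
                virial = sr$virial, pairs = pairs))
  }
  sr <- .eval_entity_pairs(system, entities, pairs$short_pairs, positions, params)
  refresh <- is.null(pairs$cache) || pairlist_due_for_update(step, scheme)
  if (nrow(pairs$intermediate_pairs) > 0) {
    if (refresh) {
      pairs$cache <- .eval_entity_pairs(system, entities,
                                        pairs$intermediate_pairs, positions,
                                        params)
      pairs$last_update_step <- as.integer(step)
    }
    ir <- pairs$cache
  } else {
    pairs$cache <- NULL
    ir <- list(e_el = numeric(3), e_lj = numeric(3), forces = 0, virial = 0)
  }
  list(energy = .decomp(sr$e_el + ir$e_el, sr$e_lj + ir$e_lj),
       forces = sr$forces + ir$forces,
       virial = sr$virial + ir$virial,
       pairs = pairs)
}

#' One-shot nonbonded evaluation of a configuration
#'
#' Convenience wrapper: builds entities and a fresh pairlist and evaluates
#' both ranges at the current positions (no caching) -- the single-range
#' evaluation used for stored-frame re-analysis and static checks.
#'
#' @inheritParams compute_nonbonded
#' @param eps_rf Reaction-field dielectric constant.
#' @param positions Optional coordinates overriding `system$positions`.
#' @param box Optional box overriding `system$box`.
#' @return As [compute_nonbonded()], plus the pair structure used.
#' @export
nonbonded_energy <- function(system, scheme, eps_rf = 61, positions = system$positions,
                             box = system$box) {
  params <- rf_params(eps_rf, scheme$r_long)
  sys <- system
  sys$box <- box
  ent <- make_entities(sys, scheme)
  pl <- build_pairlist(ent, positions, box, scheme)
  sr <- .eval_entity_pairs(sys, ent, pl$short_pairs, positions, params)
  ir <- .eval_entity_pairs(sys, ent, pl$intermediate_pairs, positions, params)
  list(energy = .decomp(sr$e_el + ir$e_el, sr$e_lj + ir$e_lj),
       forces = sr$forces + ir$forces, virial = sr$virial + ir$virial,
       pairs = pl)
}
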