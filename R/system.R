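#' Lennard-Jones interaction table
#'
#' Symmetric per-type-pair C6/C12 tables.  The default table carries two
#' types: `"none"` (no van der Waals site, used for water hydrogens) and
#' `"OW"`, the SPC water oxygen with C6 = 2.61735e-3 kJ mol^-1 nm^6 and
#' C12 = 2.634129e-6 kJ mol^-1 nm^12.  Cross terms follow the geometric
#' combination rule.
#'
#' @param c6,c12 Square symmetric matrices (kJ mol^-1 nm^6 / nm^12) with
#'   matching dimnames giving the type labels.
#' @return An object of class `lj_table`.
#' @export
lj_table <- function(c6, c12) {
  stopifnot(is.matrix(c6), is.matrix(c12), all(dim(c6) == dim(c12)))
  if (any(c6 < 0) || any(c12 < 0)) stop("C6 and C12 must be non-negative")
  if (max(abs(c6 - t(c6))) > 0 || max(abs(c12 - t(c12))) > 0)
    stop("LJ tables must be symmetric in the two types")
  structure(list(c6 = c6, c12 = c12, types = rownames(c6)),
            class = "lj_table")
}

#' @rdname lj_table
#' @export
default_lj_table <- function() {
  types <- c("none", "OW")
  c6v <- c(none = 0, OW = 2.61735e-3)
  c12v <- c(none = 0, OW = 2.634129e-6)
  c6 <- sqrt(outer(c6v, c6v))
  c12 <- sqrt(outer(c12v, c12v))
  dimnames(c6) <- dimnames(c12) <- list(types, types)
  lj_table(c6, c12)
}

#' Construct a simulation system
#'
#' The container for everything the engine needs: coordinates, velocities,
#' per-atom parameters, molecule / charge-group / subsystem assignments,
#' holonomic distance constraints, nonbonded exclusions and the periodic box.
#'
#' @param positions N x 3 matrix, nm.
#' @param velocities N x 3 matrix, nm/ps (defaults to zero).
#' @param masses Atomic masses, u.
#' @param charges Partial charges, e.
#' @param lj_type Character vector of LJ type labels matching `lj`.
#' @param name Atom names (e.g. `"OW"`); used by designated-atom group centers.
#' @param molecule_id,charge_group_id Integer labels per atom; a charge group
#'   must never span molecules.
#' @param subsystem `"solute"` or `"solvent"` per atom.
#' @param constraints 3-column matrix `(i, j, d0)`: atom indices (1-based) and
#'   target distance in nm.  Constrained pairs are automatically excluded.
#' @param exclusions 2-column matrix of atom index pairs that never interact
#'   nonbondedly (intramolecular pairs of rigid molecules).
#' @param box Length-3 orthorhombic edge lengths, nm.
#' @param lj An [lj_table()].
#' @return An object of class `md_system`.
#' @export
md_system <- function(positions, velocities = NULL, masses, charges, lj_type,
                      name = NULL, molecule_id, charge_group_id, subsystem,
                      constraints = NULL, exclusions = NULL, box,
                      lj = default_lj_table()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(name)) name <- rep("X", n)
  if (is.null(constraints)) constraints <- matrix(0, 0, 3)
  if (is.null(exclusions)) exclusions <- matrix(0L, 0, 2)
  constraints <- matrix(as.numeric(constraints), ncol = 3)
  exclusions <- matrix(as.integer(exclusions), ncol = 2)
  stopifnot(ncol(positions) == 3, nrow(velocities) == n,
            length(masses) == n, length(charges) == n,
            length(lj_type) == n, length(molecule_id) == n,
            length(charge_group_id) == n, length(subsystem) == n,
            length(box) == 3)
  if (!all(subsystem %in% c("solute", "solvent")))
    stop("subsystem labels must be 'solute' or 'solvent'")
  if (!all(lj_type %in% lj$types)) stop("unknown LJ type label")
  if (any(box <= 0)) stop("box edges must be positive")
  # a charge group never spans molecules
  if (nrow(positions) > 0) {
    grp_mol <- tapply(molecule_id, charge_group_id, function(m) length(unique(m)))
    if (any(grp_mol > 1)) stop("a charge group must not span molecules")
    grp_sub <- tapply(subsystem, charge_group_id, function(s) length(unique(s)))
    if (any(grp_sub > 1)) stop("a charge group must not span subsystems")
  }
  if (nrow(constraints) > 0) {
    if (any(constraints[, 3] <= 0)) stop("constraint target distances must be positive")
    exclusions <- rbind(exclusions, constraints[, 1:2, drop = FALSE])
  }
  if (nrow(exclusions) > 0) {
    exclusions <- t(apply(matrix(as.integer(exclusions), ncol = 2), 1L, sort))
    exclusions <- unique(exclusions)
    exclusions <- exclusions[order(exclusions[, 1], exclusions[, 2]), , drop = FALSE]
  }
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 masses = as.numeric(masses), charges = as.numeric(charges),
                 lj_type = as.character(lj_type), name = as.character(name),
                 molecule_id = as.integer(molecule_id),
                 charge_group_id = as.integer(charge_group_id),
                 subsystem = as.character(subsystem),
                 constraints = constraints,
                 exclusions = matrix(as.integer(exclusions), ncol = 2),
                 box = as.numeric(box), lj = lj),
            class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf("<md_system> %d atoms, %d molecules, %d charge groups\n",
              n_atoms(x), length(unique(x$molecule_id)),
              length(unique(x$charge_group_id))))
  cat(sprintf("  solute %d / solvent %d atoms; %d constraints; box %.4f x %.4f x %.4f nm\n",
              sum(x$subsystem == "solute"), sum(x$subsystem == "solvent"),
              nrow(x$constraints), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @rdname md_system
#' @param system An `md_system`.
#' @export
n_atoms <- function(system) nrow(system$positions)

# SPC geometry: O-H 0.1 nm, H-O-H 109.47 deg (rigid, SHAKE-constrained).
.spc <- local({
  d_oh <- 0.1
  theta <- 109.47 * pi / 180
  d_hh <- 2 * d_oh * sin(theta / 2)
  list(d_oh = d_oh, d_hh = d_hh,
       # template with O at origin, dipole along +z
       template = rbind(c(0, 0, 0),
                        c(d_oh * sin(theta / 2), 0, d_oh * cos(theta / 2)),
                        c(-d_oh * sin(theta / 2), 0, d_oh * cos(theta / 2))),
       masses = c(15.9994, 1.008, 1.008),
       charges = c(-0.82, 0.41, 0.41),
       lj_type = c("OW", "none", "none"),
       name = c("OW", "HW1", "HW2"))
})

# Uniform random rotation matrix (quaternion method), driven by runif().
.random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Build a periodic box of rigid three-site water
#'
#' Places `n_molecules` rigid SPC-parameterized waters on the smallest
#' enclosing cubic lattice inside a cubic box, jitters the lattice sites by
#' +/- 0.01 nm per coordinate and gives every molecule an independent random
#' orientation.  Each water is one molecule, one (neutral) charge group and
#' belongs to the solvent subsystem; the three intramolecular distances are
#' constrained (O-H, O-H, H-H) and excluded from nonbonded interactions.
#'
#' @param n_molecules Number of waters.
#' @param box_edge Cubic box edge, nm.
#' @param seed Integer seed; builds are bit-reproducible for a fixed seed.
#' @return An [md_system()] with zero velocities (assign them with
#'   [assign_maxwell_velocities()]).
#' @examples
#' w <- build_water_box(8, 1.24, seed = 1)
#' n_atoms(w)  # 24
#' @export
build_water_box <- function(n_molecules, box_edge, seed = 1L) {
  stopifnot(n_molecules >= 1, box_edge > 0)
  n_side <- ceiling(n_molecules^(1 / 3) - 1e-9)
  spacing <- box_edge / n_side
  jitter <- 0.01
  # worst-case O displacement from its site is sqrt(3)*jitter per molecule
  if (spacing - 2 * sqrt(3) * jitter < 0.24)
    stop(sprintf(paste0("box too small: lattice spacing %.3f nm cannot ",
                        "guarantee the 0.24 nm minimum O-O separation for %d ",
                        "molecules"), spacing, n_molecules))
  with_seed(seed, function() {
    sites <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                   z = seq_len(n_side)))[seq_len(n_molecules), , drop = FALSE]
    sites <- (sites - 0.5) * spacing
    pos <- matrix(0, 3 * n_molecules, 3)
    for (m in seq_len(n_molecules)) {
      rot <- .random_rotation()
      centre <- sites[m, ] + runif(3, -jitter, jitter)
      pos[(3 * m - 2):(3 * m), ] <- .spc$template %*% t(rot) +
        matrix(centre, 3, 3, byrow = TRUE)
    }
    idx <- rep(seq_len(n_molecules), each = 3)
    base <- 3 * (seq_len(n_molecules) - 1)
    cons <- rbind(cbind(base + 1, base + 2, .spc$d_oh),
                  cbind(base + 1, base + 3, .spc$d_oh),
                  cbind(base + 2, base + 3, .spc$d_hh))
    cons <- cons[order(cons[, 1], cons[, 2]), , drop = FALSE]
    sys <- md_system(positions = pos,
                     masses = rep(.spc$masses, n_molecules),
                     charges = rep(.spc$charges, n_molecules),
                     lj_type = rep(.spc$lj_type, n_molecules),
                     name = rep(.spc$name, n_molecules),
                     molecule_id = idx, charge_group_id = idx,
                     subsystem = rep("solvent", 3 * n_molecules),
                     constraints = cons, box = rep(box_edge, 3))
    omin <- cpp_min_pair_distance(pos[rep(.spc$name, n_molecules) == "OW", ,
                                      drop = FALSE], sys$box)
    if (n_molecules > 1 && omin < 0.24)
      stop("internal: O-O separation below 0.24 nm after placement")
    sys
  })
}

#' Build a toy charge-grouped solute chain
#'
#' A stand-in for a protein solute: `n_beads` dipolar residues of two atoms
#' (+0.4 e / -0.4 e, 0.1 nm apart, one neutral charge group each) strung on
#' constrained 0.38 nm virtual bonds.  Every solute atom carries a small
#' water-oxygen-sized LJ site so the chain cannot collapse onto the solvent.
#' The chain is built along the x axis (dipoles perpendicular to it) and given
#' a random rigid-body orientation and placement near the box centre.
#'
#' @param n_beads Number of residues (>= 1).
#' @param seed Integer seed.
#' @param box_edge Cubic box edge in nm; defaults to snugly enclosing the chain
#'   (override with the target solvent box before calling [solvate()]).
#' @return An [md_system()] labelled `solute`.
#' @examples
#' s <- build_toy_solute(5, seed = 1)
#' sum(s$charges)  # 0
#' @export
build_toy_solute <- function(n_beads, seed = 1L, box_edge = NULL) {
  stopifnot(n_beads >= 1)
  if (is.null(box_edge)) box_edge <- 0.38 * n_beads + 1
  with_seed(seed, function() {
    half <- 0.05
    xs <- 0.38 * (seq_len(n_beads) - (n_beads + 1) / 2)
    pos <- matrix(0, 2 * n_beads, 3)
    pos[seq(1, 2 * n_beads, by = 2), ] <- cbind(xs, half, 0)
    pos[seq(2, 2 * n_beads, by = 2), ] <- cbind(xs, -half, 0)
    rot <- .random_rotation()
    pos <- pos %*% t(rot)
    pos <- pos + matrix(box_edge / 2, 2 * n_beads, 3)
    idx <- rep(seq_len(n_beads), each = 2)
    intra <- cbind(seq(1, 2 * n_beads, by = 2), seq(2, 2 * n_beads, by = 2), 0.1)
    cons <- intra
    if (n_beads > 1) {
      plus <- seq(1, 2 * n_beads, by = 2)
      cons <- rbind(cons, cbind(plus[-n_beads], plus[-1], 0.38))
    }
    md_system(positions = pos,
              masses = rep(50, 2 * n_beads),
              charges = rep(c(0.4, -0.4), n_beads),
              lj_type = rep("OW", 2 * n_beads),
              name = rep(c("CB+", "CB-"), n_beads),
              molecule_id = rep(1L, 2 * n_beads), charge_group_id = idx,
              subsystem = rep("solute", 2 * n_beads),
              constraints = cons, box = rep(box_edge, 3))
  })
}

#' Merge a solute into a water box
#'
#' Any water molecule with an atom within `overlap_cutoff` (minimum image) of
#' any solute atom is removed whole; the remaining waters are appended after
#' the solute with remapped molecule / charge-group ids.
#'
#' @param solute,water Two [md_system()]s sharing the same box.
#' @param overlap_cutoff Removal distance, nm.
#' @return The merged `md_system`.
#' @export
solvate <- function(solute, water, overlap_cutoff = 0.25) {
  if (max(abs(solute$box - water$box)) > 1e-12)
    stop("solute and water boxes are incompatible")
  ns <- n_atoms(solute)
  if (ns == 0) return(water)
  keep_mol <- rep(TRUE, length(unique(water$molecule_id)))
  for (m in unique(water$molecule_id)) {
    wpos <- water$positions[water$molecule_id == m, , drop = FALSE]
    dmin <- Inf
    for (k in seq_len(nrow(wpos))) {
      d <- sweep(solute$positions, 2, wpos[k, ])
      d <- d - sweep(round(sweep(d, 2, water$box, "/")), 2, water$box, "*")
      dmin <- min(dmin, sqrt(min(rowSums(d^2))))
    }
    if (dmin < overlap_cutoff) keep_mol[m] <- FALSE
  }
  sel <- water$molecule_id %in% which(keep_mol)
  widx <- which(sel)
  remap <- match(widx, widx)  # 1..nw
  oldc <- water$constraints
  wcons <- oldc[oldc[, 1] %in% widx, , drop = FALSE]
  wcons[, 1] <- ns + match(wcons[, 1], widx)
  wcons[, 2] <- ns + match(wcons[, 2], widx)
  olde <- water$exclusions
  wexcl <- olde[olde[, 1] %in% widx & olde[, 2] %in% widx, , drop = FALSE]
  wexcl[, 1] <- ns + match(wexcl[, 1], widx)
  wexcl[, 2] <- ns + match(wexcl[, 2], widx)
  mol_off <- max(solute$molecule_id)
  grp_off <- max(solute$charge_group_id)
  md_system(positions = rbind(solute$positions, water$positions[sel, , drop = FALSE]),
            velocities = rbind(solute$velocities, water$velocities[sel, , drop = FALSE]),
            masses = c(solute$masses, water$masses[sel]),
            charges = c(solute$charges, water$charges[sel]),
            lj_type = c(solute$lj_type, water$lj_type[sel]),
            name = c(solute$name, water$name[sel]),
            molecule_id = c(solute$molecule_id,
                            mol_off + match(water$molecule_id[sel],
                                            sort(unique(water$molecule_id[sel])))),
            charge_group_id = c(solute$charge_group_id,
                                grp_off + match(water$charge_group_id[sel],
                                                sort(unique(water$charge_group_id[sel])))),
            subsystem = c(solute$subsystem, water$subsystem[sel]),
            constraints = rbind(solute$constraints, wcons),
            exclusions = rbind(solute$exclusions, wexcl),
            box = water$box, lj = solute$lj)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each velocity component is drawn from a normal distribution with variance
#' `k_B T / m`, then the components along constrained bonds are projected out
#' so rigid molecules carry no internal motion.
#'
#' @param system An [md_system()].
#' @param temperature Target temperature, K.
#' @param seed Integer seed.
#' @return The system with velocities set.
#' @export
assign_maxwell_velocities <- function(system, temperature, seed = 1L) {
  stopifnot(temperature >= 0)
  n <- n_atoms(system)
  if (temperature == 0) {
    system$velocities <- matrix(0, n, 3)
    return(system)
  }
  v <- with_seed(seed, function() {
    sdv <- sqrt(.k_boltz * temperature / system$masses)
    matrix(rnorm(3 * n, sd = rep(sdv, 3)), n, 3)
  })
  if (nrow(system$constraints) > 0) {
    v <- cpp_project_velocities(v, system$positions,
                                as.integer(system$constraints[, 1]) - 1L,
                                as.integer(system$constraints[, 2]) - 1L,
                                1 / system$masses, 1e-12, 200L)
  }
  system$velocities <- v
  system
}
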