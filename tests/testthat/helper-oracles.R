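# Independent oracles, written against the definitions rather than the
# package internals.

F_ELEC <- 138.935458
K_BOLTZ <- 8.31446e-3

# minimum-image displacement
mi_vec <- function(d, box) d - box * round(d / box)

# reaction-field pair term, coded independently of the package
oracle_rf <- function(qi, qj, r, R, eps) {
  crf <- 2 * (eps - 1) / (2 * eps + 1)
  F_ELEC * qi * qj * (1 / r - crf * r^2 / (2 * R^3) - (1 - crf / 2) / R)
}

# brute-force O(N^2) pairlist classification on centre coordinates
oracle_classify <- function(centers, box, rs, rl) {
  n <- nrow(centers)
  short <- NULL; inter <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum(mi_vec(centers[i, ] - centers[j, ], box)^2))
    if (r < rs) short <- rbind(short, c(i, j))
    else if (r < rl) inter <- rbind(inter, c(i, j))
  }
  list(short = short, inter = inter)
}

# brute-force double-loop nonbonded oracle under an atomistic inclusion rule
oracle_atomistic_energy <- function(sys, R, eps) {
  n <- nrow(sys$positions)
  excl <- paste(sys$exclusions[, 1], sys$exclusions[, 2])
  e_el <- 0; e_lj <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sys$molecule_id[i] == sys$molecule_id[j] && paste(i, j) %in% excl) next
    r <- sqrt(sum(mi_vec(sys$positions[i, ] - sys$positions[j, ], sys$box)^2))
    if (r >= R) next
    e_el <- e_el + oracle_rf(sys$charges[i], sys$charges[j], r, R, eps)
    e_lj <- e_lj + sys$lj$c12[sys$lj_type[i], sys$lj_type[j]] / r^12 -
      sys$lj$c6[sys$lj_type[i], sys$lj_type[j]] / r^6
  }
  c(el = e_el, lj = e_lj)
}

# brute-force molecular-pair energy: all atom pairs of two molecules at their
# atomic minimum-image distances (the group-inclusion energy)
oracle_molecular_pair <- function(sys, mol_a, mol_b, R, eps) {
  ia <- which(sys$molecule_id == mol_a); ib <- which(sys$molecule_id == mol_b)
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum(mi_vec(sys$positions[i, ] - sys$positions[j, ], sys$box)^2))
    e <- e + oracle_rf(sys$charges[i], sys$charges[j], r, R, eps)
  }
  e
}

# pair-set comparison helper (order-independent)
pair_key <- function(m) if (is.null(m) || nrow(m) == 0) character(0) else
  sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))

# a deterministic dense random-water configuration fixture
dense_water <- function(n = 50, edge = 2.9, seed = 1) {
  build_water_box(n, edge, seed = seed)
}

# singleton-charge-group copy of a system (scheme-degeneracy fixture)
singleton_groups <- function(sys) {
  md_system(positions = sys$positions, velocities = sys$velocities,
            masses = sys$masses, charges = sys$charges, lj_type = sys$lj_type,
            name = sys$name, molecule_id = sys$molecule_id,
            charge_group_id = seq_len(n_atoms(sys)),
            subsystem = sys$subsystem, constraints = sys$constraints,
            exclusions = sys$exclusions, box = sys$box, lj = sys$lj)
}
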