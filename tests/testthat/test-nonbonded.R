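test_that("the reaction-field constant matches its closed form", {
  expect_equal(rf_constant(1), 0)
  expect_equal(rf_constant(61), 120 / 123, tolerance = 1e-12)
  expect_equal(rf_constant(78), 154 / 157, tolerance = 1e-12)
  expect_error(rf_constant(0.5), ">= 1")
})

test_that("reaction-field pair energies match a term-by-term oracle", {
  p <- rf_params(61, 1.4)
  # independent evaluation of the three terms
  expect_equal(rf_pair_energy(1, 1, 0.7, p), oracle_rf(1, 1, 0.7, 1.4, 61),
               tolerance = 1e-12)
  expect_equal(rf_pair_energy(1, 1, 0.7, p), 135.55, tolerance = 1e-2)
  # vanishes identically at the cutoff, symmetric in the charges
  expect_identical(rf_pair_energy(0.41, -0.82, 1.4, p), 0)
  expect_equal(rf_pair_energy(2, -3, 0.9, p), rf_pair_energy(-3, 2, 0.9, p))
  # pure-water setting
  p78 <- rf_params(78, 1.4)
  expect_equal(rf_pair_energy(-1, 1, 1.1, p78),
               oracle_rf(-1, 1, 1.1, 1.4, 78), tolerance = 1e-12)
  expect_error(rf_pair_energy(1, 1, 0, p), "positive")
})

test_that("reaction-field forces agree with finite differences and Newton's third law", {
  p <- rf_params(61, 1.4)
  h <- 1e-6
  for (r in c(0.5, 0.9, 1.3)) {
    fd <- -(rf_pair_energy(1, 1, r + h, p) - rf_pair_energy(1, 1, r - h, p)) / (2 * h)
    f <- rf_pair_force(1, 1, c(r, 0, 0), p)
    expect_equal(f[1], fd, tolerance = 1e-6)
    expect_equal(f[2:3], c(0, 0))
  }
  rv <- c(0.2, -0.3, 0.4)
  expect_equal(rf_pair_force(1.3, -0.7, rv, p) + rf_pair_force(-0.7, 1.3, -rv, p),
               c(0, 0, 0))
  # unlike charges attract: force on i points toward j
  f <- rf_pair_force(1, -1, c(0.3, 0, 0), p)
  expect_lt(f[1], 0)
})

test_that("Lennard-Jones terms reproduce the closed-form minimum and vanish for null types", {
  lj <- default_lj_table()
  c6 <- lj$c6["OW", "OW"]; c12 <- lj$c12["OW", "OW"]
  rmin <- (2 * c12 / c6)^(1 / 6)
  at_min <- lj_pair_energy_force("OW", "OW", c(rmin, 0, 0), lj)
  expect_equal(at_min$energy, -c6^2 / (4 * c12), tolerance = 1e-12)
  expect_equal(at_min$force, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(lj_pair_energy_force("none", "none", c(0.2, 0, 0), lj)$energy, 0)
  expect_equal(lj_pair_energy_force("none", "OW", c(0.2, 0, 0), lj)$force, c(0, 0, 0))
  h <- 1e-6
  for (r in c(0.28, 0.35, 0.5)) {
    fd <- -(lj_pair_energy_force("OW", "OW", c(r + h, 0, 0), lj)$energy -
              lj_pair_energy_force("OW", "OW", c(r - h, 0, 0), lj)$energy) / (2 * h)
    expect_equal(lj_pair_energy_force("OW", "OW", c(r, 0, 0), lj)$force[1], fd,
                 tolerance = 1e-6)
  }
})

test_that("two-water group evaluation equals the nine-term brute-force oracle", {
  w <- build_water_box(8, 4, seed = 6)
  keep <- w$molecule_id %in% 1:2
  pos <- w$positions[keep, ]
  pos[4:6, ] <- pos[4:6, ] - matrix(pos[4, ] - pos[1, ] - c(0.35, 0.1, 0), 3, 3,
                                    byrow = TRUE)
  sys <- md_system(positions = pos, masses = w$masses[keep],
                   charges = w$charges[keep], lj_type = w$lj_type[keep],
                   name = w$name[keep], molecule_id = w$molecule_id[keep],
                   charge_group_id = w$charge_group_id[keep],
                   subsystem = w$subsystem[keep],
                   constraints = w$constraints[1:6, ], box = c(4, 4, 4))
  sch <- scheme_preset("CG(OW)", r_short = 1.4, r_long = 1.4)
  nb <- nonbonded_energy(sys, sch, eps_rf = 61)
  e_ora <- oracle_molecular_pair(sys, 1, 2, 1.4, 61)
  expect_equal(nb$energy$total_electrostatic, e_ora, tolerance = 1e-12)
  # O-O LJ term on top
  r_oo <- sqrt(sum((pos[1, ] - pos[4, ])^2))
  lj <- default_lj_table()
  expect_equal(nb$energy$total_lj,
               lj$c12["OW", "OW"] / r_oo^12 - lj$c6["OW", "OW"] / r_oo^6,
               tolerance = 1e-12)
  # decomposition sums to the total
  expect_equal(sum(nb$energy$electrostatic) + sum(nb$energy$lj),
               nb$energy$total, tolerance = 1e-13)
})

test_that("a group pair beyond the long cutoff contributes nothing", {
  w <- build_water_box(8, 4, seed = 6)
  keep <- w$molecule_id %in% 1:2
  pos <- w$positions[keep, ]
  pos[4:6, ] <- pos[4:6, ] - matrix(pos[4, ] - pos[1, ] - c(1.55, 0, 0), 3, 3,
                                    byrow = TRUE)
  sys <- md_system(positions = pos, masses = w$masses[keep],
                   charges = w$charges[keep], lj_type = w$lj_type[keep],
                   name = w$name[keep], molecule_id = w$molecule_id[keep],
                   charge_group_id = w$charge_group_id[keep],
                   subsystem = w$subsystem[keep],
                   constraints = w$constraints[1:6, ], box = c(4, 4, 4))
  sch <- scheme_preset("CG(OW)", r_short = 0.8, r_long = 1.5)
  nb <- nonbonded_energy(sys, sch, eps_rf = 61)
  expect_identical(nb$energy$total, 0)
  expect_identical(max(abs(nb$forces)), 0)
})

test_that("atomistic evaluation equals the double-loop oracle and conserves momentum", {
  w <- dense_water(50, 2.9, seed = 3)
  sch <- scheme_preset("AT", r_short = 1.4, r_long = 1.4)
  nb <- nonbonded_energy(w, sch, eps_rf = 78)
  ora <- oracle_atomistic_energy(w, 1.4, 78)
  expect_equal(nb$energy$total_electrostatic, ora[["el"]], tolerance = 1e-12)
  expect_equal(nb$energy$total_lj, ora[["lj"]], tolerance = 1e-12)
  expect_lt(max(abs(colSums(nb$forces))), 1e-9)
})

test_that("solute/solvent decomposition buckets are label-correct", {
  s <- build_toy_solute(2, seed = 1, box_edge = 2.9)
  w <- dense_water(20, 2.9, seed = 8)
  sys <- solvate(s, w, overlap_cutoff = 0.28)
  sch <- scheme_preset("SA/TR", r_short = 1.4, r_long = 1.4)
  nb <- nonbonded_energy(sys, sch, eps_rf = 61)
  # zero out solute charges: solute-solute and solute-solvent electrostatics vanish
  sys0 <- sys; sys0$charges[sys0$subsystem == "solute"] <- 0
  nb0 <- nonbonded_energy(sys0, sch, eps_rf = 61)
  expect_identical(nb0$energy$electrostatic[["solute-solute"]], 0)
  expect_identical(nb0$energy$electrostatic[["solute-solvent"]], 0)
  expect_equal(nb0$energy$electrostatic[["solvent-solvent"]],
               nb$energy$electrostatic[["solvent-solvent"]], tolerance = 1e-12)
})
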