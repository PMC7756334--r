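test_that("leapfrog reproduces hand-iterated closed forms", {
  # free flight
  st <- leapfrog_step(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1),
                      matrix(0, 1, 3), 1, 0.002)
  expect_equal(st$positions[1, ], c(0.002, 0, 0))
  # zero velocity and force: nothing moves
  st0 <- leapfrog_step(matrix(1, 2, 3), matrix(0, 2, 3), matrix(0, 2, 3),
                       c(2, 3), 0.002)
  expect_equal(st0$positions, matrix(1, 2, 3))
  # constant force: v_n = v_0 + n a dt,  x_n = sum_k v_k dt (discrete closed form)
  m <- 2; f <- 3; dt <- 0.01; n <- 25
  pos <- matrix(0, 1, 3); vel <- matrix(0, 1, 3)
  for (k in seq_len(n)) {
    st <- leapfrog_step(pos, vel, matrix(c(f, 0, 0), 1), m, dt)
    pos <- st$positions; vel <- st$velocities
  }
  a <- f / m
  expect_equal(vel[1, 1], n * a * dt, tolerance = 1e-12)
  expect_equal(pos[1, 1], a * dt^2 * n * (n + 1) / 2, tolerance = 1e-12)
})

test_that("SHAKE restores bonds symmetrically and leaves satisfied ones alone", {
  # already satisfied: fixed point
  p <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  cons <- matrix(c(1, 2, 0.1), 1)
  out <- shake(p, p, cons, 1e-10, c(1, 1))
  expect_equal(out$positions, p)
  expect_equal(out$iterations, 1L)
  # collinear stretch 0.12 vs target 0.10, equal masses: each atom moves 0.01 inward
  p2 <- rbind(c(0, 0, 0), c(0.12, 0, 0))
  out2 <- shake(p2, p2, cons, 1e-12, c(1, 1))
  expect_equal(out2$positions[1, 1], 0.01, tolerance = 1e-7)
  expect_equal(out2$positions[2, 1], 0.11, tolerance = 1e-7)
  # rigid water triplet under random perturbation: all constraints restored
  w <- build_water_box(8, 1.24, seed = 2)
  idx <- 1:3
  cons3 <- w$constraints[1:3, ]
  set.seed(4)
  for (rep in 1:200) {
    ref <- w$positions[idx, ]
    pert <- ref + matrix(rnorm(9, sd = 0.01), 3, 3)
    out3 <- shake(pert, ref, cons3, 1e-6, w$masses[idx])
    d2 <- rowSums((out3$positions[cons3[, 1], ] - out3$positions[cons3[, 2], ])^2)
    expect_true(all(abs(d2 - cons3[, 3]^2) / cons3[, 3]^2 <= 1e-6))
  }
})

test_that("bath temperature is the kinetic-energy identity", {
  expect_equal(bath_temperature(1.5 * K_BOLTZ * 300, 3), 300)
  expect_equal(bath_temperature(0, 10), 0)
  expect_equal(bath_temperature(2 * 1.5 * K_BOLTZ * 300, 3), 600)
  expect_error(bath_temperature(1, 0), "positive")
})

test_that("weak-coupling scaling follows the relaxation algebra", {
  expect_equal(weak_coupling_t_scale(300, 300, 0.002, 0.1), 1)
  # T' = T + (dt/tau)(Tref - T): 310 -> 309.8 exactly
  lam <- weak_coupling_t_scale(310, 300, 0.002, 0.1)
  expect_equal(lam^2 * 310, 309.8, tolerance = 1e-12)
  # repeated application contracts monotonically to the reference
  t <- 350
  for (k in 1:2000) t <- weak_coupling_t_scale(t, 300, 0.002, 0.1)^2 * t
  expect_equal(t, 300, tolerance = 1e-6)
  # pressure factor: identity at P = Pref, expansion when too hot a pressure
  expect_equal(weak_coupling_p_scale(1, 1, 0.002, 0.5, 4.575e-4), 1)
  expect_gt(weak_coupling_p_scale(2, 1, 0.002, 0.5, 4.575e-4), 1)
  mu <- weak_coupling_p_scale(1.8, 1, 0.002, 0.5, 4.575e-4)
  expect_equal(mu^3, 1 - 4.575e-4 * (0.002 / 0.5) * (1 - 1.8), tolerance = 1e-12)
  expect_warning(weak_coupling_p_scale(1e6, 1, 0.1, 0.1, 1), "clamped")
})

test_that("pressure reduces to the ideal-gas law without interactions", {
  expect_equal(compute_pressure(0, 0, 10), 0)
  expect_equal(compute_pressure(30, 0, 10), 2 * 30 / (3 * 10))
  # 100 non-interacting particles: P V = (2/3) E_kin exactly, approx N kB T
  n <- 100; box <- c(3, 3, 3)
  set.seed(12)
  sys <- md_system(positions = matrix(runif(3 * n) * 3, n, 3),
                   masses = rep(20, n), charges = rep(0, n),
                   lj_type = rep("none", n), molecule_id = seq_len(n),
                   charge_group_id = seq_len(n), subsystem = rep("solvent", n),
                   box = box)
  sys <- assign_maxwell_velocities(sys, 250, seed = 5)
  sch <- cutoff_scheme("atomistic", "atomistic", r_short = 1.2, r_long = 1.2,
                       update_interval = 1)
  run <- run_simulation(sys, sch, md_protocol(n_steps = 200, thermostat = FALSE,
                                              log_interval = 1))
  pv <- mean(run$energy$pressure) * prod(box)
  nkt <- n * K_BOLTZ * 250
  # sampling error of E_kin is sqrt(2/(3N)) relative; allow 3 sigma
  expect_lt(abs(pv - nkt) / nkt, 3 * sqrt(2 / (3 * n)))
  expect_equal(run$energy$virial, rep(0, 200))
})

test_that("baths are scaled independently and the barostat leaves NVT boxes alone", {
  # unconstrained, chargeless mixed system: forces vanish, so one step is
  # pure thermostat algebra
  n <- 10
  set.seed(21)
  sys <- md_system(positions = matrix(runif(3 * n) * 3, n, 3),
                   masses = rep(15, n), charges = rep(0, n),
                   lj_type = rep("none", n), molecule_id = seq_len(n),
                   charge_group_id = seq_len(n),
                   subsystem = rep(c("solute", "solvent"), each = n / 2),
                   box = c(3, 3, 3))
  sys <- assign_maxwell_velocities(sys, 320, seed = 9)
  sch <- cutoff_scheme("atomistic", "atomistic", r_short = 1.2, r_long = 1.2,
                       update_interval = 1)
  sol <- sys$subsystem == "solute"
  ke_atom <- 0.5 * sys$masses * rowSums(sys$velocities^2)
  ke_sol <- sum(ke_atom[sol])
  # the solute bath sits exactly at its reference, the solvent bath far off:
  # scaling the solvent must leave solute velocities bit-identical
  run <- run_simulation(sys, sch, md_protocol(
    n_steps = 1, thermostat = TRUE,
    t_ref_solute = bath_temperature(ke_sol, bath_dof(sys)[["solute"]]),
    t_ref_solvent = 200, log_interval = 1))
  expect_identical(run$system$velocities[sol, ], sys$velocities[sol, ])
  expect_false(isTRUE(all.equal(run$system$velocities[!sol, ],
                                sys$velocities[!sol, ])))
  # barostat off: box exactly constant
  expect_identical(run$system$box, sys$box)
})
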