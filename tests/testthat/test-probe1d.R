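test_that("standard presets have the stated charge structure and decay laws", {
  cfgs <- standard_configs()
  expect_named(cfgs, c("dipole-dipole", "dipole-charge", "charge-charge"))
  expect_equal(sum(cfgs[["dipole-dipole"]]$charges_a), 0)
  expect_equal(sum(cfgs[["dipole-dipole"]]$charges_b), 0)
  # charge-charge inside the cutoff decays ~ 1/r before the shift dominates
  s <- c(0.4, 0.8)
  e_cc <- probe_bare_energy(cfgs[["charge-charge"]], s)
  expect_equal(e_cc[1] / e_cc[2], 2, tolerance = 0.02)
  # bare dipole-dipole falls off as r^-3 at 5x the bond length and beyond
  s3 <- c(0.5, 1.0)
  e_dd <- probe_bare_energy(cfgs[["dipole-dipole"]], s3)
  expect_equal(e_dd[1] / e_dd[2], 8, tolerance = 0.05)
})

test_that("profiles vanish where no pair can be inside the cutoff", {
  for (nm in names(standard_configs())) {
    for (sch in c("atomistic", "group", "mixed")) {
      cfg <- probe_config(standard_configs()[[nm]]$charges_a,
                          standard_configs()[[nm]]$charges_b,
                          scheme = sch, grid = c(1.55, 1.8, 0.005))
      pr <- scan_profile(cfg)
      expect_identical(max(abs(pr$energy)), 0)
      expect_identical(max(abs(pr$force)), 0)
    }
  }
})

test_that("the group scheme jumps by exactly the four-term energy at the centre crossing", {
  cfg <- probe_config(c(1, -1), c(1, -1), scheme = "group",
                      grid = c(1.2, 1.6, 1e-3))
  pr <- scan_profile(cfg)
  eps <- 1e-7
  inside <- scan_profile(probe_config(c(1, -1), c(1, -1), scheme = "group",
                                      grid = c(1.4 - eps, 1.4, eps)))$energy[1]
  # four-term oracle at the crossing geometry (bond perpendicular to the axis)
  h <- 0.05
  s0 <- 1.4 - eps
  ora <- 0
  for (i in 1:2) for (j in 1:2) {
    dy <- c(h, -h)[i] - c(h, -h)[j]
    r <- sqrt(s0^2 + dy^2)
    ora <- ora + oracle_rf(c(1, -1)[i], c(1, -1)[j], r, 1.4, 61)
  }
  expect_equal(inside, ora, tolerance = 1e-10)
  # and the scanned profile carries exactly one energy discontinuity, at R_rf
  disc <- find_discontinuities(pr, "energy")
  expect_equal(nrow(disc), 1)
  expect_lt(abs(disc$location - 1.4), 1e-3)
  expect_equal(disc$jump, -inside, tolerance = 5e-3)  # grid-resolution limited
})

test_that("discontinuity detection flags steps and ignores smooth profiles", {
  x <- seq(0, 1, by = 0.01)
  lin <- data.frame(separation = x, energy = 3 * x - 1)
  expect_equal(nrow(find_discontinuities(lin, "energy")), 0)
  stepped <- data.frame(separation = x, energy = 0.2 * x + ifelse(x > 0.5, 2, 0))
  d <- find_discontinuities(stepped, "energy")
  expect_equal(nrow(d), 1)
  expect_equal(d$jump, 2, tolerance = 1e-3)
  expect_lt(abs(d$location - 0.5), 0.011)
})

test_that("atomistic profiles are continuous while forces spike at crossings", {
  mk <- function(step) scan_profile(probe_config(c(1, -1), c(1, -1),
                                                 scheme = "atomistic",
                                                 grid = c(1.3, 1.5, step)))
  # max inter-grid energy jump shrinks ~ linearly with the grid step
  j1 <- max(abs(diff(mk(2e-3)$energy)))
  j2 <- max(abs(diff(mk(1e-3)$energy)))
  j4 <- max(abs(diff(mk(5e-4)$energy)))
  expect_lt(j2 / j1, 0.65)
  expect_lt(j4 / j2, 0.65)
  # force discontinuities at the two atomic crossing distances
  pr <- mk(1e-3)
  d <- find_discontinuities(pr, "force")
  crossings <- c(sqrt(1.4^2 - 0.1^2), 1.4)
  expect_gte(nrow(d), 2)
  expect_true(any(abs(d$location - crossings[1]) < 2e-3))
  expect_true(any(abs(d$location - crossings[2]) < 2e-3))
})

test_that("the mixed scheme is continuous at the centre crossings of A's atoms", {
  # with B's bond perpendicular to every sight line from A's atoms, both B
  # atoms sit at the same distance from a toggling A atom, so the toggled
  # term is (q3 + q4) V(r) = 0 for a neutral B: exact continuity
  cfg <- probe_config(c(1, -1), c(1, -1), scheme = "mixed",
                      grid = c(1.3, 1.5, 1e-3), orientation = c("x", "y"))
  pr <- scan_profile(cfg)
  expect_equal(nrow(find_discontinuities(pr, "energy")), 0)
  # straddle each crossing (s = R -/+ b/2): the centred difference is
  # J + 2 eps E', so the Richardson combination 2 d(eps) - d(2 eps) isolates
  # the jump J, expected to vanish
  ener_at <- function(s) scan_profile(probe_config(
    c(1, -1), c(1, -1), scheme = "mixed", grid = c(s, s + 1e-9, 1e-8),
    orientation = c("x", "y")))$energy[1]
  for (s0 in c(1.4 - 0.05, 1.4 + 0.05)) {
    eps <- 1e-6
    d1 <- ener_at(s0 + eps) - ener_at(s0 - eps)
    d2 <- ener_at(s0 + 2 * eps) - ener_at(s0 - 2 * eps)
    expect_lt(abs(2 * d1 - d2), 1e-10)
  }
  # same geometry, dipole-charge: the group scheme still jumps at the centre
  # crossing while the mixed scheme stays smooth
  prg <- scan_profile(probe_config(c(1, -1), c(1, 0), scheme = "group",
                                   grid = c(1.3, 1.5, 1e-3),
                                   orientation = c("x", "y")))
  expect_gte(nrow(find_discontinuities(prg, "energy")), 1)
  prm <- scan_profile(probe_config(c(1, -1), c(1, 0), scheme = "mixed",
                                   grid = c(1.3, 1.5, 1e-3),
                                   orientation = c("x", "y")))
  expect_lt(max(abs(diff(prm$energy))), 0.1 * max(abs(diff(prg$energy))))
})

test_that("all schemes agree when every distance is simultaneously inside", {
  for (nm in names(standard_configs())) {
    base <- standard_configs()[[nm]]
    prs <- lapply(c("atomistic", "group", "mixed"), function(sch)
      scan_profile(probe_config(base$charges_a, base$charges_b, scheme = sch,
                                grid = c(0.3, 1.0, 0.01))))
    expect_equal(prs[[1]]$energy, prs[[2]]$energy, tolerance = 1e-13)
    expect_equal(prs[[2]]$energy, prs[[3]]$energy, tolerance = 1e-13)
    expect_equal(prs[[1]]$force, prs[[2]]$force, tolerance = 1e-13)
  }
})
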