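frame_of <- function(pos, box) list(step = 0L, time = 0, positions = pos,
                                    box = box)

test_that("the RDF localizes fixed pairs and is translation invariant", {
  box <- c(3, 3, 3)
  pos <- rbind(c(0.5, 0.5, 0.5), c(1.2, 0.5, 0.5))
  g <- rdf(list(frame_of(pos, box)), 1:2, bin_width = 0.05, r_max = 1.4)
  occupied <- which(g$count > 0)
  expect_length(occupied, 1)
  expect_true(g$r[occupied] - 0.025 <= 0.7 && 0.7 < g$r[occupied] + 0.025)
  shift <- matrix(c(1.1, -0.4, 2.2), 2, 3, byrow = TRUE)
  g2 <- rdf(list(frame_of(pos + shift, box)), 1:2, bin_width = 0.05, r_max = 1.4)
  expect_equal(g$count, g2$count)
  expect_error(rdf(list(frame_of(pos, box)), 1:2, r_max = 2), "half the smallest")
})

test_that("RDF bin mass balances a brute-force pair count within r_max", {
  set.seed(7)
  box <- c(2.5, 2.5, 2.5)
  pos <- matrix(runif(3 * 40) * 2.5, 40, 3)
  g <- rdf(list(frame_of(pos, box)), 1:40, bin_width = 0.05, r_max = 1.25)
  n_ora <- 0
  for (i in 1:39) for (j in (i + 1):40)
    if (sqrt(sum(mi_vec(pos[i, ] - pos[j, ], box)^2)) < 1.25)
      n_ora <- n_ora + 1
  expect_equal(sum(g$count), n_ora)
})

test_that("the dipole correlation hits its exact limits", {
  # two waters with artificially aligned, then antiparallel, dipoles
  w <- build_water_box(8, 2.4, seed = 1)
  keep <- w$molecule_id %in% 1:2
  pos <- w$positions[keep, ]
  # rebuild molecule 2 as a translated copy of molecule 1: parallel dipoles
  d <- 0.62
  pos[4:6, ] <- pos[1:3, ] + matrix(c(d, 0, 0), 3, 3, byrow = TRUE)
  sys <- md_system(positions = pos, masses = w$masses[keep],
                   charges = w$charges[keep], lj_type = w$lj_type[keep],
                   name = w$name[keep], molecule_id = w$molecule_id[keep],
                   charge_group_id = w$charge_group_id[keep],
                   subsystem = w$subsystem[keep], box = c(2.4, 2.4, 2.4))
  cr <- dipole_correlation(list(frame_of(pos, sys$box)), sys, bin_width = 0.05)
  expect_equal(cr$value[cr$count > 0], 1, tolerance = 1e-12)
  # flip molecule 2 through its centre: antiparallel pair, C = -1 in its bin
  ctr <- colMeans(pos[4:6, ])
  pos2 <- pos
  pos2[4:6, ] <- 2 * matrix(ctr, 3, 3, byrow = TRUE) - pos[4:6, ]
  cr2 <- dipole_correlation(list(frame_of(pos2, sys$box)), sys, bin_width = 0.05)
  expect_equal(cr2$value[cr2$count > 0], -1, tolerance = 1e-12)
  expect_true(all(abs(cr$value[cr$count > 0]) <= 1 + 1e-12))
})

test_that("radius of gyration follows its definition and invariances", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1), 12), 0)
  two <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  expect_equal(radius_of_gyration(two, c(5, 5)), 0.1)
  set.seed(3)
  pos <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 1, 16)
  rg <- radius_of_gyration(pos, m)
  # rigid translation + rotation
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(radius_of_gyration(pos %*% rot + 2.5, m), rg, tolerance = 1e-12)
  expect_error(radius_of_gyration(matrix(0, 0, 3), numeric(0)), "empty")
})

test_that("RMSD100 normalizes by chain length as stated", {
  expect_equal(rmsd100(0.31, 100), 0.31)
  expect_equal(rmsd100(0, 250), 0)
  expect_equal(rmsd100(0.2, 400), 0.2 / (1 + log(2)), tolerance = 1e-12)
  expect_equal(rmsd100(0.2, 400), 0.1181, tolerance = 1e-3)
  expect_warning(out <- rmsd100(0.2, 5), "too short")
  expect_true(is.na(out))
})

test_that("superposition RMSD recovers rotated copies", {
  set.seed(8)
  x <- matrix(rnorm(45), 15, 3)
  th <- 1.1
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_lt(rmsd_fit(x, x %*% rot + 3), 1e-10)
  y <- x; y[1, ] <- y[1, ] + c(0.3, 0, 0)
  expect_gt(rmsd_fit(x, y), 0)
})

test_that("hydrogen bonds follow the printed distance and angle thresholds", {
  box <- c(3, 3, 3)
  mk <- function(da_dist, angle_deg) {
    # exact construction: angle at H is angle_deg, |HD| = 0.1, |DA| = da_dist
    th <- angle_deg * pi / 180
    h <- c(1, 1, 1)
    d <- h + 0.1 * c(1, 0, 0)
    ha <- 0.1 * cos(th) + sqrt(da_dist^2 - 0.01 * sin(th)^2)
    a <- h + ha * c(cos(th), sin(th), 0)
    frame_of(rbind(d, h, a), box)
  }
  expect_equal(count_hbonds(mk(0.24, 150), 1, 2, 3), 1L)
  expect_equal(count_hbonds(mk(0.26, 150), 1, 2, 3), 0L)
  expect_equal(count_hbonds(mk(0.24, 119), 1, 2, 3), 0L)
  # hydrogen-site variant shifts which distance is thresholded
  expect_equal(count_hbonds(mk(0.26, 170), 1, 2, 3,
                            distance_site = "hydrogen"), 1L)
})

test_that("NOE averaging weights short distances and handles edge cases", {
  expect_equal(noe_average(rep(0.3, 5)), 0.3)
  expect_equal(noe_average(c(0.2, 0.4)), 70.3125^(-1 / 3), tolerance = 1e-12)
  expect_equal(noe_average(c(0.2, 0.4)), 0.2423, tolerance = 1e-3)
  set.seed(2)
  r <- runif(50, 0.2, 0.6)
  expect_lte(noe_average(r), mean(r))
  expect_error(noe_average(numeric(0)), "empty")
  expect_error(noe_average(c(0.2, -1)), "positive")
})

test_that("bath temperature series windows and summarizes the log exactly", {
  log <- data.frame(time = seq(0, 1, by = 0.1),
                    t_solute = rep(305, 11), t_solvent = seq(290, 300, by = 1))
  out <- bath_temperature_series(log)
  expect_equal(out$summary$sd[out$summary$bath == "solute"], 0)
  expect_equal(out$summary$mean[out$summary$bath == "solvent"], 295)
  win <- bath_temperature_series(log, window = c(0.55, 1))
  expect_equal(nrow(win$series), 5)
  expect_equal(win$summary$mean[win$summary$bath == "solvent"], mean(297:300) - 0.5)
  expect_error(bath_temperature_series(data.frame(a = 1)), "missing")
})
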