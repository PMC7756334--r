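test_that("entity construction follows the scheme rules", {
  w <- build_water_box(8, 1.24, seed = 1)
  at <- make_entities(w, scheme_preset("AT"))
  expect_equal(at$n_entities, 24)
  cg <- make_entities(w, scheme_preset("CG(OW)"))
  expect_equal(cg$n_entities, 8)
  # CG(OW) centres sit on the oxygen regardless of the hydrogens
  ctr <- entity_centers(cg, w$positions)
  expect_equal(ctr, w$positions[w$name == "OW", ], ignore_attr = TRUE)
  shifted <- w$positions
  shifted[w$name != "OW", ] <- shifted[w$name != "OW", ] + 0.05
  expect_equal(entity_centers(cg, shifted), ctr, ignore_attr = TRUE)
  # SA: 5-bead solute (10 atomistic entities) + 8 water groups = 18
  s <- build_toy_solute(5, seed = 1, box_edge = 1.24)
  merged <- solvate(s, w, overlap_cutoff = 0)
  sa <- make_entities(merged, scheme_preset("SA/TR"))
  expect_equal(sa$n_entities, 18)
  expect_equal(sum(sa$subsystem == "solute"), 10)
  # designated-atom rule with no matching atom errors
  expect_error(make_entities(w, cutoff_scheme("group", "group", "atom",
                                              designated_atom = "XX")),
               "no atom named")
})

test_that("entity centres follow cog / designated-atom / single-atom rules", {
  w <- build_water_box(8, 1.24, seed = 3)
  cog <- make_entities(w, scheme_preset("CG(cog)"))
  expect_equal(entity_center(cog, w$positions, 1),
               colMeans(w$positions[1:3, ]), ignore_attr = TRUE)
  expect_equal(entity_centers(cog, w$positions)[1, ],
               colMeans(w$positions[1:3, ]), ignore_attr = TRUE)
  at <- make_entities(w, scheme_preset("AT"))
  expect_equal(entity_center(at, w$positions, 5), w$positions[5, ],
               ignore_attr = TRUE)
})

test_that("pair classification respects the strict thresholds", {
  # two waters at controlled O-O distances along x
  mk2 <- function(d) {
    w <- build_water_box(8, 4, seed = 1)
    keep <- w$molecule_id %in% 1:2
    pos <- w$positions[keep, ]
    pos[4:6, ] <- pos[4:6, ] - matrix(pos[4, ] - pos[1, ] - c(d, 0, 0), 3, 3,
                                      byrow = TRUE)
    md_system(positions = pos, masses = w$masses[keep], charges = w$charges[keep],
              lj_type = w$lj_type[keep], name = w$name[keep],
              molecule_id = w$molecule_id[keep],
              charge_group_id = w$charge_group_id[keep],
              subsystem = w$subsystem[keep], constraints = w$constraints[1:6, ],
              box = c(4, 4, 4))
  }
  sch <- scheme_preset("CG(OW)", r_short = 0.8, r_long = 1.4)
  for (case in list(list(d = 0.79, short = 1, inter = 0),
                    list(d = 1.39, short = 0, inter = 1),
                    list(d = 1.41, short = 0, inter = 0))) {
    sys <- mk2(case$d)
    ent <- make_entities(sys, sch)
    pl <- build_pairlist(ent, sys$positions, sys$box, sch)
    expect_equal(nrow(pl$short_pairs), case$short)
    expect_equal(nrow(pl$intermediate_pairs), case$inter)
  }
  expect_error(build_pairlist(make_entities(mk2(0.5), sch), mk2(0.5)$positions,
                              c(2, 2, 2), sch), "twice the long-range")
})

test_that("update cadence matches the twin-range bookkeeping", {
  tr <- scheme_preset("CG/TR")  # interval 5 = 10 fs at 2 fs steps
  expect_true(pairlist_due_for_update(10, tr))
  expect_false(pairlist_due_for_update(7, tr))
  expect_true(pairlist_due_for_update(0, tr))
  sr <- scheme_preset("CG/SR")
  for (s in 0:7) expect_true(pairlist_due_for_update(s, sr))
})

test_that("cell-list and brute-force classification match the R oracle", {
  sch <- cutoff_scheme("atomistic", "atomistic", r_short = 0.9, r_long = 1.4,
                       update_interval = 1)
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(60:140, 1)
    box <- rep(runif(1, 4.3, 5.5), 3)
    centers <- matrix(runif(3 * n) * box[1], n, 3)
    sys <- md_system(positions = centers, masses = rep(1, n),
                     charges = rep(0, n), lj_type = rep("none", n),
                     molecule_id = seq_len(n), charge_group_id = seq_len(n),
                     subsystem = rep("solvent", n), box = box)
    ent <- make_entities(sys, sch)
    bf <- build_pairlist(ent, centers, box, sch, method = "brute")
    cl <- build_pairlist(ent, centers, box, sch, method = "cell")
    ref <- oracle_classify(centers, box, 0.9, 1.4)
    expect_identical(pair_key(bf$short_pairs), pair_key(ref$short))
    expect_identical(pair_key(bf$intermediate_pairs), pair_key(ref$inter))
    expect_identical(pair_key(cl$short_pairs), pair_key(bf$short_pairs))
    expect_identical(pair_key(cl$intermediate_pairs),
                     pair_key(bf$intermediate_pairs))
  }
})

test_that("CG with singleton groups is entity-identical to AT", {
  w <- dense_water(20, 2.9, seed = 11)
  at <- make_entities(w, scheme_preset("AT"))
  cg <- make_entities(singleton_groups(w), scheme_preset("CG(cog)"))
  expect_identical(at$ptr, cg$ptr)
  expect_identical(at$atoms, cg$atoms)
  expect_identical(at$center_atom, cg$center_atom)
})
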