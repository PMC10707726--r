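test_that("per-loop rmsd matrices are symmetric, zero-diagonal and mode-labelled", {
  pair <- generate_conformer_pair(synthetic_spec(seed = 12))
  chains <- list(list(structure = pair$folded, chain = "A"),
                 list(structure = pair$folded, chain = "A"),
                 list(structure = pair$straight, chain = "A"))
  for (mode in c("core-frame", "loop-local")) {
    res <- per_loop_rmsd(chains, tsabgl_loops(), mode = mode)
    expect_equal(res$mode, mode)
    for (m in res$matrices) {
      expect_equal(m, t(m))
      expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
    }
    # duplicated structure: off-diagonal entry between the copies is 0
    expect_lt(res$matrices$L3[1, 2], 1e-9)
  }
})

test_that("the swung loop dominates every per-loop rmsd summary", {
  pair <- generate_conformer_pair(synthetic_spec(seed = 4))
  chains <- list(list(structure = pair$folded, chain = "A"),
                 list(structure = pair$straight, chain = "A"))
  for (mode in c("core-frame", "loop-local")) {
    res <- per_loop_rmsd(chains, tsabgl_loops(), mode = mode)
    s <- res$summary
    expect_gt(s$max[s$loop == "L3"], 5 * max(s$max[s$loop != "L3"]))
  }
  expect_error(per_loop_rmsd(chains, list(region_spec("L9", 900, 910))),
               "unresolvable")
})

test_that("a loop perturbed at sigma 0.3 shows the largest loop-local rmsd", {
  loops <- tsabgl_loops()
  hits <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    spec <- synthetic_spec(noise_sigma = 0.05, loop_noise_sigma = 0.3,
                           swing_amplitude = 0, seed = seed)
    e1 <- generate_structure(spec, id = "e1")$structure
    e2 <- generate_structure(synthetic_spec(noise_sigma = 0.05,
                                            loop_noise_sigma = 0.3,
                                            swing_amplitude = 0,
                                            seed = seed + 1000),
                             id = "e2")$structure
    res <- per_loop_rmsd(list(list(structure = e1, chain = "A"),
                              list(structure = e2, chain = "A")),
                         loops, mode = "loop-local")
    if (res$summary$loop[which.max(res$summary$max)] == "L3") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("conformer classification is threshold-monotone and localizes the swing", {
  spec <- synthetic_spec(swing_amplitude = 6, noise_sigma = 0, seed = 2)
  pair <- generate_conformer_pair(spec)
  loops <- tsabgl_loops()
  prof_self <- displacement_profile(pair$folded, pair$folded, "A", "A",
                                    exclude = loops)
  self <- classify_conformer(prof_self)
  expect_equal(self$label, "reference-equal")
  expect_lt(self$max_disp, 1e-9)
  prof <- displacement_profile(pair$folded, pair$straight, "A", "A",
                               exclude = loops)
  cl <- classify_conformer(prof, region = loops$L3,
                           alternate_label = "straight")
  expect_equal(cl$label, "straight")
  expect_equal(cl$max_disp, 6, tolerance = 0.05)
  expect_equal(cl$max_residue, pair$folded$atoms$resno[
    which.max(pair$truth$planted_displacement)][1])
  # raising the threshold can only move labels toward reference-equal
  lab <- function(thr) classify_conformer(prof, region = loops$L3,
                                          threshold = thr)$label
  states <- vapply(c(1, 3, 5.9, 6.5, 20), lab, "")
  flipped <- which(states == "reference-equal")
  expect_true(all(diff(flipped) == 1) && tail(states, 1) == "reference-equal")
  expect_error(classify_conformer(prof, region = region_spec("z", 900, 920)),
               "absent")
})

test_that("pocket geometry recovers constructed distances and rigid invariance", {
  # two 5-residue loops laid on parallel lines 5 angstrom apart
  la <- make_atoms("CA", seq(0, 16, by = 4), 0, 0, 10:14, resid = "GLY")
  lb <- make_atoms("CA", seq(0, 16, by = 4), 5, 0, 30:34, resid = "GLY")
  s <- make_structure(la, lb)
  pg <- pocket_geometry(s, "A", l2 = region_spec("L2", 10, 14),
                        l3 = region_spec("L3", 30, 34))
  expect_equal(pg$min_l2_l3, 5, tolerance = 1e-9)
  expect_equal(pg$entrance_width, sqrt(16^2 + 25), tolerance = 1e-9)
  expect_match(pg$definition, "L2 vs L3")
  # shared atom position: zero gap
  lc <- make_atoms("CA", c(0, 4), 0, 0, 50:51, resid = "GLY")
  s2 <- make_structure(la, lc)
  expect_equal(pocket_geometry(s2, "A", region_spec("L2", 10, 14),
                               region_spec("L3", 50, 51))$min_l2_l3, 0)
  # explicit rim pairs and rigid-transform invariance
  pg_rim <- pocket_geometry(s, "A", region_spec("L2", 10, 14),
                            region_spec("L3", 30, 34),
                            rim_pairs = rbind(c(10, 34), c(14, 30)))
  R0 <- random_rotation_matrix()
  s3 <- s
  xyz <- sweep(as.matrix(s3$atoms[, c("x", "y", "z")]) %*% t(R0), 2,
               c(-3, 8, 1), "+")
  s3$atoms$x <- xyz[, 1]; s3$atoms$y <- xyz[, 2]; s3$atoms$z <- xyz[, 3]
  pg3 <- pocket_geometry(s3, "A", region_spec("L2", 10, 14),
                         region_spec("L3", 30, 34),
                         rim_pairs = rbind(c(10, 34), c(14, 30)))
  expect_equal(pg3$min_l2_l3, pg$min_l2_l3, tolerance = 1e-6)
  expect_equal(pg3$entrance_width, pg_rim$entrance_width, tolerance = 1e-6)
})

test_that("net formal charge follows the residue charge table", {
  expect_equal(loop_charge("GGGG"), 0)
  expect_equal(loop_charge("DEKR"), 0)
  expect_equal(loop_charge("DDE"), -3)
  expect_equal(loop_charge("DDDDK"), -3)   # 4 Asp + 1 Lys
  expect_equal(loop_charge("HHH"), 0)      # His neutral by convention
  # from a structure region, counting each residue once
  atoms <- rbind(
    make_atoms("CA", 0, 0, 0, 1, resid = "ASP"),
    make_atoms(c("CA", "CB"), c(4, 5), 0, 0, 2, resid = "ASP"),
    make_atoms("CA", 8, 0, 0, 3, resid = "LYS"),
    make_atoms("CA", 12, 0, 0, 4, resid = "GLY")
  )
  s <- make_structure(atoms)
  expect_equal(loop_charge(s, region_spec("r", 1, 4)), -1)
  expect_error(loop_charge(s, region_spec("r", 50, 60)), "no residues")
})
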