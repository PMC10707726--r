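test_that("self-fit gives zero rmsd, identity rotation, zero translation", {
  set.seed(41)
  P <- matrix(rnorm(30), 10, 3)
  f <- kabsch_fit(P, P)
  expect_lt(f$rmsd, 1e-12)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f$translation, rep(0, 3), tolerance = 1e-9)
  expect_true(all(f$kept_mask))
  expect_equal(f$n_cycles_run, 0L)
})

test_that("a planted rigid transform is recovered exactly", {
  set.seed(42)
  for (rep in 1:10) {
    P <- matrix(rnorm(45), 15, 3) * 4
    R0 <- random_rotation_matrix()
    t0 <- rnorm(3, sd = 5)
    Q <- sweep(P %*% t(R0), 2, t0, "+")
    f <- kabsch_fit(P, Q)
    expect_lt(f$rmsd, 1e-9)
    expect_equal(f$rotation, R0, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(f$translation, t0, tolerance = 1e-6, ignore_attr = TRUE)
    # proper rotation invariant
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(f$rotation), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("the proper-rotation constraint is enforced on mirror-image sets", {
  # Q is a reflection of a chiral 4-point set: rmsd 0 is reachable only by
  # an improper transform, which the fit must refuse
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0.5, 0.5, 1.5))
  Q <- P
  Q[, 3] <- -Q[, 3]
  f <- kabsch_fit(P, Q)
  expect_gt(f$rmsd, 0.1)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  # and it still attains the best achievable proper rotation (grid oracle)
  set.seed(7)
  grid <- random_rotations(1e5)
  expect_lte(f$rmsd, grid_min_rmsd(P, Q, grid) + 1e-6)
})

test_that("degenerate inputs are refused", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "degenerate")
  expect_error(kabsch_fit(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  expect_error(kabsch_fit(matrix(rnorm(9), 3, 3), matrix(rnorm(12), 4, 3)),
               "pairing")
})

test_that("rmsd matches the direct formula and closed-form cases", {
  expect_equal(rmsd(diag(3), diag(3)), 0)
  # two single points at distance d
  expect_equal(rmsd(rbind(c(0, 0, 0)), rbind(c(0, 3, 4))), 5)
  set.seed(13)
  P <- matrix(rnorm(60), 20, 3)
  Q <- matrix(rnorm(60), 20, 3)
  expect_equal(rmsd(P, Q), sqrt(sum((P - Q)^2) / 20), tolerance = 1e-12)
  # symmetry after superposition
  expect_equal(rmsd(P, Q, superpose = TRUE), rmsd(Q, P, superpose = TRUE),
               tolerance = 1e-9)
})

test_that("fitted rmsd agrees with an independent rigid-fit implementation", {
  set.seed(99)
  for (rep in 1:5) {
    P <- matrix(rnorm(90), 30, 3) * 3
    Q <- P %*% t(random_rotation_matrix()) + matrix(rnorm(90, sd = 0.5), 30, 3)
    ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
    expect_equal(kabsch_fit(P, Q)$rmsd, ref, tolerance = 1e-3)
  }
})

test_that("rmsd and displacement profiles are invariant under a common rigid transform", {
  set.seed(3)
  P <- matrix(rnorm(90), 30, 3)
  Q <- P + matrix(rnorm(90, sd = 0.3), 30, 3)
  R0 <- random_rotation_matrix()
  t0 <- c(3, -2, 7)
  move <- function(X) sweep(X %*% t(R0), 2, t0, "+")
  expect_equal(rmsd(move(P), move(Q)), rmsd(P, Q), tolerance = 1e-6)
  expect_equal(rmsd(move(P), move(Q), superpose = TRUE),
               rmsd(P, Q, superpose = TRUE), tolerance = 1e-6)
  spec <- synthetic_spec(n_residues = 60,
                         loop_spans = list(LA = region_spec("LA", 20, 30)),
                         flexible_loop = "LA", swing_amplitude = 4,
                         noise_sigma = 0, seed = 5)
  pair <- generate_conformer_pair(spec)
  prof <- displacement_profile(pair$folded, pair$straight, "A", "A",
                               exclude = list(region_spec("LA", 20, 30)))
  moved <- pair$straight
  xyz <- move(as.matrix(moved$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  prof2 <- displacement_profile(pair$folded, moved, "A", "A",
                                exclude = list(region_spec("LA", 20, 30)))
  expect_equal(prof2$displacement, prof$displacement, tolerance = 1e-6)
})

test_that("outlier-free refinement equals the plain fit after one cycle", {
  set.seed(21)
  P <- matrix(rnorm(150), 50, 3) * 5
  Q <- P + matrix(rnorm(150, sd = 0.1), 50, 3)
  plain <- kabsch_fit(P, Q)
  ref <- refine_superposition(P, Q)
  expect_equal(ref$rmsd, plain$rmsd, tolerance = 1e-9)
  expect_true(all(ref$kept_mask))
  expect_equal(ref$n_cycles_run, 1L)
})

test_that("a planted outlier is rejected and the kept rmsd recovers the noise level", {
  sigma <- 0.1
  hits <- 0
  set.seed(77)
  for (rep in 1:20) {
    P <- matrix(rnorm(150), 50, 3) * 5
    Q <- P + matrix(rnorm(150, sd = sigma), 50, 3)
    Q[7, ] <- Q[7, ] + 10
    f <- refine_superposition(P, Q)
    expect_false(f$kept_mask[7])
    # kept rmsd ~ sigma * sqrt(3), within 20%
    if (abs(f$rmsd - sigma * sqrt(3)) <= 0.2 * sigma * sqrt(3)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("kept-pair rmsd is non-increasing across refinement cycles", {
  set.seed(31)
  P <- matrix(rnorm(240), 80, 3) * 5
  Q <- P + matrix(rnorm(240, sd = 0.2), 80, 3)
  Q[c(3, 40, 77), ] <- Q[c(3, 40, 77), ] + matrix(c(8, 0, 0, 0, 6, 0, 0, 0, 9), 3, 3)
  prev <- Inf
  for (cyc in 0:5) {
    f <- refine_superposition(P, Q, max_cycles = cyc)
    expect_lte(f$rmsd, prev + 1e-12)
    prev <- f$rmsd
  }
})

test_that("displacement profiles localize planted loop motion", {
  loops <- list(LA = region_spec("LA", 30, 40))
  spec <- synthetic_spec(n_residues = 80, loop_spans = loops,
                         flexible_loop = "LA", swing_amplitude = 0,
                         noise_sigma = 0, seed = 8)
  s <- generate_structure(spec, id = "a")$structure
  # identical chains: all displacements zero
  prof0 <- displacement_profile(s, s, "A", "A")
  expect_true(all(prof0$displacement < 1e-12))
  # translate the loop residues by exactly 4 angstrom, rigid elsewhere
  s2 <- s
  in_loop <- s2$atoms$resno >= 30 & s2$atoms$resno <= 40
  s2$atoms$x[in_loop] <- s2$atoms$x[in_loop] + 4
  prof <- displacement_profile(s, s2, "A", "A", exclude = loops)
  expect_equal(max(prof$displacement[prof$resno < 30 | prof$resno > 40]), 0,
               tolerance = 1e-9)
  expect_equal(prof$displacement[prof$resno >= 30 & prof$resno <= 40],
               rep(4, 11), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(displacement_profile(s, s2, "A", "A",
                                    core = region_spec("c", 33, 34)),
               "fewer than 3")
})
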