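test_that("kabsch_superpose recovers known rigid motions and rejects reflections", {
  set.seed(21)
  for (trial in 1:20) {
    a <- matrix(stats::rnorm(60, sd = 10), 20, 3)
    Rstar <- random_rotation()
    tstar <- stats::rnorm(3, sd = 5)
    b <- sweep(a %*% t(Rstar), 2, tstar, "+")
    sup <- kabsch_superpose(a, b)       # recover the motion a -> b
    expect_lt(max(abs(sup$rotation - Rstar)), 1e-6)
    expect_lt(sup$rmsd, 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
  # identity case
  a <- matrix(stats::rnorm(30), 10, 3)
  s <- kabsch_superpose(a, a)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  # mirror image: proper rotation enforced, rmsd > 0
  m <- a; m[, 1] <- -m[, 1]
  sm <- kabsch_superpose(m, a)
  expect_equal(det(sm$rotation), 1, tolerance = 1e-9)
  expect_gt(sm$rmsd, 0.1)
  # error contracts
  expect_error(kabsch_superpose(a[1:5, ], a), "mismatch")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd is invariant under rigid motion of either input", {
  set.seed(8)
  a <- matrix(stats::rnorm(90, sd = 20), 30, 3)
  b <- a + matrix(stats::rnorm(90, sd = 1), 30, 3)
  base <- kabsch_superpose(a, b)$rmsd
  for (k in 1:5) {
    tr <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 50))
    expect_equal(kabsch_superpose(apply_transform(tr, a), b)$rmsd, base,
                 tolerance = 1e-9)
    expect_equal(kabsch_superpose(a, apply_transform(tr, b))$rmsd, base,
                 tolerance = 1e-9)
  }
})

test_that("domain_rmsd separates individual-domain from combined-domain differences", {
  ts <- make_two_state_protomers(protomer_spec(seed = 6), d1_rotation = 6)
  expect_equal(domain_rmsd(ts$reference, ts$reference, "D0"), 0, tolerance = 1e-12)
  d0 <- domain_rmsd(ts$reference, ts$rotated, "D0")
  d1 <- domain_rmsd(ts$reference, ts$rotated, "D1")
  both <- domain_rmsd(ts$reference, ts$rotated, "D0D1")
  # individual domains superpose to numerical zero (rigid-body difference
  # only); the connected D0+D1 core cannot
  expect_lt(d0, 0.1)
  expect_lt(d1, 0.1)
  expect_gt(both, 0.3)
  expect_gt(both, 10 * max(d0, d1))
  expect_error(domain_rmsd(ts$reference, ts$rotated, "D0",
                           correspondence = data.frame(a = integer(), b = integer())),
               "empty")
})

test_that("implanted D1 rotations of 2-10 degrees are recovered within 0.5", {
  for (theta in c(2, 4, 6, 8, 10)) {
    ts <- make_two_state_protomers(protomer_spec(seed = 30 + theta),
                                   d1_rotation = theta)
    rec <- domain_rotation(ts$reference, ts$rotated)
    expect_lt(abs(rec$angle - theta), 0.5)
  }
})

test_that("D1 displacement after D0 alignment grows with distance from the axis", {
  ts <- make_two_state_protomers(protomer_spec(seed = 9), d1_rotation = 6)
  d <- domain_rotation(ts$reference, ts$rotated)$displacements
  expect_gt(stats::cor(d$radius, d$displacement, method = "spearman"), 0.9)
})

test_that("five-subunit complex extraction and neighbor bookkeeping", {
  p <- make_protomer(protomer_spec(seed = 10))
  f <- apply_symmetry(p, helical_symmetry(4.72, 65.30), count = 17)
  blocks <- extract_five_subunit_complex(f)
  expect_named(blocks, c("S0", "S+5", "S+6", "S+11", "S+16"))
  expect_identical(unique_contact_indices(), c(0L, 5L, 6L, 11L, 16L))
  # each block superposes onto the protomer exactly
  ca <- cbind(p$atoms$x, p$atoms$y, p$atoms$z)[p$atoms$atom == "CA", ]
  for (b in blocks) expect_lt(kabsch_superpose(b, ca)$rmsd, 1e-9)
  short <- apply_symmetry(p, helical_symmetry(4.72, 65.30), count = 10)
  expect_error(extract_five_subunit_complex(short), "lacks")
})

test_that("packing RMSD matrix clusters synthetic filaments by hand", {
  sym_l <- helical_symmetry(4.72, 65.30)
  sym_r <- helical_symmetry(4.65, 65.81)
  idx <- unique_contact_indices()
  fils <- list()
  for (i in 1:4) {
    ts <- make_two_state_protomers(protomer_spec(seed = i), d1_rotation = 6)
    fils[[paste0("L", i)]] <- apply_symmetry(ts$reference, sym_l, indices = idx)
    fils[[paste0("R", i)]] <- apply_symmetry(ts$rotated, sym_r, indices = idx)
  }
  m <- packing_rmsd_matrix(fils)
  expect_equal(m$values, t(m$values))
  expect_equal(diag(m$values), rep(0, 8), ignore_attr = TRUE)
  hand <- rep(c("L", "R"), 4)
  same <- outer(hand, hand, "==") & upper.tri(m$values)
  diff <- outer(hand, hand, "!=") & upper.tri(m$values)
  expect_lt(mean(m$values[same]), mean(m$values[diff]))
  # between-hand packing RMSD falls in the observed 1.5 - 3.3 A range
  expect_gt(mean(m$values[diff]), 1.5)
  expect_lt(mean(m$values[diff]), 3.3)
  # duplicate filament gives a zero off-diagonal entry
  dup <- packing_rmsd_matrix(list(a = fils$L1, b = fils$L1))
  expect_equal(dup$values["a", "b"], 0, tolerance = 1e-9)
  # clustering behavior at the three canonical thresholds
  part <- cluster_by_hand(m)                       # default 1.5 A
  expect_equal(length(unique(part)), 2L)
  expect_true(all(tapply(hand, part, function(h) length(unique(h)) == 1)))
  expect_equal(length(unique(cluster_by_hand(m, threshold = 10))), 1L)
  expect_equal(length(unique(cluster_by_hand(m, threshold = 0))), 8L)
  expect_error(packing_rmsd_matrix(fils[1]), "at least 2")
})

test_that("residue_pair_distance measures generator-placed distances", {
  p <- make_protomer(protomer_spec(seed = 12))
  sym <- helical_symmetry(4.72, 65.30)
  f <- apply_symmetry(p, sym, count = 12)
  # same residue, same subunit
  expect_equal(residue_pair_distance(f, 50, 50), 0)
  # oracle: compute the expected distance directly from the screw transform
  ca <- cbind(p$atoms$x, p$atoms$y, p$atoms$z)[p$atoms$atom == "CA", ]
  r47_s11 <- apply_transform(subunit_transform(sym, 11), ca[47, , drop = FALSE])
  truth <- sqrt(sum((r47_s11 - ca[143, ])^2))
  expect_equal(residue_pair_distance(f, 47, 143, offset_i = 11, offset_j = 0),
               truth, tolerance = 1e-12)
  expect_error(residue_pair_distance(f, 999, 50), "not modeled")
})
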