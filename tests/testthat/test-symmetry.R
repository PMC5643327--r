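test_that("normalize_twist wraps into (-180, 180] with the boundary at +180", {
  expect_equal(normalize_twist(65.30), 65.30)
  expect_equal(normalize_twist(718.30), -1.70)
  expect_equal(normalize_twist(180), 180)
  expect_equal(normalize_twist(-180), 180)
  expect_equal(normalize_twist(c(-361, 361, 0)), c(-1, 1, 0))
  expect_error(normalize_twist(NaN), "finite")
  expect_error(normalize_twist(Inf), "finite")
  # wrap invariance: property over random angles
  set.seed(42)
  a <- stats::runif(200, -1000, 1000)
  expect_equal(normalize_twist(a + 360), normalize_twist(a))
  expect_equal(normalize_twist(a - 360), normalize_twist(a))
  expect_true(all(normalize_twist(a) > -180 & normalize_twist(a) <= 180))
})

test_that("helical_symmetry validates and wraps; +-360 gives identical objects", {
  sym <- helical_symmetry(4.72, 65.30)
  expect_s3_class(sym, "helical_symmetry")
  # wrap invariance holds to within an ulp of 360 (the +-360 shift itself
  # rounds in double precision, so strict bit identity is unattainable)
  expect_equal(helical_symmetry(4.72, 65.30 + 360)$twist, sym$twist,
               tolerance = 1e-12)
  expect_equal(helical_symmetry(4.72, 65.30 - 360)$twist, sym$twist,
               tolerance = 1e-12)
  expect_identical(sym, helical_symmetry(4.72, normalize_twist(65.30)))
  expect_error(helical_symmetry(0, 65), "rise")
  expect_error(helical_symmetry(-1, 65), "rise")
})

test_that("start_family reproduces the published 11-start tilts and family signs", {
  # L-type: 11 x 65.30 wraps to -1.70 (left); R-type: 11 x 65.81 to +3.91
  L <- start_family(helical_symmetry(4.72, 65.30), 11)
  expect_equal(L$step_twist, -1.70, tolerance = 1e-12)
  expect_identical(L$handedness, "left")
  R <- start_family(helical_symmetry(4.65, 65.81), 11)
  expect_equal(R$step_twist, 3.91, tolerance = 1e-10)
  expect_identical(R$handedness, "right")
  # magnitudes by direct arithmetic: 5-start -33.5 left, 6-start +31.8 right
  sym <- helical_symmetry(4.72, 65.30)
  f5 <- start_family(sym, 5); f6 <- start_family(sym, 6); f1 <- start_family(sym, 1)
  expect_equal(f5$step_twist, 5 * 65.30 - 360, tolerance = 1e-12)   # -33.5
  expect_equal(f6$step_twist, 6 * 65.30 - 360, tolerance = 1e-12)   # +31.8
  expect_identical(c(f1$handedness, f5$handedness, f6$handedness),
                   c("right", "left", "right"))
  expect_equal(f5$step_rise, 5 * 4.72)
  expect_equal(f5$strand_pitch, 360 / 33.5 * 5 * 4.72)
  expect_equal(f1$bessel_order, 1L)
  expect_equal(f5$bessel_order, -5L)
  expect_error(start_family(sym, 0), "positive")
})

test_that("handedness suite holds for all nine published parameter sets", {
  for (i in seq_len(nrow(table1))) {
    sym <- helical_symmetry(table1$rise[i], table1$twist[i])
    expect_identical(start_family(sym, 1)$handedness, "right", label = table1$mutant[i])
    expect_identical(start_family(sym, 5)$handedness, "left", label = table1$mutant[i])
    expect_identical(start_family(sym, 6)$handedness, "right", label = table1$mutant[i])
    expect_identical(start_family(sym, 11)$handedness, table1$hand_11[i],
                     label = table1$mutant[i])
    expect_identical(protofilament_count(sym), 11L, label = table1$mutant[i])
  }
})

test_that("enumerate_families lists 1..n_max consistently with start_family", {
  sym <- helical_symmetry(4.72, 65.30)
  fams <- enumerate_families(sym, 11)
  expect_equal(nrow(fams), 11L)
  expect_identical(fams$handedness[11], "left")
  for (n in c(1L, 5L, 11L)) {
    f <- start_family(sym, n)
    expect_equal(fams$step_twist[n], f$step_twist)
    expect_equal(fams$layer_line_height[n], f$layer_line_height)
  }
  expect_equal(enumerate_families(sym, 1)$step_twist, start_family(sym, 1)$step_twist)
  # wrap invariance of the whole listing (to rounding of the 360 shift)
  expect_equal(fams, enumerate_families(helical_symmetry(4.72, 425.30), 11),
               tolerance = 1e-12)
  expect_error(enumerate_families(sym, 0), ">= 1")
})

test_that("protofilament_count minimizes the wrapped step twist", {
  # exact 11-in-2-turns repeat: residual exactly 0
  expect_identical(protofilament_count(helical_symmetry(4.7, 720 / 11)), 11L)
  # 7-protofilament case (2 turns / 7 subunits), brute-force check
  sym7 <- helical_symmetry(5, 2 * 360 / 7)
  n <- 2:15
  resid <- abs(normalize_twist(n * sym7$twist))
  expect_identical(protofilament_count(sym7), n[which.min(resid)])
  expect_identical(protofilament_count(sym7), 7L)
  # tie-break toward smaller n: twist 90 gives residual 0 at n = 4, 8, 12
  expect_identical(protofilament_count(helical_symmetry(5, 90)), 4L)
  expect_error(protofilament_count(helical_symmetry(5, 90), n_max = 1), ">= 2")
})

test_that("principal_layer_line matches hand computation and bound", {
  sym <- helical_symmetry(4.72, 65.30)
  expect_equal(principal_layer_line(sym, 1), 0.03843, tolerance = 2e-4)
  expect_equal(principal_layer_line(sym, 11), -0.00100, tolerance = 1e-2)
  # exact repeat: layer line on the equator
  expect_equal(principal_layer_line(helical_symmetry(4.72, 720 / 11), 11), 0)
  # bound |Z| <= 1/(2 rise), property over random symmetries
  set.seed(7)
  for (k in 1:50) {
    s <- helical_symmetry(stats::runif(1, 1, 10), stats::runif(1, -180, 180))
    n <- sample(1:30, 1)
    expect_lte(abs(principal_layer_line(s, n)), 1 / (2 * s$rise) + 1e-12)
  }
})

test_that("principal_layer_line agrees with the brute-force structure-factor oracle", {
  # spot check here; the full nine-parameter-set sweep runs in test-acceptance
  sym <- helical_symmetry(4.72, 65.30)
  for (n in c(1L, 11L)) {
    o <- oracle_layer_line(sym$rise, sym$twist, n)
    expect_lt(abs(principal_layer_line(sym, n) - o$Z), 2 * o$spacing)
  }
})

test_that("seam_supersymmetry reproduces the published 22-subunit numbers", {
  sym <- helical_symmetry(4.61, 65.75)
  ss <- seam_supersymmetry(sym, 22)
  expect_equal(ss$super_rise, 22 * 4.61)          # 101.42, paper prints 101.5
  expect_equal(ss$super_rise, 101.5, tolerance = 1e-3)
  # with the refined rotation the printed chain of numbers follows
  ssr <- seam_supersymmetry(sym, 22, super_twist = 6.41)
  expect_equal(ssr$units_per_turn, 56.16, tolerance = 1e-4)
  expect_equal(ssr$super_pitch, 5700, tolerance = 2e-3)
  # k = 1 reduces to the base symmetry
  s1 <- seam_supersymmetry(sym, 1)
  expect_equal(s1$super_rise, sym$rise)
  expect_equal(s1$super_twist, sym$twist)
  expect_error(seam_supersymmetry(sym, 0), ">= 1")
})

test_that("k base screw steps equal one supersymmetry step (composition invariant)", {
  set.seed(11)
  pts <- matrix(stats::runif(300, -60, 60), 100, 3)
  for (case in list(c(4.61, 65.75, 22), c(4.72, 65.30, 5), c(3.9, -17.0, 7))) {
    sym <- helical_symmetry(case[1], case[2])
    k <- as.integer(case[3])
    ss <- seam_supersymmetry(sym, k)
    step <- subunit_transform(sym, 1)
    acc <- pts
    for (j in seq_len(k)) acc <- apply_transform(step, acc)
    once <- apply_transform(subunit_transform(ss, 1), pts)
    expect_lt(max(abs(acc - once)), 1e-9)
  }
})
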