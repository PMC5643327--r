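test_that("curvature_twist limits and hand-computed example", {
  # straight limit: D = 0
  straight <- curvature_twist(2.5, 0)
  expect_equal(straight$kappa, 0)
  expect_equal(straight$tau, 2 * pi / 2.5)
  # circle limit: P -> 0 with D fixed
  circ <- curvature_twist(1e-9, 0.8)
  expect_equal(circ$kappa, 1 / 0.4, tolerance = 1e-6)
  expect_equal(circ$tau, 0, tolerance = 1e-6)
  # independent hand computation: P = 2.0, D = 0.5
  kt <- curvature_twist(2.0, 0.5)
  r <- 0.25; h <- 2 / (2 * pi)
  expect_equal(kt$kappa, r / (r^2 + h^2))
  expect_equal(kt$tau, h / (r^2 + h^2))
  expect_equal(kt$kappa, 1.526, tolerance = 1e-3)
  expect_equal(kt$tau, 1.943, tolerance = 1e-3)
  expect_error(curvature_twist(0, 0.5), "positive")
  expect_error(curvature_twist(2, -1), ">= 0")
})

test_that("kappa^2 + tau^2 identity and monotonicity properties", {
  set.seed(15)
  P <- stats::runif(200, 0.5, 6); D <- stats::runif(200, 0, 2)
  kt <- curvature_twist(P, D)
  expect_equal(kt$kappa^2 + kt$tau^2, 1 / ((D / 2)^2 + (P / (2 * pi))^2),
               tolerance = 1e-14)
  # at fixed D > 0, kappa strictly decreases with increasing P
  kk <- curvature_twist(seq(0.5, 6, by = 0.25), 0.6)$kappa
  expect_true(all(diff(kk) < 0))
})

test_that("pitch_diameter inverts curvature_twist to machine precision", {
  set.seed(16)
  P <- stats::runif(1000, 0.2, 8); D <- stats::runif(1000, 0, 3)
  kt <- curvature_twist(P, D)
  pd <- pitch_diameter(kt$kappa, kt$tau)
  expect_equal(pd$P, P, tolerance = 1e-12)
  expect_equal(pd$D, D, tolerance = 1e-12)
  # straight case
  pd0 <- pitch_diameter(0, 2)
  expect_equal(pd0$D, 0)
  expect_equal(pd0$P, pi)
  # hand example inverse
  inv <- pitch_diameter(1.526054, 1.943033)
  expect_equal(c(inv$P, inv$D), c(2.0, 0.5), tolerance = 1e-5)
  expect_error(pitch_diameter(0, 0), "zero")
})

test_that("measure_pitch_diameter recovers noise-free and noisy traces", {
  # exact recovery without noise
  tr <- make_waveform_traces(waveform_spec(seed = 1, P = 2.2, D = 0.6,
                                           noise_sd = 0, n_traces = 1))[[1]]
  m <- measure_pitch_diameter(tr)
  expect_equal(m$P, 2.2, tolerance = 1e-6)
  expect_equal(m$D, 0.6, tolerance = 1e-6)
  expect_false(m$indeterminate)
  # ten noisy traces: mean recovered P and D within 5 percent
  traces <- make_waveform_traces(waveform_spec(seed = 2, P = 2.2, D = 0.6,
                                               noise_sd = 0.02, n_traces = 10))
  ws <- waveform_summary(traces)
  means <- ws$summary[ws$summary$stat == "mean", ]
  expect_equal(means$P, 2.2, tolerance = 0.05)
  expect_equal(means$D, 0.6, tolerance = 0.05)
  # straight trace: amplitude below the noise floor, pitch indeterminate
  s <- seq(0, 6, by = 0.05)
  flat <- waveform_trace(s, stats::rnorm(length(s), 0, 0.01), id = "straight")
  mf <- measure_pitch_diameter(flat)
  expect_true(mf$indeterminate)
  expect_true(is.na(mf$P))
  expect_lt(mf$D, 0.1)
  # trace spanning less than one period errors
  short <- waveform_trace(seq(0, 0.5, by = 0.01),
                          0.3 * sin(2 * pi * seq(0, 0.5, by = 0.01) / 2.2) + 0.3,
                          id = "short")
  expect_error(measure_pitch_diameter(short), "period|span")
})

test_that("recovery property: median relative error < 3 percent over random waveforms", {
  set.seed(17)
  errs <- t(replicate(100, {
    P <- stats::runif(1, 1, 5); D <- stats::runif(1, 0.2, 1)
    tr <- make_waveform_traces(waveform_spec(seed = sample.int(1e6, 1), P = P,
                                             D = D, noise_sd = 0.02,
                                             n_traces = 1))[[1]]
    m <- measure_pitch_diameter(tr)
    c(abs(m$P - P) / P, abs(m$D - D) / D)
  }))
  expect_lt(stats::median(errs[, 1]), 0.03)
  expect_lt(stats::median(errs[, 2]), 0.03)
})

test_that("waveform_summary aggregates per strain and preserves ordering", {
  one <- waveform_summary(make_waveform_traces(
    waveform_spec(seed = 3, noise_sd = 0, n_traces = 1)))
  expect_equal(one$summary[one$summary$stat == "sd", c("P", "D")],
               data.frame(P = 0, D = 0), ignore_attr = TRUE)
  # two strains with distinct (P, D) keep distinct, correctly ordered centers
  a <- waveform_summary(make_waveform_traces(
    waveform_spec(seed = 4, P = 1.5, D = 0.4, n_traces = 5)))
  b <- waveform_summary(make_waveform_traces(
    waveform_spec(seed = 5, P = 3.0, D = 0.8, n_traces = 5)))
  ma <- a$summary[1, ]; mb <- b$summary[1, ]
  expect_gt(ma$kappa, mb$kappa)     # smaller, fatter supercoil curves more
  expect_gt(ma$tau, mb$tau)
  expect_gt(mb$P, ma$P)
})

test_that("trace CSV round-trips", {
  traces <- make_waveform_traces(waveform_spec(seed = 6, n_traces = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(traces, path)
  back <- read_trace_csv(path)
  expect_length(back, 3L)
  expect_equal(back[[1]]$x, traces[[1]]$x, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_trace_csv(bad), "columns")
})
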