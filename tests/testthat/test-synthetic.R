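test_that("phantom generation is deterministic and internally consistent", {
  sp <- phantom_spec()
  p1 <- make_phantom(sp); p2 <- make_phantom(sp)
  expect_identical(p1$m0, p2$m0)
  expect_identical(p1$t2, p2$t2)
  expect_identical(p1$landmarks, p2$landmarks)
  # brain fits inside the skull shell; compartments partition the brain
  expect_false(any(p1$masks$brain & p1$masks$skull))
  expect_identical(p1$masks$brain, p1$masks$white | p1$masks$grey)
  expect_false(any(p1$masks$white & p1$masks$grey))
  # identical grey/white parameters give a constant in-brain T2 truth
  pu <- make_phantom(phantom_spec(white = list(m0 = 8000, t1 = 180, t2 = 75)))
  expect_equal(diff(range(pu$t2[pu$masks$brain])), 0)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(grid = c(10, 8, 8), skull_width_mm = 4),
               class = "zfqmri_validation_error")
  expect_error(phantom_spec(brain_width_mm = 3, skull_width_mm = 2),
               class = "zfqmri_validation_error")
  expect_error(phantom_spec(noise_sigma = -1),
               class = "zfqmri_domain_error")
})

test_that("noiseless motion-free series equals the signal model exactly", {
  ph <- tiny_phantom()
  s2 <- simulate_series(ph, "T2")
  inb <- ph$masks$brain
  for (i in seq_along(acq_te)) {
    expected <- t2_signal(ph$m0[inb], ph$t2[inb], acq_te[i])
    expect_equal(s2$series$volumes[[i]]$data[inb], expected)
    expect_true(all(s2$series$volumes[[i]]$data[!inb] == 0))
  }
  s1 <- simulate_series(ph, "T1")
  expect_equal(s1$series$times_ms, c(50, 150, 275, 450, 600))
  expect_equal(s1$series$volumes[[3]]$data[inb],
               t1_signal(ph$m0[inb], ph$t1[inb], 275))
})

test_that("a TE = 0 volume reproduces the M0 truth map", {
  ph <- tiny_phantom()
  s <- simulate_series(ph, "T2", times_ms = c(1e-9, acq_te))
  expect_equal(s$series$volumes[[1]]$data, ph$m0, tolerance = 1e-9)
})

test_that("series simulation is reproducible from its seed", {
  ph <- tiny_phantom()
  a <- simulate_series(ph, "T2", noise_sigma = 80, seed = 33)
  b <- simulate_series(ph, "T2", noise_sigma = 80, seed = 33)
  for (i in 1:3)
    expect_identical(a$series$volumes[[i]]$data, b$series$volumes[[i]]$data)
  c <- simulate_series(ph, "T2", noise_sigma = 80, seed = 34)
  expect_false(identical(a$series$volumes[[1]]$data,
                         c$series$volumes[[1]]$data))
})

test_that("Rician sample mean matches the numerical-integration oracle", {
  set.seed(19)
  for (case in list(c(3400, 170), c(1200, 120))) {
    nu <- case[1]; sigma <- case[2]
    draws <- rician_noise(rep(nu, 1e4), sigma)
    truth <- rician_mean_oracle(nu, sigma)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - truth), 3 * se)
    # high-SNR expansion agrees with the integral
    expect_equal(truth, sqrt(nu^2 + 2 * sigma^2),
                 tolerance = (sigma / nu)^2)
  }
  expect_error(rician_noise(1, -0.1), class = "zfqmri_domain_error")
})

test_that("injected motion moves the landmarks with the image", {
  ph <- tiny_phantom()
  T <- rigid2d(0.02, 0.8, -0.6)
  s <- simulate_series(ph, "T2", motion = list(NULL, T, NULL))
  base <- s$landmarks[[1]]
  moved <- s$landmarks[[2]]
  expect_equal(as.matrix(moved[, c("x", "y")]),
               transform_points(T, as.matrix(base[, c("x", "y")])),
               ignore_attr = TRUE)
})

test_that("cohorts are reproducible and carry the declared group deltas", {
  c1 <- simulate_cohort(n_per_group = 3, seed = 5)
  c2 <- simulate_cohort(n_per_group = 3, seed = 5)
  expect_identical(c1, c2)
  # zero variability: specimens differ only by the group deltas
  c0 <- simulate_cohort(n_per_group = 1, cv_size = 0, cv_t2 = 0, seed = 2)
  expect_identical(c0[[1]]$genotype, "wildtype")
  expect_identical(c0[[2]]$genotype, "mutant")
  expect_equal(c0[[1]]$spec$brain_length_mm / c0[[1]]$spec$skull_width_mm,
               1.11)
  expect_equal(c0[[2]]$spec$brain_length_mm / c0[[2]]$spec$skull_width_mm,
               0.933)
  expect_gt(c0[[2]]$spec$white$t2, c0[[1]]$spec$white$t2)
})

test_that("cohort size variability has the declared CV", {
  co <- simulate_cohort(n_per_group = 300, cv_size = 0.05, seed = 8)
  lens <- vapply(co[1:300], function(s) s$spec$brain_length_mm, 0)
  expect_equal(sd(lens) / mean(lens), 0.05, tolerance = 0.2)
})

test_that("fiber sets are deterministic with exact truth for clean circles", {
  f1 <- make_fiber_set(25, 0.6, 0.05, seed = 44)
  f2 <- make_fiber_set(25, 0.6, 0.05, seed = 44)
  expect_identical(f1$contours, f2$contours)
  met <- fiber_metrics_table(f1$contours)
  # jitter-free circular contours: measured g equals drawn g exactly
  expect_equal(met$g_ratio, f1$truth$g_true, tolerance = 1e-12)
})

test_that("large fiber samples recover the declared mean", {
  fs <- make_fiber_set(10000, 0.5, 0.08, seed = 13)
  g <- fs$truth$g_true
  expect_lt(abs(mean(g) - 0.5), 3 * 0.08 / sqrt(10000) + 1e-3)
})

test_that("generated artifacts round-trip through the readers", {
  ph <- tiny_phantom()
  d <- withr::local_tempdir()
  write_landmarks(structure(list(truth = ph$landmarks),
                            class = "zf_landmarks"),
                  file.path(d, "lm.tsv"))
  lm <- read_landmarks(file.path(d, "lm.tsv"))
  expect_equal(lm[["truth"]]$x, ph$landmarks$x)
  write_roi_spec(ph$roi, file.path(d, "roi.yaml"))
  roi <- read_roi_spec(file.path(d, "roi.yaml"))
  expect_equal(roi$centers, ph$roi$centers)
  fs <- make_fiber_set(5, 0.6, 0.04, jitter_sd = 0.01, seed = 3)
  write_contours(fs$contours, file.path(d, "fibers.tsv"))
  fc <- read_contours(file.path(d, "fibers.tsv"))
  expect_equal(nrow(fc), nrow(fs$contours))
})
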