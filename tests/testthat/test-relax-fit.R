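test_that("noiseless voxels at the acquisition TR/TE sets are recovered", {
  # T2: truth (8000, 75) equals the initialisation, and nearby values
  for (t2 in c(46.6, 56.2, 75)) {
    f <- relax_fit(t2_signal(8000, t2, acq_te), acq_te, "T2")
    expect_lt(abs(f$t_value - t2) / t2, 0.005)
    expect_lt(abs(f$m0 - 8000) / 8000, 0.005)
  }
  for (t1 in c(150, 180, 280)) {
    f <- relax_fit(t1_signal(8000, t1, acq_tr), acq_tr, "T1")
    expect_lt(abs(f$t_value - t1) / t1, 0.005)
    expect_lt(abs(f$m0 - 8000) / 8000, 0.005)
  }
})

test_that("scaled mode recovers a wide (M0, T) grid on noiseless voxels", {
  ctl <- relax_control(mode = "scaled")
  for (m0 in c(2000, 8000, 16000)) {
    for (t2 in c(20, 75, 200)) {
      f <- relax_fit(t2_signal(m0, t2, acq_te), acq_te, "T2", ctl)
      expect_lt(abs(f$t_value - t2) / t2, 0.005)
      expect_lt(abs(f$m0 - m0) / m0, 0.005)
    }
    for (t1 in c(50, 150, 600)) {
      f <- relax_fit(t1_signal(m0, t1, acq_tr), acq_tr, "T1", ctl)
      expect_lt(abs(f$t_value - t1) / t1, 0.005)
      expect_lt(abs(f$m0 - m0) / m0, 0.005)
    }
  }
})

test_that("all-zero signal yields the degenerate flag, not an error", {
  f <- relax_fit(c(0, 0, 0), acq_te, "T2")
  expect_true(f$degenerate)
  expect_false(f$converged)
  expect_equal(f$m0, 0)
  expect_true(is.na(f$t_value))
})

test_that("non-finite or negative input is a typed error", {
  expect_error(relax_fit(c(1, NA, 3), acq_te, "T2"),
               class = "zfqmri_domain_error")
  expect_error(relax_fit(c(1, -2, 3), acq_te, "T2"),
               class = "zfqmri_domain_error")
  expect_error(relax_fit(c(1, 2), c(1, 2, 3), "T2"),
               class = "zfqmri_validation_error")
})

test_that("SSE trajectory is non-increasing for accepted steps", {
  for (mode in c("raw", "scaled")) {
    ctl <- relax_control(mode = mode, loop_limit = 5000)
    for (t2 in c(50, 90)) {
      f <- relax_fit(t2_signal(8000, t2, acq_te), acq_te, "T2", ctl,
                     trace = TRUE)
      tr <- f$trace
      expect_true(all(diff(tr) <= 1e-9 * max(tr[1], 1)),
                  label = sprintf("monotone SSE (%s mode, T2 = %g)", mode, t2))
    }
  }
})

test_that("disabling early stop forces the full loop limit", {
  ctl <- relax_control(early_stop_tol = 0, loop_limit = 500)
  f <- relax_fit(t2_signal(8000, 75, acq_te), acq_te, "T2", ctl)
  expect_identical(f$iterations, 500L)
  expect_false(f$converged)
})

test_that("scaled-mode fits are scale invariant when m0_init scales too", {
  te <- acq_te
  base <- relax_fit(t2_signal(8000, 60, te), te, "T2",
                    relax_control(mode = "scaled"))
  for (c_fac in c(0.01, 100)) {
    f <- relax_fit(t2_signal(8000 * c_fac, 60, te), te, "T2",
                   relax_control(mode = "scaled", m0_init = 8000 * c_fac))
    expect_lt(abs(f$t_value - base$t_value) / base$t_value, 1e-3)
    expect_lt(abs(f$m0 - c_fac * base$m0) / (c_fac * base$m0), 1e-3)
  }
})

test_that("gradient-descent fits agree with the independent NLS oracle", {
  # noiseless: both must sit on the same optimum
  for (t2 in c(50, 75, 95)) {
    y <- t2_signal(8000, t2, acq_te)
    gd <- relax_fit(y, acq_te, "T2")
    or <- nls_oracle_fit(y, acq_te, "T2")
    expect_lt(abs(gd$t_value - or[["t_value"]]) / or[["t_value"]], 0.01)
  }
  # noisy voxels: agreement within the descent's convergence tolerance
  set.seed(42)
  for (i in 1:5) {
    y <- rician_noise(t2_signal(8000, 70, acq_te), 100)
    gd <- relax_fit(y, acq_te, "T2")
    or <- nls_oracle_fit(y, acq_te, "T2")
    if (gd$converged)
      expect_lt(abs(gd$t_value - or[["t_value"]]) / or[["t_value"]], 0.03)
  }
})

test_that("the two-point T2 closed form is reproduced exactly", {
  # t2 = (TE2 - TE1) / log(S1 / S2)
  o <- nls_oracle_fit(c(100, 100 / exp(1)), c(10, 60), "T2")
  expect_equal(o[["t_value"]], 50, tolerance = 1e-12)
  s <- t2_signal(5000, 80, c(15, 45))
  o2 <- nls_oracle_fit(s, c(15, 45), "T2")
  expect_equal(o2[["t_value"]], 80, tolerance = 1e-12)
  expect_equal(o2[["m0"]], 5000, tolerance = 1e-9)
})

test_that("relax_fit methods are consistent with the fit", {
  y <- t2_signal(8000, 50, acq_te)
  f <- relax_fit(y, acq_te, "T2")
  expect_named(coef(f), c("m0", "t2"))
  expect_equal(unname(predict(f, acq_te)), fitted(f))
  expect_equal(residuals(f), y - fitted(f))
  expect_equal(sum(residuals(f)^2), f$sse, tolerance = 1e-8)
  sims <- simulate(f, nsim = 3, seed = 1, sigma = 10)
  expect_equal(dim(sims), c(3L, 3L))
  expect_output(print(summary(f)), "RMSE")
})
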