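lm_frame <- function(pts, names = c("lens_left", "lens_right",
                                    "vagal_lobe_tip")) {
  data.frame(name = names[seq_len(nrow(pts))], x = pts[, 1], y = pts[, 2],
             slice = 0)
}

test_that("identical landmark sets give the identity transform", {
  p <- rbind(c(10, 5), c(20, 5), c(15, 12))
  T <- estimate_rigid2d(lm_frame(p), lm_frame(p))
  expect_equal(T$theta, 0)
  expect_equal(c(T$tx, T$ty), c(0, 0))
  expect_lt(attr(T, "rms_residual"), 1e-12)
})

test_that("pure translations and rotations are recovered exactly", {
  p <- rbind(c(10, 5), c(20, 5), c(15, 12))
  T <- estimate_rigid2d(lm_frame(p), lm_frame(sweep(p, 2, c(-3, 2))))
  expect_equal(T$theta, 0)
  expect_equal(c(T$tx, T$ty), c(3, -2))

  # rotation by 10 degrees about the centroid
  th <- 10 * pi / 180
  ctr <- colMeans(p)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- t(R %*% t(sweep(p, 2, ctr))) + rep(ctr, each = 3)
  T2 <- estimate_rigid2d(lm_frame(p), lm_frame(q))
  expect_lt(abs(T2$theta - th), 1e-9)
  expect_lt(attr(T2, "rms_residual"), 1e-9)
  # exactness for any true rigid image of the source
  expect_lt(max(abs(transform_points(T2, p) - q)), 1e-9)
})

test_that("estimation is equivariant under common translations", {
  set.seed(2)
  p <- matrix(runif(8, 0, 30), 4)
  q <- transform_points(rigid2d(0.21, 1.3, -0.7), p) +
    matrix(rnorm(8, 0, 0.1), 4)
  nm <- c("a", "b", "c", "d")
  t1 <- estimate_rigid2d(lm_frame(p, nm), lm_frame(q, nm))
  shift <- c(12.5, -4)
  t2 <- estimate_rigid2d(lm_frame(sweep(p, 2, -shift), nm),
                         lm_frame(sweep(q, 2, -shift), nm))
  expect_equal(t1$theta, t2$theta, tolerance = 1e-12)
})

test_that("degenerate and underdetermined landmark sets are handled", {
  p <- rbind(c(5, 5), c(5, 5))  # coincident: rotation ill-posed
  q <- p + rep(c(1, 2), each = 2)
  T <- estimate_rigid2d(lm_frame(p, c("a", "b")), lm_frame(q, c("a", "b")))
  expect_true(attr(T, "rotation_illposed"))
  expect_equal(T$theta, 0)
  expect_equal(c(T$tx, T$ty), c(1, 2))
  expect_error(estimate_rigid2d(lm_frame(p[1, , drop = FALSE], "a"),
                                lm_frame(q[1, , drop = FALSE], "a")),
               class = "zfqmri_validation_error")
})

test_that("transform algebra: inverse composes to identity", {
  T <- rigid2d(0.3, 4.5, -2.2, center = c(10, 7))
  I <- compose_rigid2d(T, invert_rigid2d(T))
  expect_lt(abs(I$theta), 1e-10)
  expect_lt(abs(I$tx), 1e-10)
  expect_lt(abs(I$ty), 1e-10)
  p <- matrix(runif(10, 0, 20), 5)
  expect_lt(max(abs(transform_points(invert_rigid2d(T),
                                     transform_points(T, p)) - p)), 1e-10)
})

test_that("slice-wise resampling honours identity and integer shifts", {
  set.seed(3)
  v <- volume(array(runif(16 * 12 * 4), c(16, 12, 4)), 0.1)
  out <- apply_transform_slicewise(v, rigid2d())
  expect_identical(out$data, v$data)

  fwd <- apply_transform_slicewise(v, rigid2d(0, 3, -2))
  back <- apply_transform_slicewise(fwd, rigid2d(0, -3, 2))
  # interior (untouched by the border fill) restored exactly
  expect_equal(back$data[4:13, 3:10, ], v$data[4:13, 3:10, ])
})

test_that("sub-pixel shift then inverse is close on smooth images", {
  g <- c(24, 16, 3)
  x <- outer(seq_len(g[1]), seq_len(g[2]),
             function(i, j) sin(i / 8) + cos(j / 6))
  v <- volume(array(rep(x, g[3]), g) + 2, 0.1)
  fwd <- apply_transform_slicewise(v, rigid2d(0, 0.4, -0.3))
  back <- apply_transform_slicewise(fwd, rigid2d(0, -0.4, 0.3))
  i <- 4:21; j <- 4:13
  rel <- sqrt(sum((back$data[i, j, ] - v$data[i, j, ])^2) /
                sum(v$data[i, j, ]^2))
  expect_lt(rel, 1e-2)
})

test_that("align_series recovers injected motion from exact landmarks", {
  ph <- tiny_phantom()
  mo <- list(NULL, rigid2d(0.015, 0.7, -0.45), rigid2d(-0.01, -0.3, 0.55))
  sm <- simulate_series(ph, "T2", motion = mo)
  al <- align_series(sm$series, sm$landmarks, 1)
  expect_equal(al$transforms[[1]]$theta, 0)
  for (i in 2:3) {
    Ti <- invert_rigid2d(mo[[i]])
    expect_lt(abs(al$transforms[[i]]$theta - Ti$theta), 1e-9)
    expect_lt(abs(al$transforms[[i]]$tx - Ti$tx), 1e-6)
    expect_lt(abs(al$transforms[[i]]$ty - Ti$ty), 1e-6)
  }
  # no injected motion: all transforms identity, volumes untouched
  s0 <- simulate_series(ph, "T2")
  al0 <- align_series(s0$series, s0$landmarks, 1)
  for (T in al0$transforms) expect_equal(c(T$theta, T$tx, T$ty), c(0, 0, 0))
  expect_identical(al0$series$volumes[[2]]$data, s0$series$volumes[[2]]$data)
})

test_that("landmark jitter of 0.25 px keeps translation error under 0.2 px", {
  set.seed(7)
  p <- rbind(c(15.5, 9.5), c(31.5, 9.5), c(23.5, 17.5))
  ctr <- colMeans(p)
  # translation error measured as the displacement error at the landmark
  # centroid, where the rotational component has no lever arm: this is the
  # registration error the aligned image actually sees
  errs <- replicate(50, {
    true <- rigid2d(runif(1, -0.02, 0.02), runif(1, -1, 1), runif(1, -1, 1))
    q <- transform_points(true, p) + matrix(rnorm(6, 0, 0.25), 3)
    T <- estimate_rigid2d(lm_frame(p), lm_frame(q))
    sqrt(sum((transform_points(T, rbind(ctr)) -
                transform_points(true, rbind(ctr)))^2))
  })
  expect_lt(median(errs), 0.2)
})

test_that("volume averaging is the voxelwise mean with 1/sqrt(N) noise", {
  v <- volume(array(runif(60), c(5, 4, 3)), 0.1)
  expect_identical(average_volumes(list(v))$data, v$data)
  w <- volume(2 - v$data, 0.1)
  expect_equal(average_volumes(list(v, w))$data, array(1, c(5, 4, 3)))
  expect_error(average_volumes(list(v, volume(array(1, c(2, 2, 2)), 0.1))),
               class = "zfqmri_validation_error")

  set.seed(9)
  base <- array(1000, c(10, 10, 2))
  sigma <- 20
  for (n in c(4, 16)) {
    vols <- lapply(seq_len(n), function(i)
      volume(base + array(rnorm(200, 0, sigma), dim(base)), 0.1))
    res_sd <- sd(average_volumes(vols)$data - base)
    expect_equal(res_sd, sigma / sqrt(n), tolerance = 0.25)
  }
})
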