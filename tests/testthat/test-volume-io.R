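test_that("series round-trip through NIfTI + manifest is lossless", {
  ph <- tiny_phantom()
  ser <- tiny_t2_series(ph, noise_sigma = 40)$series
  d <- withr::local_tempdir()
  write_series(ser, d)
  back <- read_series(d)
  expect_identical(back$series_type, "T2")
  expect_equal(back$times_ms, ser$times_ms)
  for (i in seq_along(ser$volumes)) {
    expect_identical(back$volumes[[i]]$data, ser$volumes[[i]]$data)
    expect_equal(back$volumes[[i]]$voxel_size, ser$volumes[[i]]$voxel_size)
  }
})

test_that("series with repetitions round-trips", {
  ph <- tiny_phantom()
  ser <- tiny_t2_series(ph, noise_sigma = 20, n_rep = 2)$series
  d <- withr::local_tempdir()
  write_series(ser, d)
  back <- read_series(d)
  expect_length(back$repetitions, 3)
  expect_identical(back$repetitions[[2]][[1]]$data,
                   ser$repetitions[[2]][[1]]$data)
})

test_that("malformed series inputs raise typed errors", {
  d <- withr::local_tempdir()
  expect_error(read_series(d), class = "zfqmri_format_error")
  v <- volume(array(1, c(3, 3, 3)), 0.1)
  expect_error(acquisition_series(list(v), "T1", 50),
               class = "zfqmri_validation_error")
  v2 <- volume(array(1, c(3, 3, 2)), 0.1)
  expect_error(acquisition_series(list(v, v2), "T1", c(50, 150)),
               class = "zfqmri_validation_error")
  expect_error(acquisition_series(list(v, v), "T1", c(150, 50)),
               class = "zfqmri_validation_error")
  # manifest missing its sidecar metadata
  jsonlite::write_json(list(files = "vol_001.nii.gz"),
                       file.path(d, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_series(d), class = "zfqmri_format_error")
})

test_that("landmark tables round-trip and validate", {
  lm <- data.frame(frame_id = rep("frame_01", 3),
                   name = c("lens_left", "lens_right", "vagal_lobe_tip"),
                   x = c(15.5, 31.5, 23.5), y = c(9.5, 9.5, 17.25),
                   slice = 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_length(back, 1)
  expect_equal(back[["frame_01"]]$x, lm$x)
  expect_equal(back[["frame_01"]]$y, lm$y)

  # duplicate name within one frame
  bad <- rbind(lm, lm[1, ])
  write_landmarks(bad, f)
  expect_error(read_landmarks(f), class = "zfqmri_validation_error")

  # empty table: empty set with a warning
  write_landmarks(lm[0, ], f)
  expect_warning(empty <- read_landmarks(f), "empty")
  expect_length(empty, 0)
})

test_that("contour tables validate pairing, simplicity and containment", {
  f <- withr::local_tempfile(fileext = ".tsv")
  mk <- function(id, boundary, poly)
    data.frame(fiber_id = id, boundary = boundary,
               vertex_order = seq_len(nrow(poly)), x = poly[, 1],
               y = poly[, 2])
  good <- rbind(mk("f1", "axon", circle_poly(1, 4)),
                mk("f1", "myelin", circle_poly(2, 4)),
                mk("f2", "axon", circle_poly(0.5, 4)),
                mk("f2", "myelin", circle_poly(1.5, 4)))
  write_contours(good, f)
  tab <- read_contours(f, unit = "nm")
  expect_s3_class(tab, "zf_contours")
  expect_length(unique(tab$fiber_id), 2)

  # only one boundary
  write_contours(mk("f1", "axon", circle_poly(1, 4)), f)
  expect_error(read_contours(f), class = "zfqmri_validation_error")

  # axon outside myelin
  bad <- rbind(mk("f1", "axon", circle_poly(2, 8)),
               mk("f1", "myelin", circle_poly(1, 8)))
  write_contours(bad, f)
  expect_error(read_contours(f), class = "zfqmri_validation_error")

  # under 3 vertices
  bad2 <- rbind(mk("f1", "axon", circle_poly(1, 8)[1:2, ]),
                mk("f1", "myelin", circle_poly(2, 8)))
  write_contours(bad2, f)
  expect_error(read_contours(f), class = "zfqmri_validation_error")

  # self-crossing bow-tie polygon
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  bad3 <- rbind(mk("f1", "axon", bow / 4 + 0.4),
                mk("f1", "myelin", circle_poly(2, 8, center = c(0.5, 0.5))))
  write_contours(bad3, f)
  expect_error(read_contours(f), class = "zfqmri_validation_error")
})

test_that("polygon simplicity agrees with a brute-force crossing check", {
  set.seed(11)
  # star-shaped (radial) polygons are always simple
  for (i in 1:10) {
    r <- runif(12, 0.5, 1.5)
    th <- sort(runif(12, 0, 2 * pi))
    expect_true(polygon_is_simple(cbind(r * cos(th), r * sin(th))))
  }
  expect_false(polygon_is_simple(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))))
})

test_that("parameter maps round-trip with their hyperparameter sidecar", {
  ph <- tiny_phantom()
  map <- fit_map(tiny_t2_series(ph)$series,
                 control = relax_control(loop_limit = 1500))
  d <- withr::local_tempdir()
  write_parameter_map(map, d)
  side <- jsonlite::read_json(file.path(d, "parameter_map.json"),
                              simplifyVector = TRUE)
  expect_equal(side$learning_rate, 1e-6)
  expect_equal(side$m0_init, 8000)
  back <- read_parameter_map(d)
  expect_identical(back$t_value, map$t_value)
  expect_identical(back$m0, map$m0)
  expect_identical(back$mask, map$mask)
  expect_identical(back$iterations, map$iterations)
  expect_equal(back$hyperparams$loop_limit, 1500)
})

test_that("a non-finite value inside the fit mask blocks writing", {
  ph <- tiny_phantom()
  map <- fit_map(tiny_t2_series(ph)$series,
                 control = relax_control(loop_limit = 200))
  map$t_value[which(map$mask)[1]] <- NaN
  expect_error(write_parameter_map(map, withr::local_tempdir()),
               class = "zfqmri_validation_error")
})

test_that("ROI specifications round-trip through YAML", {
  spec <- roi_spec(9, list(list(pgz = c(11.5, 5.5), tectum = c(11.5, 8.5)),
                           list(pgz = c(11.5, 5.5), tectum = c(11.5, 8.5)),
                           list(pgz = c(11.5, 5.5), tectum = c(11.5, 8.5))),
                   rostral_direction = -1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_roi_spec(spec, f)
  back <- read_roi_spec(f)
  expect_equal(back$reference_slice, spec$reference_slice)
  expect_equal(back$centers, spec$centers)
  expect_equal(back$rostral_direction, -1L)
})
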